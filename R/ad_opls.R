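# Hierarchical age-corrected OPLS classifier for AD vs CTL.
#
# Volumetric and thickness measures are modelled separately (base models);
# the base models' output scores feed a top-level OPLS model.  Three
# correction strategies are supported:
#   none      - raw measures
#   covariate - age joins the top model alongside the base scores
#   detrend   - measures are age-detrended (control-estimated slopes)
#               before any model sees them
# During training the top model consumes the base models' CROSS-VALIDATED
# scores (fitted scores would leak information and inflate the top-level
# Q2); at prediction time the base models' ordinary predicted scores are
# used.  Classification uses a fixed cutoff of 0.5 on the cross-validated
# score: a subject scoring near 1 shows an AD-like pattern, near 0 a
# control-like pattern.

#' Fit the hierarchical age-corrected OPLS classifier
#'
#' The main fitting function.  Takes a cohort table, restricts it to AD and
#' CTL subjects, fits the two base OPLS models (21 volumes; 34 thickness
#' measures) and the top model on their cross-validated scores, selecting
#' the number of orthogonal components of every model by cross-validated
#' Q2 with a parsimony rule.  All data-dependent transformations
#' (detrending, scaling) are refit inside each training partition of the
#' sevenfold cross-validation.
#'
#' @param cohort a [cohort_table()]; only AD and CTL rows are used.
#' @param correction `"none"`, `"covariate"` (age joins the top model), or
#'   `"detrend"` (control-based linear age detrending of every measure).
#' @param k number of CV folds (default 7).
#' @param max_ortho,tol passed to [select_n_ortho()].
#' @param cutoff classification cutoff on the score scale (default 0.5;
#'   a score `>= cutoff` is labelled AD-like).
#' @param seed seed governing all fold construction.
#' @return an object of class `ad_opls` with, among others:
#'   `cv` (top-level [cv_opls] result: `q2`, `r2`, cross-validated scores),
#'   `metrics` (a `confusion_metrics` object for AD/CTL classification),
#'   `base` (the two base `cv_opls` objects), `top` (full-data top `opls`),
#'   `detrend` (full-data `age_detrend` fit when `correction = "detrend"`),
#'   `correct` (logical; which training subjects were correctly
#'   classified).
#' @seealso [predict.ad_opls()], [evaluate_at_month()], [run_experiment()]
#' @export
#' @examples
#' cfg <- cohort_config(n = c(60, 0, 0, 60))
#' coh <- simulate_cohort(cfg, seed = 3)
#' fit <- ad_opls(coh, correction = "detrend", seed = 3)
#' fit
ad_opls <- function(cohort, correction = c("none", "covariate", "detrend"),
                    k = 7, max_ortho = 5, tol = 0.01, cutoff = 0.5,
                    seed = 1) {
  correction <- match.arg(correction)
  stopifnot(inherits(cohort, "cohort_table"))
  train <- cohort_subset(cohort, c("CTL", "AD"))
  if (!all(table(train$diagnosis) >= 2) || length(unique(train$diagnosis)) < 2)
    stop_schema("need at least 2 subjects in each of CTL and AD")
  y <- as.numeric(train$diagnosis == "AD")
  ages <- train$age
  ctl_mask <- train$diagnosis == "CTL"
  feat_corr <- if (correction == "detrend") "detrend" else "none"

  fit_block <- function(block, stream) {
    X <- cohort_features(train, type = block)
    sel <- select_n_ortho(X, y, correction = feat_corr, ages = ages,
                          ctl_mask = ctl_mask, k = k,
                          seed = derive_seed(seed, stream),
                          max_ortho = max_ortho, tol = tol)
    attr(sel, "cv")
  }
  base_vol <- fit_block("volume", 1L)
  base_th <- fit_block("thickness", 2L)

  top_X <- cbind(volume_score = base_vol$yhat_cv,
                 thickness_score = base_th$yhat_cv)
  if (correction == "covariate") top_X <- cbind(top_X, age = ages)
  top_sel <- select_n_ortho(top_X, y, correction = "none", k = k,
                            seed = derive_seed(seed, 3L),
                            max_ortho = max_ortho, tol = tol)
  top_cv <- attr(top_sel, "cv")

  labels <- classify_scores(top_cv$yhat_cv, cutoff)
  metrics <- confusion_metrics(labels, y)

  # full-data detrender (fit on all training CTL rows) for unseen data;
  # per-feature OLS makes its coefficients identical to the per-block fits
  detrend_all <- if (correction == "detrend")
    age_detrend(cohort_features(train)[ctl_mask, , drop = FALSE], ages[ctl_mask])

  structure(list(
    correction = correction, cutoff = cutoff, k = k, seed = seed,
    base = list(volume = base_vol, thickness = base_th),
    top = top_cv$model, cv = top_cv,
    detrend = detrend_all,
    metrics = metrics,
    correct = labels == y,
    y = y, subject_id = train$subject_id,
    diagnosis = train$diagnosis, train = train,
    call = match.call()),
    class = "ad_opls")
}

#' Classify scores at a fixed cutoff
#'
#' @param scores numeric score vector.
#' @param cutoff decision threshold; a score `>= cutoff` is labelled 1
#'   (AD-like), below it 0 (CTL-like).
#' @return integer 0/1 labels.
#' @export
classify_scores <- function(scores, cutoff = 0.5) {
  as.integer(scores >= cutoff)
}

#' Confusion counts and classification percentages
#'
#' Positive class is AD (or AD-like truth).  Percentages are kept as raw
#' floats; `print()` reports them rounded half-up to one decimal.
#'
#' @param predicted 0/1 predicted labels.
#' @param truth 0/1 true labels; both classes must be present.
#' @return an object of class `confusion_metrics`: counts `tp, fn, tn, fp`
#'   and percentages `accuracy, sensitivity, specificity`.
#' @export
#' @examples
#' m <- confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' m$accuracy
confusion_metrics <- function(predicted, truth) {
  predicted <- as.integer(predicted)
  truth <- as.integer(truth)
  if (length(predicted) != length(truth)) stop_schema("label vectors differ in length")
  if (length(unique(truth)) < 2)
    stop_schema("truth has a single class; sensitivity or specificity undefined")
  tp <- sum(predicted == 1 & truth == 1)
  fn <- sum(predicted == 0 & truth == 1)
  tn <- sum(predicted == 0 & truth == 0)
  fp <- sum(predicted == 1 & truth == 0)
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 n = tp + fn + tn + fp,
                 accuracy = 100 * (tp + tn) / (tp + fn + tn + fp),
                 sensitivity = 100 * tp / (tp + fn),
                 specificity = 100 * tn / (tn + fp)),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.1f%%  sensitivity %.1f%%  specificity %.1f%%  (tp %d, fn %d, tn %d, fp %d)\n",
              round_half_up(x$accuracy), round_half_up(x$sensitivity),
              round_half_up(x$specificity), x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

#' @export
print.ad_opls <- function(x, ...) {
  cat(sprintf("Hierarchical OPLS AD/CTL classifier (%s correction)\n", x$correction))
  cat(sprintf("  n = %d (AD %d / CTL %d); %d-fold CV, cutoff %.2f\n",
              length(x$y), sum(x$y == 1), sum(x$y == 0), x$k, x$cutoff))
  cat(sprintf("  Q2 = %.3f, R2 = %.3f\n", x$cv$q2, x$cv$r2))
  cat("  "); print(x$metrics)
  invisible(x)
}

#' @export
summary.ad_opls <- function(object, ...) {
  structure(list(correction = object$correction,
                 q2 = object$cv$q2, r2 = object$cv$r2,
                 metrics = object$metrics,
                 n_ortho = c(volume = object$base$volume$n_ortho,
                             thickness = object$base$thickness$n_ortho,
                             top = object$cv$n_ortho),
                 base_q2 = c(volume = object$base$volume$q2,
                             thickness = object$base$thickness$q2)),
            class = "summary.ad_opls")
}

#' @export
print.summary.ad_opls <- function(x, ...) {
  cat(sprintf("Hierarchical OPLS AD/CTL classifier (%s correction)\n", x$correction))
  cat(sprintf("  top model:  Q2 = %.3f, R2 = %.3f, %d orthogonal component(s)\n",
              x$q2, x$r2, x$n_ortho[["top"]]))
  cat(sprintf("  base models: volume Q2 = %.3f (%d ortho), thickness Q2 = %.3f (%d ortho)\n",
              x$base_q2[["volume"]], x$n_ortho[["volume"]],
              x$base_q2[["thickness"]], x$n_ortho[["thickness"]]))
  cat("  classification: "); print(x$metrics)
  invisible(x)
}

#' @export
fitted.ad_opls <- function(object, ...) object$cv$yhat_cv

#' @export
residuals.ad_opls <- function(object, ...) object$y - object$cv$yhat_cv

#' @export
coef.ad_opls <- function(object, ...) {
  list(top = coef(object$top),
       volume = coef(object$base$volume$model),
       thickness = coef(object$base$thickness$model))
}

#' Predict unseen subjects with a fitted hierarchical classifier
#'
#' Applies the model's full transformation chain to new rows: age
#' detrending with the control-derived coefficients (when fitted with
#' `correction = "detrend"`), base-model scaling and scoring per feature
#' block, then the top model over the base scores (plus age for the
#' covariate strategy).  This is how MCI patients are scored as unseen
#' data.
#'
#' @param object an `ad_opls` fit.
#' @param newdata a `cohort_table` (any diagnoses; features must conform).
#' @param ... unused.
#' @return a data frame with `subject_id`, `score` and `label`
#'   (1 = AD-like, 0 = CTL-like at the model's cutoff).
#' @export
predict.ad_opls <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "cohort_table"))
  if (nrow(newdata) == 0)
    return(data.frame(subject_id = character(), score = numeric(),
                      label = integer()))
  ages <- newdata$age
  score_block <- function(block_cv, type) {
    X <- cohort_features(newdata, type = type)
    if (!is.null(object$detrend)) {
      dcols <- object$detrend$columns
      Xc <- apply_detrend(object$detrend,
                          cohort_features(newdata)[, dcols, drop = FALSE], ages)
      X <- Xc[, colnames(X), drop = FALSE]
    }
    predict(block_cv$model, X, scale = TRUE)
  }
  top_X <- cbind(volume_score = score_block(object$base$volume, "volume"),
                 thickness_score = score_block(object$base$thickness, "thickness"))
  if (object$correction == "covariate") top_X <- cbind(top_X, age = ages)
  score <- predict(object$top, top_X, scale = TRUE)
  data.frame(subject_id = newdata$subject_id, score = score,
             label = classify_scores(score, object$cutoff))
}

#' @export
plot.ad_opls <- function(x, ...) {
  sc <- x$cv$yhat_cv
  grp <- factor(ifelse(x$y == 1, "AD", "CTL"), levels = c("CTL", "AD"))
  graphics::stripchart(sc ~ grp, vertical = TRUE, method = "jitter",
                       pch = 16, cex = 0.5,
                       col = c("#2c7fb8", "#d95f0e"),
                       ylab = "cross-validated score",
                       main = sprintf("AD/CTL separation (%s correction)",
                                      x$correction), ...)
  graphics::abline(h = x$cutoff, lty = 2)
  invisible(x)
}

#' Evaluate MCI predictions against progression status at a follow-up month
#'
#' Progression to AD by the given month is the positive truth; subjects
#' with unknown status at that month are excluded (their count is reported
#' in the result).  Follow-up beyond month 12 is typically only available
#' for the ADNI sub-cohort; restrict `mci` accordingly before calling, or
#' rely on the unknown-status exclusion.
#'
#' @param predictions a prediction data frame from [predict.ad_opls()] (or
#'   an integer 0/1 label vector) aligned with `mci` rows.
#' @param mci a `cohort_table` of MCI subjects.
#' @param month follow-up month: 12, 18, 24 or 36.
#' @return a `confusion_metrics` object with extra fields `month` and
#'   `n_unknown`.
#' @export
evaluate_at_month <- function(predictions, mci, month) {
  stopifnot(inherits(mci, "cohort_table"))
  if (!month %in% progression_months())
    stop_schema("month must be one of %s",
                paste(progression_months(), collapse = ", "))
  labels <- if (is.data.frame(predictions)) predictions$label else as.integer(predictions)
  if (length(labels) != nrow(mci))
    stop_schema("predictions and cohort rows differ in length")
  status <- mci[[prog_col(month)]]
  known <- status != "unknown"
  if (!any(known)) stop_schema("no subject has known status at month %d", month)
  truth <- as.integer(status[known] == "progressed")
  m <- confusion_metrics(labels[known], truth)
  m$month <- month
  m$n_unknown <- sum(!known)
  m
}
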