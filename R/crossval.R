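# Sevenfold cross-validation: per-subject cross-validated scores, Q2, and
# data-driven selection of the number of orthogonal components.  Every
# transformation that depends on the data (age detrending, UV scaling) is
# refit inside each training partition, so held-out rows never leak into
# any fitted parameter.

#' Stratified fold assignment
#'
#' Partitions `n` subjects into `k` folds whose sizes differ by at most one
#' overall and within each class.  Falls back to unstratified assignment
#' (with a warning) when a class has fewer members than `k`.
#' Deterministic given `seed`.
#'
#' @param n number of subjects.
#' @param k number of folds (default 7).
#' @param labels 0/1 class labels used for stratification.
#' @param seed RNG seed.
#' @return integer vector of fold ids in `1:k`, one per subject.
#' @export
make_folds <- function(n, k = 7, labels = NULL, seed = 1) {
  if (n < k) stop_schema("need at least k = %d subjects, got %d", k, n)
  with_seed(seed, {
    if (is.null(labels)) labels <- rep(0L, n)
    if (length(labels) != n) stop_schema("labels must have length n")
    counts <- table(labels)
    if (length(counts) > 1 && any(counts < k)) {
      warning("a class has fewer members than k; falling back to unstratified folds")
      ord <- sample.int(n)
    } else {
      # shuffle within class, concatenate classes, then assign cyclically:
      # contiguous class blocks make per-class fold sizes differ by <= 1,
      # and rep_len balances the overall sizes.
      ord <- unlist(lapply(split(seq_len(n), labels),
                           function(ix) ix[sample.int(length(ix))]),
                    use.names = FALSE)
    }
    folds <- integer(n)
    folds[ord] <- rep_len(seq_len(k), n)
    folds
  })
}

#' Cross-validated OPLS scores and Q2
#'
#' Runs stratified k-fold cross-validation of a two-class OPLS model.
#' Within each fold the age-detrending model (when
#' `correction = "detrend"`) is fit on the control members of the training
#' partition only, UV scaling is fit on the (corrected) training rows, an
#' OPLS model is fit, and the held-out rows are predicted.  Q2 is
#' `1 - PRESS/SS`, with deviations taken from the overall mean response.
#' The returned object also carries a full-data refit with identical
#' settings (its R2 is the reported goodness of fit, and it is the model
#' used to predict genuinely unseen data).
#'
#' @param X_raw numeric matrix of raw (unscaled) features.
#' @param y 0/1 response.
#' @param n_ortho number of orthogonal components.
#' @param correction `"none"` or `"detrend"`.
#' @param ages ages in years (required for `"detrend"`).
#' @param ctl_mask logical; which rows are controls, i.e. eligible for
#'   detrend estimation.  Defaults to `y == 0`.
#' @param k number of folds.
#' @param seed RNG seed for fold construction.
#' @param folds optional explicit fold assignment (overrides `k`/`seed`).
#' @return an object of class `cv_opls`: `yhat_cv`, `folds`, `q2`, `r2`,
#'   `n_ortho`, `seed`, `model` (full-data `opls` refit with scaling
#'   attached), and `detrend` (full-data `age_detrend` fit or `NULL`).
#' @seealso [select_n_ortho()]
#' @export
cv_opls <- function(X_raw, y, n_ortho = 0, correction = c("none", "detrend"),
                    ages = NULL, ctl_mask = NULL, k = 7, seed = 1,
                    folds = NULL) {
  correction <- match.arg(correction)
  X_raw <- as.matrix(X_raw)
  y <- as.numeric(y)
  n <- nrow(X_raw)
  if (correction == "detrend") {
    if (is.null(ages)) stop_schema("ages are required for detrend correction")
    if (is.null(ctl_mask)) ctl_mask <- y == 0
  }
  if (is.null(folds)) folds <- make_folds(n, k, labels = y, seed = seed)

  prepare <- function(train_idx) {
    dt <- NULL
    Xtr <- X_raw[train_idx, , drop = FALSE]
    if (correction == "detrend") {
      ctl_idx <- train_idx[ctl_mask[train_idx]]
      dt <- age_detrend(X_raw[ctl_idx, , drop = FALSE], ages[ctl_idx])
      Xtr <- apply_detrend(dt, Xtr, ages[train_idx])
    }
    sc <- fit_scaling(Xtr)
    list(detrend = dt, scaling = sc, X = apply_scaling(sc, Xtr))
  }
  transform_new <- function(prep, idx) {
    Xn <- X_raw[idx, , drop = FALSE]
    if (!is.null(prep$detrend)) Xn <- apply_detrend(prep$detrend, Xn, ages[idx])
    apply_scaling(prep$scaling, Xn)
  }

  yhat_cv <- rep(NA_real_, n)
  for (f in sort(unique(folds))) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    prep <- prepare(train_idx)
    fit <- opls(prep$X, y[train_idx], n_ortho)
    yhat_cv[test_idx] <- predict(fit, transform_new(prep, test_idx), scale = FALSE)
  }
  press <- sum((y - yhat_cv)^2)
  ss <- sum((y - mean(y))^2)
  q2 <- 1 - press / ss

  full <- prepare(seq_len(n))
  full_fit <- opls(full$X, y, n_ortho, scaling = full$scaling)

  structure(list(yhat_cv = yhat_cv, folds = folds, q2 = q2, r2 = full_fit$r2,
                 n_ortho = n_ortho, seed = seed, y = y,
                 model = full_fit, detrend = full$detrend,
                 correction = correction),
            class = "cv_opls")
}

#' @export
print.cv_opls <- function(x, ...) {
  cat(sprintf("Cross-validated OPLS (%d folds, %d orthogonal component(s))\n",
              length(unique(x$folds)), x$n_ortho))
  cat(sprintf("  Q2 = %.3f (goodness of prediction), R2 = %.3f (goodness of fit)\n",
              x$q2, x$r2))
  invisible(x)
}

#' Export cross-validated scores to CSV / metrics to JSON
#'
#' @param cv a `cv_opls` object.
#' @param scores_path CSV path for per-subject rows
#'   (`subject_id, fold, y, yhat_cv`).
#' @param metrics_path optional JSON path for `{q2, r2, n_ortho, seed}`.
#' @param subject_id optional subject ids (defaults to row numbers).
#' @return `scores_path`, invisibly.
#' @export
write_cv_result <- function(cv, scores_path, metrics_path = NULL,
                            subject_id = NULL) {
  df <- data.frame(subject_id = subject_id %||% seq_along(cv$yhat_cv),
                   fold = cv$folds, y = cv$y, yhat_cv = cv$yhat_cv)
  utils::write.csv(df, scores_path, row.names = FALSE)
  if (!is.null(metrics_path))
    jsonlite::write_json(list(q2 = cv$q2, r2 = cv$r2, n_ortho = cv$n_ortho,
                              seed = cv$seed),
                         metrics_path, auto_unbox = TRUE, digits = NA)
  invisible(scores_path)
}

#' Select the number of orthogonal components by Q2
#'
#' Evaluates cross-validated Q2 for `n_ortho = 0 ... max_ortho` (capped at
#' one less than the number of columns) and returns the smallest count
#' whose Q2 is within `tol` of the maximum — a parsimony rule that avoids
#' chasing negligible Q2 gains with extra components.
#'
#' @inheritParams cv_opls
#' @param max_ortho largest count to consider (default 5).
#' @param tol Q2 tolerance for the parsimony rule (default 0.01).
#' @return the selected count (integer) with attributes `q2` (the Q2 value
#'   per candidate) and `cv` (the `cv_opls` object of the selected count).
#' @export
select_n_ortho <- function(X_raw, y, correction = c("none", "detrend"),
                           ages = NULL, ctl_mask = NULL, k = 7, seed = 1,
                           max_ortho = 5, tol = 0.01, folds = NULL) {
  correction <- match.arg(correction)
  X_raw <- as.matrix(X_raw)
  max_ortho <- min(max_ortho, ncol(X_raw) - 1L)
  if (is.null(folds))
    folds <- make_folds(nrow(X_raw), k, labels = y, seed = seed)
  cvs <- vector("list", max_ortho + 1L)
  q2s <- numeric(max_ortho + 1L)
  first_err <- NULL
  for (a in 0:max_ortho) {
    res <- tryCatch(
      cv_opls(X_raw, y, n_ortho = a, correction = correction, ages = ages,
              ctl_mask = ctl_mask, k = k, seed = seed, folds = folds),
      error = function(e) e)
    if (inherits(res, "error")) {
      if (is.null(first_err)) first_err <- res
      q2s[a + 1L] <- -Inf
    } else {
      cvs[[a + 1L]] <- res
      q2s[a + 1L] <- res$q2
    }
  }
  if (all(!is.finite(q2s))) stop(first_err)
  best <- max(q2s)
  sel <- which(q2s >= best - tol)[1] - 1L
  structure(as.integer(sel),
            q2 = stats::setNames(q2s, 0:max_ortho),
            cv = cvs[[sel + 1L]])
}
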