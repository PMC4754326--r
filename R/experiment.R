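# End-to-end experiment: for each correction strategy, fit the AD/CTL
# classifier, predict the MCI subjects as unseen data, evaluate progression
# at each follow-up month, and characterize correctly vs incorrectly
# classified subjects.

#' Configuration for a full three-model experiment
#'
#' @param sim a [cohort_config()] used to simulate the cohort, or `NULL`
#'   when `cohort_path` is given.
#' @param cohort_path path to a cohort CSV (read with [read_cohort()]).
#' @param corrections correction strategies to run (any of
#'   `"none"`, `"covariate"`, `"detrend"`).
#' @param seed top-level seed governing simulation and fold construction.
#' @param k CV folds (default 7).
#' @param max_ortho,tol orthogonal-component selection controls.
#' @param cutoff classification cutoff (default 0.5).
#' @param months follow-up months at which to evaluate MCI predictions;
#'   months beyond 12 are evaluated on the ADNI sub-cohort only.
#' @param characterize also produce the subgroup comparison tables.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(sim = cohort_config(),
                              cohort_path = NULL,
                              corrections = c("none", "covariate", "detrend"),
                              seed = 1, k = 7, max_ortho = 5, tol = 0.01,
                              cutoff = 0.5,
                              months = progression_months(),
                              characterize = TRUE) {
  corrections <- match.arg(corrections, several.ok = TRUE)
  if (k < 2) stop_schema("k must be at least 2")
  if (cutoff <= 0 || cutoff >= 1) stop_schema("cutoff must lie in (0, 1)")
  if (!length(corrections)) stop_schema("at least one correction strategy is required")
  structure(list(sim = sim, cohort_path = cohort_path,
                 corrections = corrections, seed = as.integer(seed), k = k,
                 max_ortho = max_ortho, tol = tol, cutoff = cutoff,
                 months = months, characterize = characterize),
            class = "experiment_config")
}

#' Read an experiment configuration from JSON or YAML
#'
#' Scalar fields of [experiment_config()] may be given in the file;
#' simulation settings go under a `sim` mapping whose entries are passed
#' to [cohort_config()].
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_schema("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path)
  sim <- if (!is.null(obj$sim)) do.call(cohort_config, obj$sim) else cohort_config()
  args <- obj[setdiff(names(obj), "sim")]
  do.call(experiment_config, c(list(sim = sim), args))
}

#' Run the full classification / prediction / characterization experiment
#'
#' For every configured correction strategy: fit the hierarchical AD/CTL
#' classifier with sevenfold cross-validation, report Q2/R2 and the
#' fixed-cutoff classification metrics; predict the MCI subjects as unseen
#' data and evaluate progression at each configured follow-up month
#' (months beyond 12 on the ADNI sub-cohort); and, optionally, build the
#' correct-vs-incorrect comparison tables for both the AD/CTL
#' classification and the month-12 MCI prediction.  Fully reproducible
#' from the single seed.
#'
#' @param config an [experiment_config()].
#' @param cohort optionally, a ready-made `cohort_table` (overrides the
#'   config's simulation/path source).
#' @return an object of class `ad_experiment`: `cohort`, `config`, and a
#'   named list `strategies`, each entry carrying `fit` (the [ad_opls]
#'   object), `mci` (prediction data frame), `months` (a list of
#'   `confusion_metrics` per month), `classification_comparison` and
#'   `mci_comparison` tables.
#' @export
#' @examples
#' cfg <- experiment_config(sim = cohort_config(n = c(50, 40, 12, 45)),
#'                          corrections = "detrend", months = 12,
#'                          characterize = FALSE)
#' res <- run_experiment(cfg)
#' res
run_experiment <- function(config = experiment_config(), cohort = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(cohort)) {
    cohort <- if (!is.null(config$cohort_path))
      read_cohort(config$cohort_path)
    else simulate_cohort(config$sim, seed = config$seed)
  }
  mci <- cohort_subset(cohort, "MCI")

  strategies <- list()
  for (corr in config$corrections) {
    fit <- ad_opls(cohort, correction = corr, k = config$k,
                   max_ortho = config$max_ortho, tol = config$tol,
                   cutoff = config$cutoff, seed = config$seed)
    pred <- predict(fit, mci)
    month_metrics <- list()
    for (m in config$months) {
      sub <- if (m > 12) mci$cohort == "ADNI" else rep(TRUE, nrow(mci))
      month_metrics[[paste0("m", m)]] <- tryCatch(
        evaluate_at_month(pred$label[sub], mci[sub, ], m),
        error = function(e) NULL)
    }
    cls_cmp <- mci_cmp <- NULL
    if (isTRUE(config$characterize)) {
      cls_cmp <- compare_subgroups(fit$train, fit$correct)
      if (nrow(mci) && "m12" %in% names(month_metrics) &&
          !is.null(month_metrics$m12)) {
        truth12 <- as.integer(mci$prog_m12 == "progressed")
        grp12 <- ifelse(truth12 == 1, "MCI-p", "MCI-s")
        mci_cmp <- compare_subgroups(mci, pred$label == truth12, group = grp12)
      }
    }
    strategies[[corr]] <- list(correction = corr, fit = fit, mci = pred,
                               months = month_metrics,
                               classification_comparison = cls_cmp,
                               mci_comparison = mci_cmp)
  }
  structure(list(cohort = cohort, config = config, strategies = strategies),
            class = "ad_experiment")
}

#' @export
print.ad_experiment <- function(x, ...) {
  cat("Age-corrected OPLS experiment\n")
  cat(sprintf("  cohort: %d subjects (%s)\n", nrow(x$cohort),
              paste(names(table(x$cohort$diagnosis)),
                    table(x$cohort$diagnosis), sep = "=", collapse = ", ")))
  cat(sprintf("  seed %d, %d-fold CV, cutoff %.2f\n\n",
              x$config$seed, x$config$k, x$config$cutoff))
  cat("AD vs CTL classification (cross-validated):\n")
  cat(sprintf("  %-10s %6s %6s %9s %12s %12s\n",
              "model", "Q2", "R2", "Acc %", "Sens %", "Spec %"))
  for (s in x$strategies) {
    m <- s$fit$metrics
    cat(sprintf("  %-10s %6.3f %6.3f %9.1f %12.1f %12.1f\n",
                s$correction, s$fit$cv$q2, s$fit$cv$r2,
                round_half_up(m$accuracy), round_half_up(m$sensitivity),
                round_half_up(m$specificity)))
  }
  months <- names(x$strategies[[1]]$months)
  if (length(months)) {
    cat("\nMCI progression prediction:\n")
    for (mm in months) {
      cat(sprintf("  month %s\n", sub("^m", "", mm)))
      for (s in x$strategies) {
        met <- s$months[[mm]]
        if (is.null(met)) next
        cat(sprintf("    %-10s acc %5.1f  sens %5.1f  spec %5.1f  (n = %d)\n",
                    s$correction, round_half_up(met$accuracy),
                    round_half_up(met$sensitivity),
                    round_half_up(met$specificity), met$n))
      }
    }
  }
  invisible(x)
}

#' Extract the headline metrics of an experiment as a data frame
#'
#' One row per (strategy, endpoint): the AD/CTL classification row plus
#' one row per evaluated MCI follow-up month.
#'
#' @param x an `ad_experiment`.
#' @return a data frame with columns `strategy`, `endpoint`, `q2`, `r2`,
#'   `accuracy`, `sensitivity`, `specificity`, `n`.
#' @export
experiment_metrics <- function(x) {
  stopifnot(inherits(x, "ad_experiment"))
  rows <- list()
  for (s in x$strategies) {
    m <- s$fit$metrics
    rows[[length(rows) + 1L]] <- data.frame(
      strategy = s$correction, endpoint = "ad_ctl",
      q2 = s$fit$cv$q2, r2 = s$fit$cv$r2,
      accuracy = m$accuracy, sensitivity = m$sensitivity,
      specificity = m$specificity, n = m$n, stringsAsFactors = FALSE)
    for (mm in names(s$months)) {
      met <- s$months[[mm]]
      if (is.null(met)) next
      rows[[length(rows) + 1L]] <- data.frame(
        strategy = s$correction, endpoint = paste0("mci_", mm),
        q2 = NA_real_, r2 = NA_real_,
        accuracy = met$accuracy, sensitivity = met$sensitivity,
        specificity = met$specificity, n = met$n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
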