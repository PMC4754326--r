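# Characterization of correctly vs incorrectly classified subjects:
# per-variable comparisons (pooled-variance t test for continuous
# variables, Pearson chi-squared without continuity correction for
# categorical ones) and the before/after age-correlation table.

.default_compare_vars <- c("age", "education", "mmse", "sex", "apoe4", "cohort")
.continuous_vars <- c("age", "education", "mmse", "cdr")

#' Compare correctly vs incorrectly classified subjects
#'
#' Produces the three standard comparisons for a two-group classification:
#' correct vs incorrect within the first group, correct vs incorrect
#' within the second group, and incorrect members of group 1 vs incorrect
#' members of group 2.  Continuous variables use a two-sided
#' pooled-variance (Student) independent-samples t test; categorical
#' variables use the Pearson chi-squared test without continuity
#' correction.  Subjects with an `unknown` level are dropped for that
#' variable only.  A comparison with an empty subgroup is marked not
#' computable rather than failing.
#'
#' Significance is flagged at 0.05, unadjusted for multiplicity.
#'
#' @param cohort a `cohort_table` aligned with `correct`.
#' @param correct logical; was each subject classified/predicted correctly.
#' @param group factor-like with two levels defining the diagnostic
#'   grouping (defaults to the cohort's `diagnosis`; for MCI prediction
#'   pass e.g. the month-12 status).
#' @param variables metadata variables to compare.
#' @return a `comparison_table`: a data frame with one row per
#'   (comparison, variable), summaries for both subgroups, the test used,
#'   its statistic, the p value, and a significance flag.
#' @export
compare_subgroups <- function(cohort, correct,
                              group = NULL,
                              variables = .default_compare_vars) {
  stopifnot(inherits(cohort, "cohort_table"))
  correct <- as.logical(correct)
  if (length(correct) != nrow(cohort))
    stop_schema("'correct' must have one value per subject")
  group <- factor(group %||% cohort$diagnosis)
  if (nlevels(droplevels(group)) != 2)
    stop_schema("'group' must have exactly two levels")
  group <- droplevels(group)
  lv <- levels(group)
  meta <- cohort_meta(cohort)

  comparisons <- list(
    list(name = sprintf("%s: correct vs incorrect", lv[1]),
         a = group == lv[1] & correct, b = group == lv[1] & !correct),
    list(name = sprintf("%s: correct vs incorrect", lv[2]),
         a = group == lv[2] & correct, b = group == lv[2] & !correct),
    list(name = sprintf("incorrect %s vs incorrect %s", lv[1], lv[2]),
         a = group == lv[1] & !correct, b = group == lv[2] & !correct))

  rows <- list()
  for (cmp in comparisons) {
    for (v in variables) {
      x <- meta[[v]]
      keep_a <- cmp$a; keep_b <- cmp$b
      continuous <- v %in% .continuous_vars
      if (!continuous) {
        known <- x != "unknown" & !is.na(x)
        keep_a <- keep_a & known; keep_b <- keep_b & known
      } else {
        keep_a <- keep_a & !is.na(x); keep_b <- keep_b & !is.na(x)
      }
      xa <- x[keep_a]; xb <- x[keep_b]
      row <- data.frame(comparison = cmp$name, variable = v,
                        n1 = length(xa), n2 = length(xb),
                        test = if (continuous) "t" else "chisq",
                        summary1 = NA_character_, summary2 = NA_character_,
                        statistic = NA_real_, p_value = NA_real_,
                        significant = NA, note = "",
                        stringsAsFactors = FALSE)
      if (length(xa) == 0 || length(xb) == 0) {
        row$note <- "not computable: empty subgroup"
      } else if (continuous) {
        row$summary1 <- sprintf("%.1f ± %.1f", mean(xa), stats::sd(xa))
        row$summary2 <- sprintf("%.1f ± %.1f", mean(xb), stats::sd(xb))
        if (length(xa) < 2 || length(xb) < 2 ||
            (stats::sd(xa) == 0 && stats::sd(xb) == 0)) {
          row$note <- "not computable: too few observations or zero variance"
        } else {
          tt <- stats::t.test(xa, xb, var.equal = TRUE)
          row$statistic <- unname(tt$statistic)
          row$p_value <- tt$p.value
        }
      } else {
        lvls <- sort(unique(c(xa, xb)))
        ca <- table(factor(xa, levels = lvls))
        cb <- table(factor(xb, levels = lvls))
        row$summary1 <- paste(sprintf("%s=%d", lvls, as.integer(ca)), collapse = " ")
        row$summary2 <- paste(sprintf("%s=%d", lvls, as.integer(cb)), collapse = " ")
        tab <- rbind(ca, cb)
        if (length(lvls) < 2) {
          row$note <- "not computable: single level"
        } else {
          ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
          row$statistic <- unname(ct$statistic)
          row$p_value <- ct$p.value
        }
      }
      row$significant <- if (is.na(row$p_value)) NA else row$p_value < 0.05
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("comparison_table", "data.frame"),
            groups = lv)
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("Subgroup comparison (t test for continuous, Pearson chi-squared for categorical)\n")
  cat("Significance flagged at p < 0.05, unadjusted for multiple comparisons.\n\n")
  for (cmp in unique(x$comparison)) {
    cat(cmp, "\n")
    sub <- x[x$comparison == cmp, ]
    for (i in seq_len(nrow(sub))) {
      r <- sub[i, ]
      if (nzchar(r$note)) {
        cat(sprintf("  %-10s %s\n", r$variable, r$note))
      } else {
        cat(sprintf("  %-10s %-22s vs %-22s p = %s%s\n", r$variable,
                    r$summary1, r$summary2,
                    format.pval(r$p_value, digits = 3, eps = 1e-3),
                    if (isTRUE(r$significant)) " *" else ""))
      }
    }
    cat("\n")
  }
  invisible(x)
}

#' Write a comparison table to CSV
#'
#' @param x a `comparison_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Pooled-variance t test from summary statistics
#'
#' Two-sided independent-samples Student t test computed from per-group
#' `n`, mean and SD — the closed form used to check printed
#' mean-plus-minus-SD tables.
#'
#' @param n1,m1,s1 size, mean and SD of group 1.
#' @param n2,m2,s2 size, mean and SD of group 2.
#' @return a list with `statistic`, `df` and `p_value`.
#' @export
#' @examples
#' t_test_summary(309, 74.5, 5.6, 31, 79.1, 5.2)$p_value
t_test_summary <- function(n1, m1, s1, n2, m2, s2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Pearson correlations of each feature with age, before and after correction
#'
#' For each feature and diagnostic group, the Pearson correlation with age
#' in the original cohort and in the corrected cohort — the standard audit
#' that age detrending actually removed the age association.
#'
#' @param cohort original `cohort_table`.
#' @param corrected a `cohort_table` with identical subjects whose
#'   features have been corrected (see [apply_detrend()]).
#' @param by_group split by diagnosis (default) or pool all subjects.
#' @return a data frame with columns `feature`, `group`, `r_before`,
#'   `r_after` (`NA` when a group has fewer than 3 subjects).
#' @export
age_correlation_table <- function(cohort, corrected, by_group = TRUE) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(corrected, "cohort_table"))
  if (!identical(cohort$subject_id, corrected$subject_id))
    stop_schema("cohorts must contain the same subjects in the same order")
  manifest <- cohort_manifest(cohort)
  Xb <- cohort_features(cohort)
  Xa <- cohort_features(corrected)
  groups <- if (by_group) split(seq_len(nrow(cohort)), cohort$diagnosis)
            else list(all = seq_len(nrow(cohort)))
  rows <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    r_of <- function(X) {
      if (length(idx) < 3) return(rep(NA_real_, ncol(X)))
      as.numeric(stats::cor(cohort$age[idx], X[idx, , drop = FALSE]))
    }
    rows[[g]] <- data.frame(feature = manifest$name, group = g,
                            r_before = r_of(Xb), r_after = r_of(Xa),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Age-detrend a whole cohort table
#'
#' Convenience wrapper: fits the detrender on the cohort's CTL subjects
#' (or uses a supplied fit) and returns a cohort whose feature columns are
#' corrected; metadata is untouched.
#'
#' @param cohort a `cohort_table`.
#' @param model optional `age_detrend` fit; by default fit on the cohort's
#'   CTL rows.
#' @return a list with `cohort` (corrected `cohort_table`) and `model`
#'   (the `age_detrend` fit used).
#' @export
detrend_cohort <- function(cohort, model = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (is.null(model)) {
    ctl <- cohort$diagnosis == "CTL"
    if (sum(ctl) < 3) stop_schema("need at least 3 CTL subjects to fit the detrender")
    model <- age_detrend(cohort_features(cohort)[ctl, , drop = FALSE],
                         cohort$age[ctl])
  }
  Xc <- apply_detrend(model, cohort_features(cohort), cohort$age)
  data <- as.data.frame(unclass(cohort), stringsAsFactors = FALSE)
  data[, colnames(Xc)] <- Xc
  list(cohort = cohort_table(data, cohort_manifest(cohort)), model = model)
}
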