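# Synthetic cohort generator.  Emulates the statistical structure the
# analysis assumes: per-feature linear age drift, graded disease effects
# concentrated in medial temporal structures, demographic mixtures per
# diagnostic group, and MCI progression labels that track latent severity.

.sim_groups <- c("ctl", "mci_s", "mci_p", "ad")

#' Simulation configuration for synthetic cohorts
#'
#' Builds the configuration object consumed by [simulate_cohort()].  The
#' defaults emulate a two-cohort AD/MCI/CTL case-control study:
#' 340 controls, 360 stable MCI, 85 progressive MCI (by month 12) and 297
#' AD patients, ages centred near 75 y, with group-specific demographic
#' mixtures.  Feature-level defaults (healthy baseline, linear age slope,
#' residual SD, AD effect size in residual-SD units) come from the packaged
#' manifest table; disease effects are largest (about -1.5 SD) in
#' hippocampus, amygdala and entorhinal cortex, intermediate (about -1 SD)
#' in the remaining temporal-lobe measures, and small elsewhere, with
#' positive effects for ventricular/CSF expansion measures.
#'
#' Per-subject disease severity is `fraction[group] * h`, with
#' `h ~ N(1, severity_sd)` truncated at 0, so diagnostic groups have graded
#' mean effects (CTL 0 < MCI-s < MCI-p < AD) while individual subjects
#' overlap.  A shared latent factor (`shared_noise_frac` of the residual
#' variance, aligned with the atrophy direction of each feature) induces
#' the positive inter-feature correlation seen in real morphometry tables;
#' marginal residual SDs equal `residual_sd`.
#'
#' @param n,age_mean,age_sd,male_prob,apoe4_prob,adni_prob,educ_mean,educ_sd,mmse_mean,mmse_sd
#'   numeric vectors of length 4, one value per group in the order
#'   CTL, MCI-s, MCI-p, AD.
#' @param mci_s_fraction,mci_p_fraction mean disease-effect fraction
#'   (of the full AD effect) for stable and progressive MCI; must satisfy
#'   `mci_p_fraction >= mci_s_fraction`.
#' @param severity_sd SD of the multiplicative per-subject severity factor.
#' @param shared_noise_frac fraction of residual variance carried by the
#'   shared latent factor, in `[0, 1)`.
#' @param age_range truncation bounds for the age distributions (years).
#' @param reference_age age at which `baseline` is defined (years).
#' @param conversion_frac named fractions of MCI-s subjects that have
#'   progressed by months 18/24/36 (cumulative, applied in decreasing order
#'   of latent severity).
#' @param manifest feature manifest.
#' @param baseline,age_slope,residual_sd,effect_ad per-feature parameter
#'   vectors in manifest order (defaults from the packaged table).
#' @param seed default RNG seed used by [simulate_cohort()].
#' @return an object of class `cohort_config`.
#' @seealso [simulate_cohort()], [confounded_config()]
#' @export
cohort_config <- function(n = c(340L, 360L, 85L, 297L),
                          age_mean = c(75.0, 75.0, 74.3, 75.7),
                          age_sd = c(5.7, 6.9, 6.5, 7.0),
                          male_prob = c(168/340, 219/360, 50/85, 132/297),
                          apoe4_prob = c(92/334, 158/340, 52/83, 178/288),
                          adni_prob = c(227/340, 260/360, 62/85, 175/297),
                          educ_mean = c(14.3, 13.9, 13.8, 12.0),
                          educ_sd = c(4.3, 4.7, 4.2, 4.9),
                          mmse_mean = c(29.1, 27.1, 26.5, 22.2),
                          mmse_sd = c(1.1, 1.7, 1.8, 3.7),
                          mci_s_fraction = 0.45,
                          mci_p_fraction = 0.70,
                          severity_sd = 0.5,
                          shared_noise_frac = 0.3,
                          age_range = c(55, 95),
                          reference_age = 75,
                          conversion_frac = c(m18 = 0.11, m24 = 0.25, m36 = 0.34),
                          manifest = default_manifest(),
                          baseline = NULL, age_slope = NULL,
                          residual_sd = NULL, effect_ad = NULL,
                          seed = 1L) {
  params <- feature_param_table()
  if (!identical(manifest$name, params$name)) params <- NULL
  pick <- function(given, col) {
    if (!is.null(given)) {
      v <- as.numeric(given)
      if (length(v) != nrow(manifest))
        stop_schema("'%s' must have one value per manifest feature", col)
      return(v)
    }
    if (is.null(params))
      stop_schema("custom manifest requires explicit '%s'", col)
    params[[col]]
  }
  cfg <- list(
    n = stats::setNames(as.integer(n), .sim_groups),
    age_mean = stats::setNames(as.numeric(age_mean), .sim_groups),
    age_sd = stats::setNames(as.numeric(age_sd), .sim_groups),
    male_prob = stats::setNames(as.numeric(male_prob), .sim_groups),
    apoe4_prob = stats::setNames(as.numeric(apoe4_prob), .sim_groups),
    adni_prob = stats::setNames(as.numeric(adni_prob), .sim_groups),
    educ_mean = stats::setNames(as.numeric(educ_mean), .sim_groups),
    educ_sd = stats::setNames(as.numeric(educ_sd), .sim_groups),
    mmse_mean = stats::setNames(as.numeric(mmse_mean), .sim_groups),
    mmse_sd = stats::setNames(as.numeric(mmse_sd), .sim_groups),
    fraction = stats::setNames(c(0, mci_s_fraction, mci_p_fraction, 1), .sim_groups),
    severity_sd = as.numeric(severity_sd),
    shared_noise_frac = as.numeric(shared_noise_frac),
    age_range = as.numeric(age_range),
    reference_age = as.numeric(reference_age),
    conversion_frac = conversion_frac,
    manifest = manifest,
    baseline = pick(baseline, "baseline"),
    age_slope = pick(age_slope, "age_slope"),
    residual_sd = pick(residual_sd, "residual_sd"),
    effect_ad = pick(effect_ad, "effect_ad"),
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_config <- function(cfg) {
  stopifnot(length(cfg$n) == 4)
  if (any(cfg$n < 0)) stop_schema("group counts must be non-negative")
  fr <- cfg$fraction
  if (any(fr < 0 | fr > 1)) stop_schema("effect fractions must lie in [0, 1]")
  if (fr["mci_p"] < fr["mci_s"])
    stop_schema("MCI-p effect fraction must be >= MCI-s fraction")
  if (any(cfg$residual_sd <= 0)) stop_schema("residual_sd must be positive")
  if (cfg$severity_sd < 0) stop_schema("severity_sd must be non-negative")
  if (cfg$shared_noise_frac < 0 || cfg$shared_noise_frac >= 1)
    stop_schema("shared_noise_frac must lie in [0, 1)")
  probs <- c(cfg$male_prob, cfg$apoe4_prob, cfg$adni_prob)
  if (any(probs < 0 | probs > 1)) stop_schema("probabilities must lie in [0, 1]")
  if (diff(cfg$age_range) <= 0) stop_schema("age_range must be increasing")
  cf <- cfg$conversion_frac
  if (any(cf < 0 | cf > 1) || is.unsorted(cf))
    stop_schema("conversion_frac must be non-decreasing fractions in [0, 1]")
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  groups (CTL/MCI-s/MCI-p/AD): %s\n",
              paste(x$n, collapse = " / ")))
  cat(sprintf("  ages: %s (truncated to [%g, %g])\n",
              paste(sprintf("%.1f+/-%.1f", x$age_mean, x$age_sd), collapse = ", "),
              x$age_range[1], x$age_range[2]))
  cat(sprintf("  effect fractions: MCI-s %.2f, MCI-p %.2f; severity SD %.2f\n",
              x$fraction["mci_s"], x$fraction["mci_p"], x$severity_sd))
  cat(sprintf("  %d features; seed %d\n", nrow(x$manifest), x$seed))
  invisible(x)
}

rnorm_trunc <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

#' Generate a synthetic cohort
#'
#' Draws a cohort from a [cohort_config()].  Feature `j` of subject `i` is
#' `baseline_j + age_slope_j * (age_i - reference_age) + s_i * effect_j *
#' sd_j + noise`, where `s_i` is the subject's latent disease severity
#' (0 for controls) and the noise has marginal SD `sd_j` with a shared
#' component across features.  MCI progression labels: group membership
#' defines month-12 status; by months 18/24/36 the configured cumulative
#' fraction of MCI-s subjects with the highest latent severity have
#' progressed; follow-up beyond month 12 is only available for the ADNI
#' sub-cohort (other subjects are `unknown` at later months).
#'
#' Deterministic given `seed`; the caller's RNG state is left untouched.
#'
#' @param config a `cohort_config`.
#' @param seed RNG seed (defaults to `config$seed`).
#' @return a [cohort_table()] with `attr(, "severity")` holding the latent
#'   severity of each subject (useful for diagnostics).
#' @export
#' @examples
#' cfg <- cohort_config(n = c(40, 30, 10, 35))
#' coh <- simulate_cohort(cfg, seed = 7)
#' table(coh$diagnosis)
simulate_cohort <- function(config, seed = config$seed) {
  validate_config(config)
  with_seed(seed, {
    manifest <- config$manifest
    p <- nrow(manifest)
    lambda <- config$shared_noise_frac
    dir <- ifelse(config$age_slope >= 0, 1, -1)
    rows <- list()
    sever <- list()
    sid <- 0L
    for (g in .sim_groups) {
      n <- config$n[[g]]
      if (n == 0L) next
      age <- rnorm_trunc(n, config$age_mean[[g]], config$age_sd[[g]],
                         config$age_range[1], config$age_range[2])
      h <- pmax(0, stats::rnorm(n, 1, config$severity_sd))
      s <- config$fraction[[g]] * h
      if (config$fraction[[g]] == 0) s[] <- 0
      gfac <- stats::rnorm(n)
      eps <- matrix(stats::rnorm(n * p), n, p)
      X <- matrix(config$baseline, n, p, byrow = TRUE) +
        outer(age - config$reference_age, config$age_slope) +
        outer(s, config$effect_ad * config$residual_sd) +
        (sqrt(lambda) * outer(gfac, dir) + sqrt(1 - lambda) * eps) *
          matrix(config$residual_sd, n, p, byrow = TRUE)
      colnames(X) <- manifest$name
      diagnosis <- switch(g, ctl = "CTL", ad = "AD", "MCI")
      mmse <- as.integer(pmin(30, pmax(0, round(
        stats::rnorm(n, config$mmse_mean[[g]], config$mmse_sd[[g]])))))
      cdr <- switch(g,
        ctl = rep(0, n),
        ad = sample(c(0.5, 1, 2), n, replace = TRUE, prob = c(0.4, 0.5, 0.1)),
        rep(0.5, n))
      meta <- data.frame(
        subject_id = sprintf("S%04d", sid + seq_len(n)),
        diagnosis = diagnosis,
        age = age,
        sex = ifelse(stats::runif(n) < config$male_prob[[g]], "M", "F"),
        education = pmax(0, stats::rnorm(n, config$educ_mean[[g]],
                                         config$educ_sd[[g]])),
        mmse = mmse,
        cdr = cdr,
        apoe4 = ifelse(stats::runif(n) < config$apoe4_prob[[g]],
                       "positive", "negative"),
        cohort = ifelse(stats::runif(n) < config$adni_prob[[g]], "ADNI", "ANM"),
        stringsAsFactors = FALSE)
      for (m in progression_months()) meta[[prog_col(m)]] <- "unknown"
      if (diagnosis == "MCI") {
        meta$prog_m12 <- if (g == "mci_p") "progressed" else "stable"
        for (m in c(18L, 24L, 36L)) meta[[prog_col(m)]] <- meta$prog_m12
      }
      sid <- sid + n
      rows[[g]] <- cbind(meta, as.data.frame(X), stringsAsFactors = FALSE)
      sever[[g]] <- s
    }
    data <- do.call(rbind, rows)
    rownames(data) <- NULL
    severity <- unlist(sever, use.names = FALSE)

    # Late conversions: the most severe stable-MCI subjects progress by the
    # configured cumulative fractions.
    is_mci_s <- data$diagnosis == "MCI" & data$prog_m12 == "stable"
    n_s <- sum(is_mci_s)
    if (n_s) {
      ord <- order(severity[is_mci_s], decreasing = TRUE)
      idx <- which(is_mci_s)[ord]
      for (m in c(18L, 24L, 36L)) {
        k <- floor(config$conversion_frac[[paste0("m", m)]] * n_s)
        if (k > 0) data[[prog_col(m)]][idx[seq_len(k)]] <- "progressed"
      }
    }
    # Follow-up beyond month 12 exists only for the ADNI sub-cohort.
    late_na <- data$diagnosis == "MCI" & data$cohort != "ADNI"
    for (m in c(18L, 24L, 36L)) data[[prog_col(m)]][late_na] <- "unknown"

    out <- cohort_table(data, manifest)
    attr(out, "severity") <- severity
    out
  })
}

#' Shift a configuration into an age-confounded scenario
#'
#' Returns a copy of `config` whose AD age distribution is shifted younger
#' by `ad_age_shift` years, creating the age-diagnosis confound that the
#' correction strategies are meant to neutralize (younger AD patients show
#' less age-related atrophy and become harder to separate from controls
#' without correction).
#'
#' @param config a `cohort_config`.
#' @param ad_age_shift years to subtract from the AD group's mean age.
#' @return a `cohort_config`.
#' @export
confounded_config <- function(config, ad_age_shift) {
  config$age_mean[["ad"]] <- config$age_mean[["ad"]] - ad_age_shift
  validate_config(config)
  config
}
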