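test_that("group counts match the configuration exactly and generation is deterministic", {
  cfg <- cohort_config()
  coh <- simulate_cohort(cfg, seed = 11)
  expect_identical(sum(coh$diagnosis == "CTL"), 340L)
  expect_identical(sum(coh$diagnosis == "MCI" & coh$prog_m12 == "stable"), 360L)
  expect_identical(sum(coh$diagnosis == "MCI" & coh$prog_m12 == "progressed"), 85L)
  expect_identical(sum(coh$diagnosis == "AD"), 297L)

  again <- simulate_cohort(cfg, seed = 11)
  expect_identical(cohort_features(again), cohort_features(coh))
  expect_identical(cohort_meta(again), cohort_meta(coh))

  other <- simulate_cohort(cfg, seed = 12)
  expect_false(identical(cohort_features(other), cohort_features(coh)))
})

test_that("null disease effect leaves detrended AD-CTL differences within 4 analytic SE", {
  cfg <- cohort_config(effect_ad = rep(0, 55))
  coh <- simulate_cohort(cfg, seed = 5)
  dt <- detrend_cohort(coh)
  X <- cohort_features(dt$cohort)
  ad <- coh$diagnosis == "AD"; ctl <- coh$diagnosis == "CTL"
  # closed-form SE of a two-sample mean difference at the configured n/SD
  se <- cfg$residual_sd * sqrt(1 / sum(ad) + 1 / sum(ctl))
  diff <- colMeans(X[ad, ]) - colMeans(X[ctl, ])
  expect_true(all(abs(diff) < 4 * se))
})

test_that("per-feature age slopes are recovered from generated controls within 3 SE", {
  cfg <- cohort_config(n = c(1000, 0, 0, 0))
  coh <- simulate_cohort(cfg, seed = 9)
  X <- cohort_features(coh)
  age <- coh$age
  fit <- age_detrend(X, age)
  # per-feature OLS slope SE from the residuals
  ac <- age - mean(age)
  for (j in seq_len(ncol(X))) {
    res <- X[, j] - (fit$beta0[j] + fit$beta1[j] * age)
    se <- sqrt(sum(res^2) / (length(age) - 2) / sum(ac^2))
    expect_lt(abs(fit$beta1[j] - cfg$age_slope[j]), 3 * se)
  }
})

test_that("group feature means are monotone CTL, MCI-s, MCI-p, AD for atrophy features", {
  cfg <- cohort_config(n = c(3000, 3000, 3000, 3000))
  coh <- simulate_cohort(cfg, seed = 21)
  X <- cohort_features(coh)
  grp <- ifelse(coh$diagnosis == "MCI",
                ifelse(coh$prog_m12 == "progressed", "MCI-p", "MCI-s"),
                coh$diagnosis)
  neg <- which(cfg$effect_ad < -0.25)  # clearly negative effects
  for (j in neg) {
    m <- tapply(X[, j], grp, mean)
    expect_true(m[["CTL"]] > m[["MCI-s"]],
                label = sprintf("CTL > MCI-s for %s", colnames(X)[j]))
    expect_true(m[["MCI-s"]] > m[["MCI-p"]],
                label = sprintf("MCI-s > MCI-p for %s", colnames(X)[j]))
    expect_true(m[["MCI-p"]] > m[["AD"]],
                label = sprintf("MCI-p > AD for %s", colnames(X)[j]))
  }
})

test_that("confounded scenario shifts only the AD age distribution", {
  base <- cohort_config()
  expect_identical(confounded_config(base, 0)$age_mean, base$age_mean)
  sh <- confounded_config(base, 5)
  expect_equal(sh$age_mean[["ad"]], base$age_mean[["ad"]] - 5)
  expect_identical(sh$age_mean[c("ctl", "mci_s", "mci_p")],
                   base$age_mean[c("ctl", "mci_s", "mci_p")])
  expect_identical(sh$age_slope, base$age_slope)

  # realized AD mean age within 3 SE of the shifted target
  coh <- simulate_cohort(sh, seed = 2)
  ad_age <- coh$age[coh$diagnosis == "AD"]
  se <- base$age_sd[["ad"]] / sqrt(length(ad_age))
  expect_lt(abs(mean(ad_age) - (base$age_mean[["ad"]] - 5)), 3 * se)
})

test_that("progression labels are internally consistent and severity-ranked", {
  cfg <- cohort_config()
  coh <- simulate_cohort(cfg, seed = 3)
  mci <- cohort_subset(coh, "MCI")
  # month-12 progressors stay progressed at every later month (when known)
  p12 <- mci$prog_m12 == "progressed"
  for (m in c(18, 24, 36)) {
    st <- mci[[paste0("prog_m", m)]]
    expect_true(all(st[p12] %in% c("progressed", "unknown")))
    # conversion is cumulative: no progressed-then-stable
    if (m > 18) {
      prev <- mci[[paste0("prog_m", m - 6)]]
      expect_false(any(prev == "progressed" & st == "stable"))
    }
  }
  # non-ADNI subjects have no follow-up beyond month 12
  anm <- mci$cohort == "ANM"
  for (m in c(18, 24, 36))
    expect_true(all(mci[[paste0("prog_m", m)]][anm] == "unknown"))
  # non-MCI subjects carry no progression status
  expect_true(all(coh$prog_m12[coh$diagnosis != "MCI"] == "unknown"))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(mci_s_fraction = 0.8, mci_p_fraction = 0.5), "fraction")
  expect_error(cohort_config(n = c(-1, 0, 0, 10)), "non-negative")
  expect_error(cohort_config(residual_sd = rep(0, 55)), "residual_sd")
  expect_error(cohort_config(shared_noise_frac = 1.2), "shared_noise_frac")
})
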