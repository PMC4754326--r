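test_that("chi-squared and t statistics match textbook closed forms", {
  # 2x2 chi-squared without continuity correction, closed form
  # n (ad - bc)^2 / (r1 r2 c1 c2)
  a <- 26; b <- 5; c <- 24; d <- 29
  n <- a + b + c + d
  chi_hand <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  ct <- chisq.test(matrix(c(a, c, b, d), 2), correct = FALSE)
  expect_lt(abs(unname(ct$statistic) - chi_hand), 1e-10)

  # pooled-variance t from summaries vs direct formula
  res <- t_test_summary(309, 74.5, 5.6, 31, 79.1, 5.2)
  sp2 <- (308 * 5.6^2 + 30 * 5.2^2) / 338
  t_hand <- (74.5 - 79.1) / sqrt(sp2 * (1 / 309 + 1 / 31))
  expect_lt(abs(res$statistic - t_hand), 1e-10)
  expect_identical(res$df, 338)

  # t_test_summary agrees with t.test(var.equal) on raw data
  set.seed(12)
  x <- rnorm(20, 1); y <- rnorm(15, 0.2)
  tt <- t.test(x, y, var.equal = TRUE)
  ts <- t_test_summary(20, mean(x), sd(x), 15, mean(y), sd(y))
  expect_equal(ts$p_value, tt$p.value, tolerance = 1e-12)
})

test_that("identical subgroups give t = 0, p = 1", {
  x <- c(70, 75, 80, 85)
  tt <- t.test(x, x, var.equal = TRUE)
  expect_equal(unname(tt$statistic), 0)
  expect_equal(tt$p.value, 1)
  ts <- t_test_summary(4, mean(x), sd(x), 4, mean(x), sd(x))
  expect_equal(ts$statistic, 0)
  expect_equal(ts$p_value, 1)
})

test_that("compare_subgroups builds the three comparisons with the right tests", {
  coh <- simulate_cohort(small_config(), seed = 301)
  adctl <- cohort_subset(coh, c("CTL", "AD"))
  set.seed(1)
  correct <- runif(nrow(adctl)) < 0.85
  tab <- compare_subgroups(adctl, correct)
  expect_s3_class(tab, "comparison_table")
  expect_identical(length(unique(tab$comparison)), 3L)
  expect_identical(unique(tab$test[tab$variable %in% c("age", "education", "mmse")]), "t")
  expect_identical(unique(tab$test[tab$variable %in% c("sex", "apoe4", "cohort")]), "chisq")
  expect_true(all(tab$n1 + tab$n2 <= nrow(adctl)))

  # cross-check one continuous row against a direct t test
  ctl <- adctl$diagnosis == "CTL"
  tt <- t.test(adctl$age[ctl & correct], adctl$age[ctl & !correct],
               var.equal = TRUE)
  row <- tab[tab$comparison == "CTL: correct vs incorrect" & tab$variable == "age", ]
  expect_equal(row$p_value, tt$p.value, tolerance = 1e-12)

  # cross-check one categorical row against a direct chi-squared
  sex_tab <- table(correct[ctl], adctl$sex[ctl])
  cs <- suppressWarnings(chisq.test(sex_tab, correct = FALSE))
  srow <- tab[tab$comparison == "CTL: correct vs incorrect" & tab$variable == "sex", ]
  expect_equal(srow$p_value, cs$p.value, tolerance = 1e-12)
})

test_that("unknown levels are dropped per variable and empty subgroups are marked", {
  coh <- simulate_cohort(small_config(), seed = 302)
  adctl <- cohort_subset(coh, c("CTL", "AD"))
  data <- as.data.frame(unclass(adctl), stringsAsFactors = FALSE)
  data$apoe4[1:10] <- "unknown"
  adctl <- cohort_table(data, cohort_manifest(coh))
  correct <- rep(TRUE, nrow(adctl)); correct[1:8] <- FALSE
  tab <- compare_subgroups(adctl, correct)
  arow <- tab[tab$variable == "apoe4" & grepl("^CTL", tab$comparison), ]
  expect_lte(arow$n1 + arow$n2, sum(adctl$diagnosis == "CTL"))

  # all-correct CTL: within-CTL comparison not computable, no crash
  all_right <- rep(TRUE, nrow(adctl))
  all_right[adctl$diagnosis == "AD"][1:5] <- FALSE
  tab2 <- compare_subgroups(adctl, all_right)
  ctl_rows <- tab2[grepl("^CTL", tab2$comparison), ]
  expect_true(all(nzchar(ctl_rows$note)))
  expect_true(all(is.na(ctl_rows$p_value)))
})

test_that("age correlations vanish after detrending but persist before", {
  cfg <- cohort_config(n = c(1000, 0, 0, 300))
  coh <- simulate_cohort(cfg, seed = 303)
  dt <- detrend_cohort(coh)
  tab <- age_correlation_table(coh, dt$cohort)
  ctl <- tab[tab$group == "CTL", ]
  expect_true(all(abs(ctl$r_after) < 0.05))
  # before correction, correlations match the analytic value implied by
  # the generating slope: r = b1 sd(age) / sqrt(b1^2 var(age) + sd_x^2)
  sd_age <- sd(coh$age[coh$diagnosis == "CTL"])
  r_pred <- cfg$age_slope * sd_age /
    sqrt(cfg$age_slope^2 * sd_age^2 + cfg$residual_sd^2)
  expect_true(all(abs(ctl$r_before - r_pred) < 0.1))
  expect_gt(median(abs(ctl$r_before)), 0.15)

  # removing the fitted line zeroes the correlation exactly (OLS
  # orthogonality of residuals and regressor)
  set.seed(9)
  n <- 200
  age <- runif(n, 60, 90)
  noisy <- cbind(f = 10 - 0.1 * age + rnorm(n))
  fitx <- age_detrend(noisy, age)
  corr <- apply_detrend(fitx, noisy, age)
  expect_lt(abs(cor(corr[, 1], age)), 1e-10)

  # a feature with zero generating slope keeps its (null) correlation
  cfg0 <- cohort_config(n = c(1000, 0, 0, 0))
  cfg0$age_slope[10] <- 0
  coh0 <- simulate_cohort(cfg0, seed = 304)
  dt0 <- detrend_cohort(coh0)
  tab0 <- age_correlation_table(coh0, dt0$cohort)
  r10 <- tab0[tab0$feature == cohort_manifest(coh0)$name[10], ]
  expect_lt(abs(r10$r_before - r10$r_after), 0.05)

  # groups with fewer than 3 subjects are marked undefined
  tiny <- coh[c(1, 2, 1001), ]
  tiny_dt <- detrend_cohort(tiny, model = dt$model)
  ttab <- age_correlation_table(tiny, tiny_dt$cohort)
  expect_true(all(is.na(ttab$r_before[ttab$group == "CTL"])))
})

test_that("comparison tables export to CSV", {
  coh <- simulate_cohort(small_config(), seed = 305)
  adctl <- cohort_subset(coh, c("CTL", "AD"))
  set.seed(2)
  tab <- compare_subgroups(adctl, runif(nrow(adctl)) < 0.8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_comparison(tab, path)
  back <- utils::read.csv(path)
  expect_identical(nrow(back), nrow(tab))
  expect_output(print(tab), "correct vs incorrect")
})
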