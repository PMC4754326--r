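test_that("stratified folds are balanced overall and per class, and deterministic", {
  f <- make_folds(14, 7, labels = rep(0:1, 7), seed = 1)
  expect_identical(sort(unique(f)), 1:7)
  expect_true(all(table(f) == 2))

  labels <- rep(c(0, 1), c(340, 297))
  f2 <- make_folds(637, 7, labels = labels, seed = 4)
  expect_true(all(table(f2) == 91))
  per_class <- table(f2, labels)
  expect_true(all(apply(per_class, 2, function(x) diff(range(x))) <= 1))

  expect_identical(make_folds(50, 7, labels = rep(0:1, 25), seed = 9),
                   make_folds(50, 7, labels = rep(0:1, 25), seed = 9))
  expect_warning(make_folds(20, 7, labels = rep(c(0, 1), c(17, 3)), seed = 1),
                 "unstratified")
})

test_that("Q2 equals an independent brute-force per-fold refit loop", {
  cfg <- small_config()
  coh <- simulate_cohort(cfg, seed = 41)
  keep <- coh$diagnosis %in% c("AD", "CTL")
  sub <- coh[keep, ]
  X <- cohort_features(sub, type = "volume")
  y <- as.numeric(sub$diagnosis == "AD")

  for (corr in c("none", "detrend")) {
    cv <- cv_opls(X, y, n_ortho = 1, correction = corr, ages = sub$age,
                  k = 7, seed = 5)
    # explicit re-implementation of the loop, outside the pipeline
    yhat <- rep(NA_real_, length(y))
    for (f in 1:7) {
      tr <- cv$folds != f; te <- !tr
      Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
      if (corr == "detrend") {
        ctl <- tr & y == 0
        dt <- age_detrend(X[ctl, , drop = FALSE], sub$age[ctl])
        Xtr <- apply_detrend(dt, Xtr, sub$age[tr])
        Xte <- apply_detrend(dt, Xte, sub$age[te])
      }
      sc <- fit_scaling(Xtr)
      fit <- opls(apply_scaling(sc, Xtr), y[tr], 1)
      yhat[te] <- predict(fit, apply_scaling(sc, Xte), scale = FALSE)
    }
    q2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
    expect_lt(abs(cv$q2 - q2), 1e-10)
    expect_equal(cv$yhat_cv, yhat, tolerance = 1e-12)
  }
})

test_that("permuted labels destroy Q2 on informative data", {
  cfg <- small_config()
  coh <- simulate_cohort(cfg, seed = 42)
  keep <- coh$diagnosis %in% c("AD", "CTL")
  sub <- coh[keep, ]
  X <- cohort_features(sub, type = "thickness")
  y <- as.numeric(sub$diagnosis == "AD")
  expect_gt(cv_opls(X, y, 0, k = 7, seed = 1)$q2, 0.2)

  set.seed(99)
  q2s <- replicate(20, cv_opls(X, sample(y), 0, k = 7, seed = 1)$q2)
  expect_lt(mean(q2s), 0.05)
})

test_that("Q2 is invariant to row order given the same fold assignment", {
  cfg <- small_config()
  coh <- simulate_cohort(cfg, seed = 43)
  keep <- coh$diagnosis %in% c("AD", "CTL")
  sub <- coh[keep, ]
  X <- cohort_features(sub, type = "volume")
  y <- as.numeric(sub$diagnosis == "AD")
  folds <- make_folds(nrow(X), 7, labels = y, seed = 2)
  cv1 <- cv_opls(X, y, 1, folds = folds)
  perm <- sample(nrow(X))
  cv2 <- cv_opls(X[perm, ], y[perm], 1, folds = folds[perm])
  expect_equal(cv2$q2, cv1$q2, tolerance = 1e-10)
  expect_equal(cv2$yhat_cv, cv1$yhat_cv[perm], tolerance = 1e-10)
})

test_that("Q2 never exceeds the full-refit R2 on shipped fixtures", {
  for (s in 1:3) {
    coh <- simulate_cohort(small_config(), seed = 50 + s)
    keep <- coh$diagnosis %in% c("AD", "CTL")
    sub <- coh[keep, ]
    X <- cohort_features(sub, type = "volume")
    y <- as.numeric(sub$diagnosis == "AD")
    cv <- cv_opls(X, y, 1, k = 7, seed = s)
    expect_lte(cv$q2, cv$r2)
  }
})

test_that("select_n_ortho applies the parsimony rule", {
  # y generated from a single latent direction: nothing to gain from
  # orthogonal components
  set.seed(71)
  n <- 120
  t_lat <- rnorm(n)
  X <- outer(t_lat, runif(8, 0.5, 1)) + matrix(rnorm(n * 8, sd = 0.3), n, 8)
  colnames(X) <- paste0("v", 1:8)
  y <- as.numeric(t_lat > 0)
  expect_identical(as.integer(select_n_ortho(X, y, k = 7, seed = 1, max_ortho = 3)), 0L)

  # a strong y-orthogonal nuisance direction: at least one component helps
  nuis <- rnorm(n)
  Xn <- X + outer(nuis, c(8, -6, 7, -8, 6, -7, 8, -6))
  colnames(Xn) <- paste0("v", 1:8)
  expect_gte(as.integer(select_n_ortho(Xn, y, k = 7, seed = 1, max_ortho = 3)), 1L)

  # infinite tolerance always returns the most parsimonious model
  expect_identical(as.integer(select_n_ortho(Xn, y, k = 7, seed = 1,
                                             max_ortho = 3, tol = Inf)), 0L)
})

test_that("cross-validated scores export to CSV with a JSON metrics block", {
  coh <- simulate_cohort(small_config(), seed = 60)
  keep <- coh$diagnosis %in% c("AD", "CTL")
  sub <- coh[keep, ]
  cv <- cv_opls(cohort_features(sub, type = "volume"),
                as.numeric(sub$diagnosis == "AD"), 0, k = 7, seed = 3)
  sp <- withr::local_tempfile(fileext = ".csv")
  mp <- withr::local_tempfile(fileext = ".json")
  write_cv_result(cv, sp, mp, subject_id = sub$subject_id)
  back <- utils::read.csv(sp)
  expect_identical(nrow(back), nrow(sub))
  met <- jsonlite::fromJSON(mp)
  expect_equal(met$q2, cv$q2)
  expect_identical(met$n_ortho, 0L)
})
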