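test_that("OPLS with no orthogonal components matches single-component PLS", {
  d <- random_classed(24, 6, seed = 101)
  fit <- opls(d$X, d$y, n_ortho = 0)
  oracle <- pls1_nipals(d$X, d$y, 1)
  expect_lt(max(abs(fitted(fit) - oracle$fitted)), 1e-10)
})

test_that("OPLS with k orthogonal components matches (1+k)-component NIPALS PLS", {
  for (seed in 1:10) {
    n <- sample(20:60, 1)
    p <- sample(5:15, 1)
    d <- random_classed(n, p, seed = 300 + seed)
    for (k in 1:2) {
      fit <- opls(d$X, d$y, n_ortho = k)
      oracle <- pls1_nipals(d$X, d$y, 1 + k)
      expect_lt(max(abs(fitted(fit) - oracle$fitted)), 1e-8)
    }
  }
})

test_that("the defining orthogonality invariants hold", {
  d <- random_classed(30, 8, seed = 55)
  fit <- opls(d$X, d$y, n_ortho = 3)
  expect_lt(abs(sum(fit$w^2) - 1), 1e-10)
  for (i in seq_len(fit$n_ortho)) {
    expect_lt(abs(sum(fit$ortho$w[, i]^2) - 1), 1e-10)
    expect_lt(abs(sum(fit$w * fit$ortho$w[, i])), 1e-10)
    # predictive scores orthogonal to orthogonal scores
    expect_lt(abs(sum(fit$scores * fit$ortho_scores[, i])), 1e-8)
    # orthogonal scores uncorrelated with the response
    yc <- d$y - mean(d$y)
    expect_lt(abs(sum(yc * fit$ortho_scores[, i])), 1e-8)
  }
})

test_that("a perfectly explained response gives R2 = 1 and errors are raised for degenerate input", {
  set.seed(77)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  X <- scale(X, center = TRUE, scale = FALSE)
  y <- as.numeric(X[, 1] > 0)
  # y exactly proportional to column a, and b orthogonal to y so the
  # predictive weight lands exactly on a
  yc <- y - mean(y)
  X[, "a"] <- yc
  X[, "b"] <- X[, "b"] - yc * sum(X[, "b"] * yc) / sum(yc^2)
  fit <- opls(X, y, n_ortho = 0)
  expect_lt(abs(fit$r2 - 1), 1e-10)

  expect_error(opls(X, rep(1, 20), 0), "both classes")
  expect_error(opls(X, y, n_ortho = 10), "rank|orthogonal")
})

test_that("prediction semantics: training rows, grand mean, and class means behave as documented", {
  cfg <- cohort_config(n = c(80, 0, 0, 80), severity_sd = 0)
  coh <- simulate_cohort(cfg, seed = 19)
  X <- cohort_features(coh)
  y <- as.numeric(coh$diagnosis == "AD")
  sc <- fit_scaling(X)
  Z <- apply_scaling(sc, X)
  fit <- opls(Z, y, n_ortho = 1, scaling = sc)

  # training rows: predict == fitted
  expect_equal(predict(fit, Z, scale = FALSE), fitted(fit), tolerance = 1e-12)
  # a row at the grand training mean scores the class prevalence
  gm <- matrix(colMeans(X), 1, dimnames = list(NULL, colnames(X)))
  expect_lt(abs(predict(fit, gm) - mean(y)), 1e-8)
  # a row at the AD training mean is AD-like on separable data
  adm <- matrix(colMeans(X[y == 1, ]), 1, dimnames = list(NULL, colnames(X)))
  expect_gt(predict(fit, adm), 0.5)
  # AD class scores higher on average (sign convention)
  expect_gt(mean(fit$scores[y == 1]), mean(fit$scores[y == 0]))
})

test_that("predictions are invariant to column permutation", {
  d <- random_classed(30, 7, seed = 66)
  fit <- opls(d$X, d$y, n_ortho = 2)
  perm <- sample(ncol(d$X))
  fit_p <- opls(d$X[, perm], d$y, n_ortho = 2)
  expect_equal(fitted(fit_p), fitted(fit), tolerance = 1e-10)
  expect_equal(unname(coef(fit_p)[colnames(d$X)]), unname(coef(fit)),
               tolerance = 1e-10)
})

test_that("r2 matches direct arithmetic and degenerate responses error", {
  d <- random_classed(26, 5, seed = 88)
  fit <- opls(d$X, d$y, n_ortho = 1)
  yhat <- predict(fit, d$X, scale = FALSE)
  expect_equal(opls_r2(fit, d$X, d$y)$r2,
               1 - sum((d$y - yhat)^2) / sum((d$y - mean(d$y))^2),
               tolerance = 1e-12)
  expect_error(opls_r2(fit, d$X, rep(1, 26)), "variance")
})

test_that("OPLS models round-trip through JSON with identical predictions", {
  cfg <- small_config()
  coh <- simulate_cohort(cfg, seed = 23)
  X <- cohort_features(coh, type = "volume")
  y <- as.numeric(coh$diagnosis == "AD")
  keep <- coh$diagnosis %in% c("AD", "CTL")
  sc <- fit_scaling(X[keep, ])
  fit <- opls(apply_scaling(sc, X[keep, ]), y[keep], n_ortho = 2, scaling = sc)
  path <- withr::local_tempfile(fileext = ".json")
  opls_to_json(fit, path)
  back <- opls_from_json(path)
  expect_equal(predict(back, X[keep, ]), predict(fit, X[keep, ]),
               tolerance = 1e-12)
})
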