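# Independent oracles and small fixtures used across the suite.

# Single-response NIPALS PLS, written independently of the package's OPLS
# code path.  With A components its training predictions coincide with
# OPLS using A-1 orthogonal components.
pls1_nipals <- function(X, y, ncomp) {
  X <- as.matrix(X)
  ybar <- mean(y)
  yc <- y - ybar
  Xd <- X
  Tm <- matrix(0, nrow(X), ncomp)
  cs <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- as.numeric(crossprod(Xd, yc))
    w <- w / sqrt(sum(w^2))
    t <- as.numeric(Xd %*% w)
    p <- as.numeric(crossprod(Xd, t)) / sum(t^2)
    cs[a] <- sum(yc * t) / sum(t^2)
    Xd <- Xd - tcrossprod(t, p)
    yc <- yc - cs[a] * t
    Tm[, a] <- t
  }
  list(fitted = ybar + as.numeric(Tm %*% cs))
}

# random two-class matrix with modest signal in the first column
random_classed <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("v", seq_len(p))))
  y <- rep(0:1, length.out = n)
  X[, 1] <- X[, 1] + y
  X <- scale(X, center = TRUE, scale = FALSE)
  attr(X, "scaled:center") <- NULL
  list(X = X, y = y)
}

# small cohort configuration that keeps unit tests fast
small_config <- function(...) {
  cohort_config(n = c(60, 40, 14, 55), ...)
}

# tiny cohort data frame built by hand (3 subjects) for I/O tests
tiny_cohort_df <- function(manifest = default_manifest()) {
  n <- 3
  set.seed(42)
  meta <- data.frame(
    subject_id = c("A1", "B2", "C3"),
    diagnosis = c("CTL", "MCI", "AD"),
    age = c(71.25, 76.5, 80.125),
    sex = c("F", "M", "M"),
    education = c(16, 12.5, 10),
    mmse = c(30L, 27L, 21L),
    cdr = c(0, 0.5, 1),
    apoe4 = c("negative", "positive", "unknown"),
    cohort = c("ADNI", "ANM", "ADNI"),
    prog_m12 = c("unknown", "stable", "unknown"),
    prog_m18 = c("unknown", "progressed", "unknown"),
    prog_m24 = c("unknown", "progressed", "unknown"),
    prog_m36 = c("unknown", "unknown", "unknown"),
    stringsAsFactors = FALSE)
  feats <- matrix(rnorm(n * nrow(manifest), mean = 5, sd = 2),
                  n, nrow(manifest), dimnames = list(NULL, manifest$name))
  cbind(meta, as.data.frame(feats), stringsAsFactors = FALSE)
}
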