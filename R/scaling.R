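# Unit-variance scaling: mean-centering and division by the sample SD,
# fit on training data and applied unchanged to unseen rows.

#' Fit mean-centering / unit-variance scaling parameters
#'
#' @param X numeric matrix with column names, at least two rows.
#' @return an object of class `uv_scaling` with per-column `mean` and
#'   sample SD `sd` (n-1 denominator).
#' @export
#' @examples
#' sc <- fit_scaling(cbind(a = c(0, 2), b = c(1, 3)))
#' sc$sd  # sqrt(2) for both columns
fit_scaling <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop_schema("scaling requires at least 2 rows")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  m <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  if (any(s == 0))
    stop_schema("degenerate feature(s) with zero variance: %s",
                paste(colnames(X)[s == 0], collapse = ", "))
  structure(list(mean = m, sd = s, columns = colnames(X)),
            class = "uv_scaling")
}

#' Apply fitted scaling to a matrix
#'
#' Computes `(x - mean) / sd` columnwise with the training-set parameters;
#' unseen data is scaled with the parameters unchanged.
#'
#' @param params a `uv_scaling` object from [fit_scaling()].
#' @param X matrix whose columns match `params`.
#' @return the scaled matrix.
#' @export
apply_scaling <- function(params, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X)) && ncol(X) == length(params$columns))
    colnames(X) <- params$columns
  if (!identical(colnames(X), params$columns))
    stop_schema("columns do not match the fitted scaling parameters")
  sweep(sweep(X, 2, params$mean, "-"), 2, params$sd, "/")
}

#' @export
print.uv_scaling <- function(x, ...) {
  cat(sprintf("UV scaling for %d columns (sample SD, n-1)\n", length(x$mean)))
  invisible(x)
}
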