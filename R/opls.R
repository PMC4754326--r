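# Two-class OPLS discriminant engine.
#
# Orthogonal projections to latent structures splits the systematic
# variation of the descriptor matrix into one predictive component
# (correlated with the 0/1 class response) and a chosen number of
# Y-orthogonal components.  For a single response, all steps are
# closed-form; there is no iteration or random initialization.
#
# Fit, with X column-centred (UV-scaled) and y in {0, 1}:
#   w  = X'yc / ||X'yc||                       (yc = y - mean(y))
#   repeat for each orthogonal component:
#     t   = X w
#     p   = X't / (t't)
#     w_o = (p - (w'p) w) normalized
#     t_o = X w_o;  p_o = X't_o / (t_o't_o)
#     X  <- X - t_o p_o'                        (deflation)
#   t = X w;  c = yc't / (t't)
# Predicted response for a row x: mean(y) + c * (x_deflated . w), where
# x_deflated removes the orthogonal components with the stored (w_o, p_o).

#' Fit a two-class OPLS discriminant model
#'
#' @param X numeric matrix, already mean-centred (and typically UV-scaled;
#'   see [fit_scaling()]).  Column names required for prediction on named
#'   data.
#' @param y response coded 0 (control-like) / 1 (case-like); both classes
#'   must be present.
#' @param n_ortho number of Y-orthogonal components (`>= 0`, less than the
#'   rank of `X`).
#' @param scaling optional `uv_scaling` object; when attached, [predict.opls()]
#'   applies it to raw new data automatically.
#' @return an object of class `opls` with elements `w` (unit predictive
#'   weight), `p` (predictive loading), `c` (score-to-response regression
#'   coefficient), `intercept` (`mean(y)`), `ortho` (`w` and `p` matrices of
#'   the orthogonal components), `coefficients` (net per-column coefficients
#'   such that `yhat = intercept + X %*% coefficients`), `scores`
#'   (training predictive score `t`), `ortho_scores`, `fitted.values`, `r2`.
#'
#' The predictive weight is oriented so the class coded 1 has the higher
#' mean predictive score.
#' @seealso [predict.opls()], [cv_opls()]
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- as.numeric(X[, 1] + rnorm(20, sd = 0.5) > 0)
#' sc <- fit_scaling(X)
#' fit <- opls(apply_scaling(sc, X), y, n_ortho = 1)
#' summary(fit)
opls <- function(X, y, n_ortho = 0, scaling = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop_schema("X and y differ in length")
  if (length(unique(y)) < 2) stop_schema("both classes must be present in y")
  if (n_ortho < 0) stop_schema("n_ortho must be non-negative")
  cols <- colnames(X)
  ybar <- mean(y)
  yc <- y - ybar
  eps <- 1e-12 * max(1, sum(X^2))

  w <- as.numeric(crossprod(X, yc))
  nw <- sqrt(sum(w^2))
  if (nw < sqrt(eps)) stop_schema("response is orthogonal to X; cannot fit")
  w <- w / nw

  Wo <- Po <- matrix(0, ncol(X), 0)
  Xd <- X
  for (i in seq_len(n_ortho)) {
    t <- as.numeric(Xd %*% w)
    tt <- sum(t^2)
    if (tt < eps) stop_schema("rank exhausted before %d orthogonal components", n_ortho)
    p <- as.numeric(crossprod(Xd, t)) / tt
    wo <- p - sum(w * p) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < sqrt(eps))
      stop_schema("no orthogonal variation left for component %d (rank error)", i)
    wo <- wo / nwo
    # deterministic sign: largest-magnitude element positive
    if (wo[which.max(abs(wo))] < 0) wo <- -wo
    to <- as.numeric(Xd %*% wo)
    po <- as.numeric(crossprod(Xd, to)) / sum(to^2)
    Xd <- Xd - tcrossprod(to, po)
    Wo <- cbind(Wo, wo)
    Po <- cbind(Po, po)
  }
  t <- as.numeric(Xd %*% w)
  tt <- sum(t^2)
  if (tt < eps) stop_schema("predictive score collapsed; too many orthogonal components")
  cc <- sum(yc * t) / tt
  p_pred <- as.numeric(crossprod(Xd, t)) / tt

  # orient the predictive direction so class 1 scores higher
  if (mean(t[y == 1]) < mean(t[y == 0])) {
    w <- -w; t <- -t; cc <- -cc; p_pred <- -p_pred
  }

  # net coefficient vector: deflation is linear, so fold it into one b with
  # yhat = intercept + X b
  D <- diag(ncol(X))
  for (i in seq_len(ncol(Wo))) D <- D %*% (diag(ncol(X)) - tcrossprod(Wo[, i], Po[, i]))
  b <- cc * as.numeric(D %*% w)

  fitted <- ybar + cc * t
  ss <- sum(yc^2)
  r2 <- 1 - sum((y - fitted)^2) / ss

  structure(list(
    w = stats::setNames(w, cols), p = stats::setNames(p_pred, cols),
    c = cc, intercept = ybar,
    ortho = list(w = Wo, p = Po), n_ortho = n_ortho,
    coefficients = stats::setNames(b, cols),
    columns = cols, scaling = scaling,
    scores = t,
    ortho_scores = if (ncol(Wo)) sapply(seq_len(ncol(Wo)), function(i) {
      # recompute training orthogonal scores from the original X chain
      Xi <- X
      if (i > 1) for (j in seq_len(i - 1))
        Xi <- Xi - tcrossprod(as.numeric(Xi %*% Wo[, j]), Po[, j])
      as.numeric(Xi %*% Wo[, i])
    }) else matrix(0, nrow(X), 0),
    fitted.values = fitted, y = y, r2 = r2,
    n = nrow(X)),
    class = "opls")
}

deflate_new <- function(model, X) {
  Wo <- model$ortho$w; Po <- model$ortho$p
  for (i in seq_len(ncol(Wo)))
    X <- X - tcrossprod(as.numeric(X %*% Wo[, i]), Po[, i])
  X
}

#' Predict class scores from an OPLS model
#'
#' Removes each orthogonal component from the new rows, projects on the
#' predictive weight, and maps the score to the response scale:
#' `yhat = intercept + c * t`.  Scores are unbounded real values, typically
#' near `[0, 1]`; a score close to 1 indicates a case-like (AD-like)
#' pattern.
#'
#' @param object an `opls` fit.
#' @param newdata matrix of new rows.  If the model carries scaling
#'   parameters and `scale = TRUE`, raw data is scaled first.
#' @param type `"response"` for predicted y (default) or `"score"` for the
#'   predictive score `t`.
#' @param scale apply the attached `uv_scaling` to `newdata` first.
#' @param ... unused.
#' @return numeric vector, one value per row.
#' @export
predict.opls <- function(object, newdata, type = c("response", "score"),
                         scale = !is.null(object$scaling), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (is.null(colnames(X)) && ncol(X) == length(object$columns))
    colnames(X) <- object$columns
  if (!is.null(object$columns) && !identical(colnames(X), object$columns))
    stop_schema("columns of newdata do not match the fitted model")
  if (scale) {
    if (is.null(object$scaling)) stop_schema("model has no attached scaling")
    X <- apply_scaling(object$scaling, X)
  }
  t <- as.numeric(deflate_new(object, X) %*% object$w)
  if (type == "score") t else object$intercept + object$c * t
}

#' @export
fitted.opls <- function(object, ...) object$fitted.values

#' @export
residuals.opls <- function(object, ...) object$y - object$fitted.values

#' @export
coef.opls <- function(object, ...) object$coefficients

#' @export
print.opls <- function(x, ...) {
  cat(sprintf("OPLS discriminant model: 1 predictive + %d orthogonal component(s), %d variables, n = %d\n",
              x$n_ortho, length(x$w), x$n))
  cat(sprintf("  training R2 = %.3f\n", x$r2))
  invisible(x)
}

#' @export
summary.opls <- function(object, ...) {
  top <- sort(abs(object$w), decreasing = TRUE)
  structure(list(n = object$n, p = length(object$w),
                 n_ortho = object$n_ortho, r2 = object$r2,
                 top_weights = object$w[names(top)[seq_len(min(6, length(top)))]]),
            class = "summary.opls")
}

#' @export
print.summary.opls <- function(x, ...) {
  cat(sprintf("OPLS discriminant model (n = %d, %d variables, %d orthogonal component(s))\n",
              x$n, x$p, x$n_ortho))
  cat(sprintf("  R2 (goodness of fit): %.3f\n", x$r2))
  cat("  largest predictive weights:\n")
  for (nm in names(x$top_weights))
    cat(sprintf("    %-28s %+.3f\n", nm, x$top_weights[[nm]]))
  invisible(x)
}

#' Goodness of fit of an OPLS model on given data
#'
#' Computes `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`.
#'
#' @param model an `opls` fit.
#' @param X matrix on the same scale the model was fit on (or raw, if the
#'   model carries scaling).
#' @param y 0/1 response; must vary.
#' @return a list with element `r2`.
#' @export
opls_r2 <- function(model, X, y) {
  y <- as.numeric(y)
  if (stats::var(y) == 0) stop_schema("response has zero variance")
  yhat <- predict(model, X)
  list(r2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2))
}

#' Serialize or restore an OPLS model as JSON
#'
#' Stores weights, loadings, orthogonal components, intercept and any
#' attached scaling, sufficient for refit-free prediction.
#'
#' @param model an `opls` fit.
#' @param path JSON file path.
#' @return `opls_from_json()` returns an `opls` object whose predictions
#'   equal the original's; `opls_to_json()` returns `path` invisibly.
#' @export
opls_to_json <- function(model, path) {
  jsonlite::write_json(list(
    columns = model$columns, w = unname(model$w), p = unname(model$p),
    c = model$c, intercept = model$intercept, n_ortho = model$n_ortho,
    ortho_w = as.numeric(model$ortho$w), ortho_p = as.numeric(model$ortho$p),
    coefficients = unname(model$coefficients),
    scaling = if (!is.null(model$scaling))
      list(mean = unname(model$scaling$mean), sd = unname(model$scaling$sd),
           columns = model$scaling$columns)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname opls_to_json
#' @export
opls_from_json <- function(path) {
  o <- jsonlite::fromJSON(path)
  k <- o$n_ortho
  as_mat <- function(m) {
    if (is.null(m) || length(m) == 0 || k == 0)
      return(matrix(0, length(o$columns), 0))
    matrix(as.numeric(m), nrow = length(o$columns), ncol = k)
  }
  sc <- if (!is.null(o$scaling))
    structure(list(mean = stats::setNames(o$scaling$mean, o$scaling$columns),
                   sd = stats::setNames(o$scaling$sd, o$scaling$columns),
                   columns = o$scaling$columns), class = "uv_scaling")
  structure(list(w = stats::setNames(o$w, o$columns),
                 p = stats::setNames(o$p, o$columns),
                 c = o$c, intercept = o$intercept,
                 ortho = list(w = as_mat(o$ortho_w), p = as_mat(o$ortho_p)),
                 n_ortho = k,
                 coefficients = stats::setNames(o$coefficients, o$columns),
                 columns = o$columns, scaling = sc),
            class = "opls")
}
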