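# Linear age detrending estimated in the control group only.
#
# For each feature an ordinary least-squares line on age is fit using
# control subjects, and the slope is then used to remove age-related drift
# from every subject (controls and patients alike):
#   x' = x - beta1 * (age - reference_age)
# Anchoring at the control mean age keeps features on their natural scale
# and makes a zero slope the exact identity.  Only the control group is
# used for estimation because age-related change in patients also carries
# disease-related change.

#' Fit a per-feature linear age-detrending model on controls
#'
#' @param ctl_features numeric matrix (control subjects x features).
#' @param ctl_ages control ages in years; must vary.
#' @return an object of class `age_detrend`: per-feature `beta0`
#'   (intercept) and `beta1` (units per year), plus `reference_age`
#'   (the control mean age).
#' @seealso [apply_detrend()]
#' @export
#' @examples
#' fit <- age_detrend(cbind(hip = c(10, 8)), c(70, 80))
#' coef(fit)  # slope -0.2, intercept 24
age_detrend <- function(ctl_features, ctl_ages) {
  X <- as.matrix(ctl_features)
  age <- as.numeric(ctl_ages)
  if (nrow(X) != length(age)) stop_schema("feature rows and ages differ in length")
  if (nrow(X) < 2) stop_schema("detrending requires at least 2 control subjects")
  va <- stats::var(age)
  if (!is.finite(va) || va == 0) stop_schema("control ages have zero variance")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  ac <- age - mean(age)
  beta1 <- as.numeric(crossprod(ac, X)) / sum(ac^2)
  beta0 <- colMeans(X) - beta1 * mean(age)
  structure(list(beta0 = stats::setNames(beta0, colnames(X)),
                 beta1 = stats::setNames(beta1, colnames(X)),
                 reference_age = mean(age),
                 columns = colnames(X),
                 n_ctl = nrow(X)),
            class = "age_detrend")
}

#' Remove the control-estimated age drift from feature values
#'
#' Applies `x' = x - beta1 * (age - reference_age)` to every row, using the
#' slopes estimated on controls; patients are corrected with the same
#' coefficients.  Values stay in their original feature units.
#'
#' @param model an `age_detrend` fit.
#' @param features matrix whose columns match the fit.
#' @param ages ages in years, one per row.
#' @return the corrected matrix.
#' @export
apply_detrend <- function(model, features, ages) {
  X <- as.matrix(features)
  if (is.null(colnames(X)) && ncol(X) == length(model$columns))
    colnames(X) <- model$columns
  if (!identical(colnames(X), model$columns))
    stop_schema("columns do not match the detrending model")
  if (nrow(X) != length(ages)) stop_schema("feature rows and ages differ in length")
  X - outer(as.numeric(ages) - model$reference_age, model$beta1)
}

#' @export
predict.age_detrend <- function(object, features, ages, ...) {
  apply_detrend(object, features, ages)
}

#' @export
coef.age_detrend <- function(object, ...) {
  cbind(beta0 = object$beta0, beta1 = object$beta1)
}

#' @export
print.age_detrend <- function(x, ...) {
  cat(sprintf("Linear age detrending: %d features, fit on %d controls\n",
              length(x$beta1), x$n_ctl))
  cat(sprintf("  reference age %.2f y; slope range [%.4g, %.4g] units/y\n",
              x$reference_age, min(x$beta1), max(x$beta1)))
  invisible(x)
}

#' Serialize or restore an age-detrending model as JSON
#'
#' @param model an `age_detrend` fit.
#' @param path JSON file path.
#' @return `detrend_from_json()` returns the `age_detrend` object;
#'   `detrend_to_json()` returns `path` invisibly.
#' @export
detrend_to_json <- function(model, path) {
  jsonlite::write_json(
    list(reference_age = model$reference_age,
         n_ctl = model$n_ctl,
         features = data.frame(name = model$columns,
                               beta0 = unname(model$beta0),
                               beta1 = unname(model$beta1))),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname detrend_to_json
#' @export
detrend_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  f <- obj$features
  structure(list(beta0 = stats::setNames(f$beta0, f$name),
                 beta1 = stats::setNames(f$beta1, f$name),
                 reference_age = obj$reference_age,
                 columns = f$name,
                 n_ctl = obj$n_ctl),
            class = "age_detrend")
}
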