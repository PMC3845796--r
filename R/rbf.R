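#' Fit a Gaussian radial-basis-function regressor
#'
#' One-dimensional RBF network: a linear tail (intercept + slope, the usual
#' polynomial tail that prevents boundary droop) plus `n_centers` Gaussian
#' kernels evenly spaced over `range`, with a common width of `width_mult`
#' times the center spacing, fitted by ridge-regularized least squares (the
#' tail is not penalized). This is the smoother used to turn sampled
#' value and risk points into continuous functions of the grip reference.
#'
#' @param x predictor values (grip references, N).
#' @param y responses.
#' @param n_centers number of Gaussian centers.
#' @param range numeric length-2, the span covered by the centers.
#' @param width_mult kernel width as a multiple of the center spacing.
#' @param ridge ridge penalty on the kernel weights.
#' @param floor_zero if `TRUE`, predictions are floored at 0 (used for the
#'   risk surface, a variance that cannot be negative).
#' @return an object of class `rbf_model`.
#' @examples
#' m <- fit_rbf(1:10, sin(1:10 / 3))
#' predict(m, c(2.5, 7.5))
#' @export
fit_rbf <- function(x, y, n_centers = 20, range = c(1, 10), width_mult = 1.5,
                    ridge = 1e-6, floor_zero = FALSE) {
  stopifnot(length(x) == length(y), is.numeric(x), is.numeric(y))
  if (length(unique(x)) < 2) stop("need at least 2 distinct x values")
  centers <- seq(range[1], range[2], length.out = n_centers)
  width <- width_mult * (centers[2] - centers[1])
  xs <- (x - mean(range)) / diff(range) # scaled linear-tail coordinate
  Phi <- cbind(1, xs, exp(-outer(x, centers, "-")^2 / (2 * width^2)))
  A <- crossprod(Phi) + diag(c(0, 0, rep(ridge, n_centers)))
  weights <- drop(solve(A, crossprod(Phi, y)))
  structure(list(centers = centers, width = width, weights = weights,
                 ridge = ridge, range = range, floor_zero = floor_zero),
            class = "rbf_model")
}

#' Predict from a fitted RBF model
#'
#' @param object an [fit_rbf()] model.
#' @param newdata numeric vector of predictor values.
#' @param ... unused.
#' @return fitted values.
#' @export
predict.rbf_model <- function(object, newdata, ...) {
  z <- as.numeric(newdata)
  zs <- (z - mean(object$range)) / diff(object$range)
  Phi <- cbind(1, zs, exp(-outer(z, object$centers, "-")^2 /
                            (2 * object$width^2)))
  out <- drop(Phi %*% object$weights)
  if (object$floor_zero) out <- pmax(0, out)
  out
}

#' @export
print.rbf_model <- function(x, ...) {
  cat(sprintf(
    "Gaussian RBF model: %d centers on [%g, %g], width %.3g, ridge %g%s\n",
    length(x$centers), x$range[1], x$range[2], x$width, x$ridge,
    if (x$floor_zero) ", floored at 0" else ""))
  invisible(x)
}
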