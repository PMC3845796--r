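#' Grip-reference noise specification
#'
#' Trial-to-trial variability of the executed grip reference: the lift is
#' run at `F_Gref + nu` with `nu ~ Uniform(-nu_range, +nu_range)`. The
#' noise half-width is condition-specific (wider on slippery surfaces, in
#' proportion to the slip force).
#'
#' @param nu_range noise half-width in N (> 0).
#' @param n_samples lifts per grip-reference value (>= 2).
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(nu_range, n_samples = 2500) {
  stopifnot(nu_range > 0, n_samples >= 2)
  structure(list(nu_range = nu_range, n_samples = n_samples),
            class = "noise_spec")
}

#' Monte-Carlo estimate of value and risk at one grip reference
#'
#' Draws `n_samples` noisy references `F_Gref + nu` (clamped at 0 N, since a
#' negative grip is unphysical), simulates each lift, maps the cost through
#' `V_CE = exp(-CE)`, and returns the mean (value) and population variance
#' (risk) of `V_CE`.
#'
#' @param F_Gref grip reference in N.
#' @param noise a [noise_spec()].
#' @param cfg a [trial_config()].
#' @param seed integer seed for the noise draws.
#' @return an object of class `value_risk_estimate`: list with `F_Gref`,
#'   `V`, `h`, `n`.
#' @export
sample_value_risk <- function(F_Gref, noise, cfg, seed = 1L) {
  stopifnot(inherits(noise, "noise_spec"), inherits(cfg, "trial_config"))
  set.seed(seed)
  nu <- runif(noise$n_samples, -noise$nu_range, noise$nu_range)
  fhat <- pmax(0, F_Gref + nu)
  batch <- .lift_batch(fhat, cfg)
  vce <- exp(-batch$CE)
  v <- mean(vce)
  h <- mean((vce - v)^2) # population variance
  structure(list(F_Gref = F_Gref, V = v, h = h, n = noise$n_samples),
            class = "value_risk_estimate")
}

#' Utility parameters
#'
#' Risk preference for the utility `U = V - alpha * h`. With
#' `use_sign_variant = TRUE` the risk weight is `alpha * sign(V)`
#' (risk-averse for gains, risk-seeking for losses); since `V_CE` lies in
#' (0, 1] here, `sign(V) = +1` and the two variants coincide.
#'
#' @param alpha risk-preference weight (>= 0); larger is more risk-averse.
#' @param use_sign_variant logical.
#' @return an object of class `utility_params`.
#' @export
utility_params <- function(alpha, use_sign_variant = FALSE) {
  stopifnot(alpha >= 0)
  structure(list(alpha = alpha, use_sign_variant = use_sign_variant),
            class = "utility_params")
}

#' Utility at a grip reference
#'
#' @param F_Gref grip reference(s) in N.
#' @param V_model,h_model fitted [fit_rbf()] models for value and risk.
#' @param params a [utility_params()].
#' @return utility value(s).
#' @export
utility_of <- function(F_Gref, V_model, h_model, params) {
  stopifnot(inherits(params, "utility_params"))
  v <- predict(V_model, F_Gref)
  h <- predict(h_model, F_Gref)
  if (params$use_sign_variant) v - params$alpha * sign(v) * h
  else v - params$alpha * h
}

#' Build the value/risk surface for an experimental condition
#'
#' Estimates `V(F_Gref)` and `h(F_Gref)` by [sample_value_risk()] on an even
#' grid of grip references spanning 1-10 N, then smooths both with Gaussian
#' RBF regression ([fit_rbf()]; the risk fit is floored at 0). A master seed
#' is split into independent per-grid-point child seeds so any single
#' estimate is reproducible in isolation.
#'
#' @param condition a condition name (see [grip_condition()]) or a list as
#'   returned by it.
#' @param n_samples lifts per grid point.
#' @param grid_n number of grid points on `range`.
#' @param seed master seed.
#' @param range span of the grip-reference grid (N); also the valid domain
#'   of the fitted models.
#' @param cfg optional [trial_config()]; built from the condition if missing.
#' @return an object of class `utility_surface`: list with the condition,
#'   the sampling `grid`, raw estimates `V`, `h`, fitted `V_model`,
#'   `h_model`, the slip force, and the settings used.
#' @examples
#' \donttest{
#' us <- build_utility("ingvarsson_sandpaper", n_samples = 100, grid_n = 10)
#' utility_of(5, us$V_model, us$h_model, utility_params(0.5))
#' }
#' @export
build_utility <- function(condition, n_samples = 2500, grid_n = 25,
                          seed = 1L, range = c(1, 10), cfg = NULL) {
  if (is.character(condition)) condition <- grip_condition(condition)
  if (is.null(cfg))
    cfg <- trial_config(plant_params(condition$mass_kg, condition$mu))
  noise <- noise_spec(condition$nu_range_n, n_samples)
  grid <- seq(range[1], range[2], length.out = grid_n)
  set.seed(seed)
  child <- sample.int(.Machine$integer.max, grid_n)
  V <- h <- numeric(grid_n)
  for (i in seq_along(grid)) {
    est <- sample_value_risk(grid[i], noise, cfg, seed = child[i])
    V[i] <- est$V; h[i] <- est$h
  }
  structure(list(condition = condition, grid = grid, V = V, h = h,
                 V_model = fit_rbf(grid, V, range = range),
                 h_model = fit_rbf(grid, h, range = range, floor_zero = TRUE),
                 slip_force = slip_force(cfg$plant),
                 cfg = cfg, n_samples = n_samples, seed = seed),
            class = "utility_surface")
}

#' @export
print.utility_surface <- function(x, ...) {
  cat(sprintf("Utility surface for '%s' (M_o = %g kg, mu = %g, nu = +/-%g N)\n",
              x$condition$name, x$condition$mass_kg, x$condition$mu,
              x$condition$nu_range_n))
  cat(sprintf("  %d grid points on [%g, %g] N, %d lifts each (seed %d)\n",
              length(x$grid), min(x$grid), max(x$grid), x$n_samples, x$seed))
  cat(sprintf("  slip force %.3f N; V in [%.3f, %.3f]; max h = %.4f at %.2f N\n",
              x$slip_force, min(x$V), max(x$V), max(x$h),
              x$grid[which.max(x$h)]))
  invisible(x)
}

#' Save / load a utility surface as JSON
#'
#' Stores the grid, the raw V and h estimates, both fitted RBF models and
#' the condition, in a plain-text portable form.
#'
#' @param surface a [build_utility()] result.
#' @param path file path.
#' @return `path` invisibly (write); a `utility_surface` (read). The
#'   reloaded surface carries no `cfg`.
#' @export
write_utility_json <- function(surface, path) {
  stopifnot(inherits(surface, "utility_surface"))
  keep <- surface[c("condition", "grid", "V", "h", "slip_force",
                    "n_samples", "seed")]
  keep$V_model <- unclass(surface$V_model)
  keep$h_model <- unclass(surface$h_model)
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_utility_json
#' @export
read_utility_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$V_model <- structure(x$V_model, class = "rbf_model")
  x$h_model <- structure(x$h_model, class = "rbf_model")
  x$V_model$floor_zero <- isTRUE(x$V_model$floor_zero)
  x$h_model$floor_zero <- isTRUE(x$h_model$floor_zero)
  structure(x, class = "utility_surface")
}
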