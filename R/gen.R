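#' Go/Explore/NoGo parameters
#'
#' Gains and sensitivities of the three-regime stochastic hill-climbing
#' update
#' \deqn{\Delta F(t) = A_G\,\mathrm{logsig}(\lambda_G \delta)\,\Delta F(t-1)
#'   - A_N\,\mathrm{logsig}(\lambda_N \delta)\,\Delta F(t-1)
#'   + A_E\,\psi\,e^{-\delta^2/\sigma_E^2}}
#' with `psi ~ Uniform(-1, 1)`. The Go term continues the previous step
#' (dominant for large positive dopamine `delta`), the NoGo term reverses
#' it (large negative `delta`), and the Explore term injects noise near
#' `delta = 0`.
#'
#' @param A_G,A_N,A_E non-negative gains of the Go, NoGo, Explore terms.
#' @param lambda_G Go sensitivity (> 0).
#' @param lambda_N NoGo sensitivity (< 0).
#' @param sigma_E Explore width (> 0).
#' @return an object of class `gen_params`.
#' @export
gen_params <- function(A_G, A_N, A_E, lambda_G, lambda_N, sigma_E) {
  stopifnot(A_G >= 0, A_N >= 0, A_E >= 0, lambda_G > 0, lambda_N < 0,
            sigma_E > 0)
  structure(list(A_G = A_G, A_N = A_N, A_E = A_E, lambda_G = lambda_G,
                 lambda_N = lambda_N, sigma_E = sigma_E),
            class = "gen_params")
}

#' Dopamine condition: control, PD OFF, PD ON
#'
#' The dopamine signal (the utility gradient `delta_U`) is passed through
#' unchanged for controls, clamped from above at `delta_lim` for PD OFF
#' (fewer nigral neurons cannot produce large phasic bursts), and clamped
#' then shifted by `delta_med` for PD ON (L-Dopa raises the tonic level).
#'
#' @param label one of `"control"`, `"pd_off"`, `"pd_on"`.
#' @param delta_lim clamp ceiling (ignored for controls).
#' @param delta_med medication shift (PD ON only).
#' @param natural_range optional empirical range `[a, b]` of the
#'   unconstrained signal, used to validate `delta_lim + delta_med < b`.
#' @return an object of class `dopamine_condition`.
#' @export
dopamine_condition <- function(label = c("control", "pd_off", "pd_on"),
                               delta_lim = Inf, delta_med = 0,
                               natural_range = NULL) {
  label <- match.arg(label)
  if (!is.null(natural_range)) {
    stopifnot(length(natural_range) == 2L, natural_range[1] < natural_range[2])
    if (label != "control" && delta_lim + delta_med >= natural_range[2])
      warning("delta_lim + delta_med >= b: the clamp never binds")
  }
  if (label == "pd_on" && delta_lim + delta_med < 0)
    message("note: delta_lim + delta_med < 0; the shifted dopamine signal ",
            "is negative for every trial (perpetual NoGo/Explore regime)")
  structure(list(label = label, delta_lim = delta_lim,
                 delta_med = delta_med, natural_range = natural_range),
            class = "dopamine_condition")
}

#' Utility-gradient dopamine signal
#'
#' @param U_now,U_prev utilities at the current and previous trial.
#' @return `U_now - U_prev`.
#' @export
delta_u <- function(U_now, U_prev) {
  stopifnot(is.finite(U_now), is.finite(U_prev))
  U_now - U_prev
}

#' Apply a dopamine condition to the raw signal
#'
#' Control: identity. PD OFF: `min(delta, delta_lim)`. PD ON:
#' `min(delta, delta_lim) + delta_med` (clamp first, then shift).
#'
#' @param delta raw dopamine signal(s).
#' @param cond a [dopamine_condition()].
#' @return the transformed signal(s).
#' @examples
#' apply_condition(0.8, dopamine_condition("pd_off", delta_lim = 0.5))
#' @export
apply_condition <- function(delta, cond) {
  stopifnot(inherits(cond, "dopamine_condition"))
  switch(cond$label,
         control = delta,
         pd_off = pmin(delta, cond$delta_lim),
         pd_on = pmin(delta, cond$delta_lim) + cond$delta_med)
}

#' Logistic sigmoid
#' @param n numeric.
#' @return `1 / (1 + exp(-n))`.
#' @export
logsig <- function(n) 1 / (1 + exp(-n))

#' One Go/Explore/NoGo update
#'
#' @param dF_prev previous grip-reference step (N).
#' @param delta dopamine signal after any condition transform.
#' @param params a [gen_params()].
#' @param psi optional explore noise in `[-1, 1]`; drawn from the current
#'   RNG stream if missing.
#' @return the next step `dF` (N).
#' @export
gen_update <- function(dF_prev, delta, params, psi = NULL) {
  stopifnot(inherits(params, "gen_params"))
  if (is.null(psi)) psi <- runif(1, -1, 1)
  params$A_G * logsig(params$lambda_G * delta) * dF_prev -
    params$A_N * logsig(params$lambda_N * delta) * dF_prev +
    params$A_E * psi * exp(-delta^2 / params$sigma_E^2)
}

#' Legacy threshold-switched Go/Explore/NoGo parameters
#'
#' The earlier three-branch rule: Go repeats the previous step when the
#' value gradient exceeds `DA_hi`, NoGo reverses it below `DA_lo`, and in
#' between an Explore step of fixed magnitude `chi` and random sign is
#' taken.
#'
#' @param DA_hi upper dopamine threshold.
#' @param DA_lo lower dopamine threshold (default `-DA_hi`).
#' @param chi explore step magnitude (> 0).
#' @return an object of class `legacy_gen_params`.
#' @export
legacy_gen_params <- function(DA_hi, DA_lo = -DA_hi, chi = 0.5) {
  stopifnot(DA_lo <= DA_hi, chi > 0)
  structure(list(DA_hi = DA_hi, DA_lo = DA_lo, chi = chi),
            class = "legacy_gen_params")
}

#' Legacy threshold-switched update
#'
#' @param dF_prev previous step (N).
#' @param delta_v value gradient.
#' @param params a [legacy_gen_params()].
#' @return the next step: `+dF_prev` (Go), `-dF_prev` (NoGo), or a step of
#'   magnitude `chi` with random sign (Explore).
#' @export
gen_update_legacy <- function(dF_prev, delta_v, params) {
  stopifnot(inherits(params, "legacy_gen_params"))
  if (delta_v > params$DA_hi) dF_prev
  else if (delta_v > params$DA_lo) params$chi * sample(c(-1, 1), 1)
  else -dF_prev
}

#' Run a Go/Explore/NoGo action-selection sequence
#'
#' Iterates `F_Gref(t) = F_Gref(t-1) + dF(t)` over the utility landscape,
#' with the dopamine signal `delta_U` transformed by the condition, the
#' grip reference clipped to the utility model's valid domain, and the
#' stored step equal to the applied (post-clipping) step. One run is one
#' simulated subject. The initial reference is drawn uniformly over the
#' domain and the initial step uniformly from `[-0.5, 0.5]` N.
#'
#' @param surface a [build_utility()] (or [read_utility_json()]) surface.
#' @param params a [gen_params()].
#' @param cond a [dopamine_condition()].
#' @param alpha risk-preference weight for the utility.
#' @param n_trials number of trials (>= 2).
#' @param seed integer seed.
#' @param init optional fixed initial grip reference (N); default random.
#' @param sgf_series if `TRUE` (default), simulate a lift at each trial's
#'   reference to record the per-trial stable grip force; requires the
#'   surface to carry a `cfg` (surfaces reloaded from JSON do not).
#' @return an object of class `gen_trace`: data frame with columns `trial`,
#'   `F_Gref`, `delta_raw`, `delta_applied`, `dF`, plus attributes
#'   `terminal_SGF` (stable grip force of a lift at the final reference)
#'   and `SGF_series` when requested.
#' @export
run_gen <- function(surface, params, cond, alpha, n_trials = 50, seed = 1L,
                    init = NULL, sgf_series = TRUE) {
  stopifnot(inherits(surface, "utility_surface"),
            inherits(params, "gen_params"),
            inherits(cond, "dopamine_condition"))
  if (n_trials < 2) stop("n_trials must be at least 2")
  up <- utility_params(alpha)
  dom <- range(surface$grid)
  set.seed(seed)
  Fg <- if (is.null(init)) runif(1, dom[1], dom[2]) else init
  dF <- runif(1, -0.5, 0.5)
  U_at <- function(f) utility_of(f, surface$V_model, surface$h_model, up)
  U_prev <- U_at(Fg)
  Fs <- dr <- da <- dFs <- numeric(n_trials)
  Fs[1] <- Fg; dr[1] <- NA; da[1] <- NA; dFs[1] <- dF
  for (t in 2:n_trials) {
    Fg2 <- min(dom[2], max(dom[1], Fg + dF))
    dF_applied <- Fg2 - Fg
    U_now <- U_at(Fg2)
    d_raw <- delta_u(U_now, U_prev)
    d_app <- apply_condition(d_raw, cond)
    dF <- gen_update(dF_applied, d_app, params)
    Fg <- Fg2; U_prev <- U_now
    Fs[t] <- Fg; dr[t] <- d_raw; da[t] <- d_app; dFs[t] <- dF_applied
  }
  tr <- data.frame(trial = seq_len(n_trials), F_Gref = Fs, delta_raw = dr,
                   delta_applied = da, dF = dFs)
  class(tr) <- c("gen_trace", "data.frame")
  has_cfg <- !is.null(surface$cfg)
  if (has_cfg) {
    attr(tr, "terminal_SGF") <- simulate_lift(Fs[n_trials], surface$cfg)$SGF
    if (sgf_series)
      attr(tr, "SGF_series") <- .lift_batch(Fs, surface$cfg)$SGF
  } else {
    attr(tr, "terminal_SGF") <- Fs[n_trials]
    if (sgf_series) attr(tr, "SGF_series") <- Fs
  }
  attr(tr, "condition") <- cond$label
  attr(tr, "seed") <- seed
  tr
}
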