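#' Design the second-order grip-force controller
#'
#' Grip-force profiles of human lifts rise to a peak and settle at a steady
#' value, like the step response of an underdamped second-order system. The
#' controller is therefore specified by its peak-to-steady-state ratio `M_p`
#' and time to peak `T_p`; the overshoot fraction `f = M_p - 1` determines
#' the damping factor
#' \deqn{\zeta = \frac{-\ln f}{\sqrt{\pi^2 + \ln^2 f}}}
#' and the peak time fixes the damped natural frequency
#' \eqn{\omega_d = \pi / T_p}, whence
#' \eqn{\omega_n = \omega_d / \sqrt{1 - \zeta^2}}.
#'
#' @param M_p peak/steady-state ratio; must lie in (1, 2) for an
#'   underdamped design.
#' @param T_p time to peak in seconds.
#' @return an object of class `grip_controller_spec` with fields `omega_n`,
#'   `zeta`, `omega_d`, `M_p`, `T_p`.
#' @examples
#' design_grip_controller(M_p = 1.25, T_p = 0.530)
#' @export
design_grip_controller <- function(M_p, T_p) {
  stopifnot(is.numeric(M_p), length(M_p) == 1L,
            is.numeric(T_p), length(T_p) == 1L)
  if (M_p <= 1 || M_p >= 2)
    stop("M_p must lie in (1, 2): the design assumes an underdamped system")
  if (T_p <= 0) stop("T_p must be positive")
  f <- M_p - 1
  lf <- log(f)
  zeta <- -lf / sqrt(pi^2 + lf^2)
  omega_d <- pi / T_p
  omega_n <- omega_d / sqrt(1 - zeta^2)
  structure(list(omega_n = omega_n, zeta = zeta, omega_d = omega_d,
                 M_p = M_p, T_p = T_p),
            class = "grip_controller_spec")
}

#' @export
print.grip_controller_spec <- function(x, ...) {
  cat("Grip-force controller (underdamped second order)\n")
  cat(sprintf("  M_p = %.4g, T_p = %.4g s\n", x$M_p, x$T_p))
  cat(sprintf("  omega_n = %.4g rad/s, zeta = %.4g, omega_d = %.4g rad/s\n",
              x$omega_n, x$zeta, x$omega_d))
  invisible(x)
}

#' Grip force at time t for a step reference
#'
#' Closed-form step response of the unity-DC-gain second-order transfer
#' function scaled by the reference `F_Gref`: starts at 0, peaks at
#' `M_p * F_Gref` at `t = T_p`, and settles at `F_Gref`.
#'
#' @param F_Gref grip-force reference (step height) in N, >= 0.
#' @param spec a [design_grip_controller()] result.
#' @param t time(s) in seconds, >= 0; vectorized.
#' @return grip force(s) in N.
#' @examples
#' spec <- design_grip_controller(1.25, 0.530)
#' grip_force_response(10, spec, c(0, 0.530, 5))
#' @export
grip_force_response <- function(F_Gref, spec, t) {
  stopifnot(inherits(spec, "grip_controller_spec"))
  if (F_Gref < 0) stop("F_Gref must be non-negative")
  if (any(t < 0)) stop("t must be non-negative")
  z <- spec$zeta; wn <- spec$omega_n
  wd <- wn * sqrt(1 - z^2)
  k <- z / sqrt(1 - z^2)
  F_Gref * (1 - exp(-z * wn * t) * (cos(wd * t) + k * sin(wd * t)))
}

#' Lift-force PID controller state
#'
#' The lift-force controller is a PID on the object's position error with a
#' first-order output filter of time constant `tau_s` that forces
#' `F_L(0) = 0` (the raw PID output is non-zero at t = 0, which is not
#' physical). The filter is discretized exactly
#' (`F_L <- F_L_pid + (F_L - F_L_pid) exp(-dt / tau_s)`), so the printed
#' `tau_s` is honoured at any step size.
#'
#' The error convention used by [simulate_lift()] is `e = X_ref - X_o` with
#' positive gains, so that a positive error drives lift; this is the
#' negative-feedback orientation of the position-error loop.
#'
#' @param K_P,K_I,K_D proportional, integral, derivative gains. Defaults
#'   are the gains obtained by genetic-algorithm tuning of the lift loop
#'   under a constant 10 N grip.
#' @param tau_s output-smoothing time constant in seconds.
#' @param e0 initial error (m), used to seed the backward difference so a
#'   pre-existing constant error contributes no derivative kick.
#' @return an object of class `lift_controller_state`.
#' @export
lift_controller <- function(K_P = 6.938, K_I = 14.484, K_D = 1.387,
                            tau_s = 0.087, e0 = 0) {
  stopifnot(tau_s > 0)
  structure(list(K_P = K_P, K_I = K_I, K_D = K_D, tau_s = tau_s,
                 integral_acc = 0, prev_error = e0, F_L_pid = 0, F_L = 0),
            class = "lift_controller_state")
}

#' One PID + smoothing update of the lift-force controller
#'
#' Accumulates the integral, takes a backward-difference derivative,
#' forms `F_L_pid = K_P e + K_I integral + K_D de/dt`, and relaxes the
#' smoothed output toward it with the exact discrete solution of the
#' first-order filter.
#'
#' @param state a [lift_controller()] state.
#' @param e_L position error in m.
#' @param dt step in s.
#' @return the updated `lift_controller_state`; the smoothed lift force is
#'   in `$F_L` and the raw PID output in `$F_L_pid`.
#' @export
lift_controller_step <- function(state, e_L, dt) {
  stopifnot(inherits(state, "lift_controller_state"))
  if (dt <= 0) stop("dt must be positive")
  state$integral_acc <- state$integral_acc + e_L * dt
  d <- (e_L - state$prev_error) / dt
  state$prev_error <- e_L
  state$F_L_pid <- state$K_P * e_L + state$K_I * state$integral_acc +
    state$K_D * d
  state$F_L <- state$F_L_pid + (state$F_L - state$F_L_pid) * exp(-dt / state$tau_s)
  state
}
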