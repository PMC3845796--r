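test_that("the published design point is recovered from overshoot and peak time", {
  spec <- design_grip_controller(M_p = 1.25, T_p = 0.530)
  expect_equal(spec$zeta, 0.4, tolerance = 0.005 / 0.4)
  expect_equal(spec$omega_n, 6.4, tolerance = 0.1 / 6.4)
  expect_equal(spec$omega_d, spec$omega_n * sqrt(1 - spec$zeta^2))
})

test_that("overshoot fraction e^(-pi) yields zeta = 1/sqrt(2)", {
  spec <- design_grip_controller(M_p = 1 + exp(-pi), T_p = 0.5)
  expect_equal(spec$zeta, 1 / sqrt(2), tolerance = 1e-12)
})

test_that("design is rejected outside the underdamped overshoot window", {
  expect_error(design_grip_controller(1, 0.5), "underdamped")
  expect_error(design_grip_controller(2.1, 0.5), "underdamped")
  expect_error(design_grip_controller(1.25, -1), "T_p")
})

test_that("simulated step response round-trips the design criteria", {
  for (mp in c(1.1, 1.25, 1.6)) {
    spec <- design_grip_controller(mp, 0.4)
    t <- seq(0, 3, by = 1e-4)
    y <- grip_force_response(1, spec, t)
    expect_equal(max(y), mp, tolerance = 0.01)
    expect_equal(t[which.max(y)], 0.4, tolerance = 0.01)
  }
})

test_that("grip response starts at zero and settles at the reference", {
  spec <- design_grip_controller(1.25, 0.530)
  expect_identical(grip_force_response(10, spec, 0), 0)
  t_inf <- 10 / (spec$zeta * spec$omega_n)
  expect_equal(grip_force_response(10, spec, t_inf), 10, tolerance = 1e-3)
  expect_error(grip_force_response(-1, spec, 1), "F_Gref")
})

test_that("closed form matches direct ODE integration of the second-order system", {
  spec <- design_grip_controller(1.25, 0.530)
  # RK4 on y'' + 2 zeta wn y' + wn^2 y = wn^2 Fgref
  wn <- spec$omega_n; z <- spec$zeta; Fg <- 10
  f <- function(s) c(s[2], wn^2 * Fg - 2 * z * wn * s[2] - wn^2 * s[1])
  s <- c(0, 0); dt <- 1e-4
  for (k in 1:20000) {
    k1 <- f(s); k2 <- f(s + dt / 2 * k1); k3 <- f(s + dt / 2 * k2)
    k4 <- f(s + dt * k3)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  expect_equal(grip_force_response(Fg, spec, 2), s[1], tolerance = 1e-6 / Fg)
})

test_that("simulated peak ratio matches the closed-form overshoot for any damping", {
  t <- seq(0, 20, by = 1e-3)
  for (z in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    spec <- structure(list(omega_n = 3, zeta = z,
                           omega_d = 3 * sqrt(1 - z^2)),
                      class = "grip_controller_spec")
    peak <- max(grip_force_response(1, spec, t))
    expect_equal(peak, 1 + exp(-z * pi / sqrt(1 - z^2)), tolerance = 0.005)
  }
})

test_that("a zero-error history keeps the lift force at zero", {
  lc <- lift_controller()
  for (k in 1:50) lc <- lift_controller_step(lc, 0, 1e-3)
  expect_identical(lc$F_L, 0)
  expect_identical(lc$F_L_pid, 0)
})

test_that("constant error gives the P+I ramp filtered with time constant tau_s", {
  kp <- 2; ki <- 3; tau <- 0.05; e <- 0.1; dt <- 1e-4
  lc <- lift_controller(K_P = kp, K_I = ki, K_D = 0, tau_s = tau, e0 = e)
  n <- 5000
  for (k in seq_len(n)) lc <- lift_controller_step(lc, e, dt)
  t_end <- n * dt
  expect_equal(lc$F_L_pid, kp * e + ki * e * t_end, tolerance = 1e-10)
  # first-order lag of a ramp+step input, evaluated in closed form:
  # response = kp*e*(1-exp(-t/tau)) + ki*e*(t - tau*(1-exp(-t/tau)))
  expected <- kp * e * (1 - exp(-t_end / tau)) +
    ki * e * (t_end - tau * (1 - exp(-t_end / tau)))
  expect_equal(lc$F_L, expected, tolerance = 0.002 * abs(expected))
})

test_that("an error jump contributes K_D * dE / dt once", {
  lc <- lift_controller(K_P = 0, K_I = 0, K_D = 1.5, tau_s = 0.1, e0 = 0)
  lc <- lift_controller_step(lc, 0.02, 1e-3)
  expect_equal(lc$F_L_pid, 1.5 * 0.02 / 1e-3)
  lc <- lift_controller_step(lc, 0.02, 1e-3) # constant afterwards
  expect_identical(lc$F_L_pid, 0)
})

test_that("the output filter contracts toward the PID output and vanishes as tau -> 0", {
  lc <- lift_controller(K_P = 1, K_I = 0, K_D = 0, tau_s = 0.05)
  gap <- numeric(20)
  for (k in 1:20) {
    lc <- lift_controller_step(lc, 1, 1e-3)
    gap[k] <- abs(lc$F_L - lc$F_L_pid)
  }
  expect_true(all(diff(gap) < 0))
  lc2 <- lift_controller(K_P = 1, K_I = 0, K_D = 0, tau_s = 1e-9)
  lc2 <- lift_controller_step(lc2, 1, 1e-3)
  expect_equal(lc2$F_L, lc2$F_L_pid)
})

test_that("the PID response is linear in the error signal", {
  set.seed(3)
  e <- rnorm(100, 0, 0.05)
  run <- function(scale) {
    lc <- lift_controller(e0 = scale * e[1])
    out <- numeric(100)
    for (k in seq_along(e)) {
      lc <- lift_controller_step(lc, scale * e[k], 1e-3)
      out[k] <- lc$F_L
    }
    out
  }
  expect_equal(run(3), 3 * run(1), tolerance = 1e-12)
})
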