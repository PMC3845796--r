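test_that("the dopamine signal is the utility difference", {
  expect_identical(delta_u(0.5, 0.5), 0)
  expect_equal(delta_u(0.9, 0.7), 0.2)
  expect_equal(delta_u(0.3, 0.8), -delta_u(0.8, 0.3))
  expect_error(delta_u(NaN, 0), "finite")
})

test_that("condition transforms clamp and shift as specified", {
  ctrl <- dopamine_condition("control")
  expect_identical(apply_condition(0.8, ctrl), 0.8)
  off <- dopamine_condition("pd_off", delta_lim = 0.5)
  expect_identical(apply_condition(0.8, off), 0.5)
  expect_identical(apply_condition(0.2, off), 0.2)
  on <- suppressMessages(
    dopamine_condition("pd_on", delta_lim = -0.5, delta_med = 0.427))
  expect_equal(apply_condition(0.2, on), -0.073)
  # clamping monotonicity: pd_off <= control; pd_on = pd_off + delta_med
  d <- seq(-1, 1, by = 0.05)
  off2 <- dopamine_condition("pd_off", delta_lim = 0.3)
  on2 <- dopamine_condition("pd_on", delta_lim = 0.3, delta_med = 0.1)
  expect_true(all(apply_condition(d, off2) <= apply_condition(d, ctrl)))
  expect_equal(apply_condition(d, on2), apply_condition(d, off2) + 0.1)
})

test_that("the three regimes dominate at the expected dopamine levels", {
  p <- gen_params(1, 1, 1, lambda_G = 2, lambda_N = -2, sigma_E = 1)
  # large positive: Go keeps the step, NoGo and Explore vanish
  expect_equal(gen_update(0.7, 50, p, psi = 1), 0.7, tolerance = 1e-10)
  # large negative: pure reversal
  expect_equal(gen_update(0.7, -50, p, psi = 1), -0.7, tolerance = 1e-10)
  # at zero the deterministic parts cancel and only psi remains
  expect_equal(gen_update(0.7, 0, p, psi = 0.37), 0.37)
})

test_that("Monte-Carlo regime profiles reproduce the Go/NoGo/Explore picture", {
  p <- gen_params(1, 1, 1, lambda_G = 2, lambda_N = -2, sigma_E = 1)
  deltas <- seq(-3, 3, by = 0.5)
  go <- abs(p$A_G * logsig(p$lambda_G * deltas) * 1)
  nogo <- abs(-p$A_N * logsig(p$lambda_N * deltas) * 1)
  expect_true(all(diff(go) > 0))   # |Go| increasing in delta
  expect_true(all(diff(nogo) < 0)) # |NoGo| decreasing in delta
  set.seed(20)
  ex_var <- vapply(deltas, function(d) {
    var(replicate(400, p$A_E * runif(1, -1, 1) * exp(-d^2 / p$sigma_E^2)))
  }, numeric(1))
  expect_equal(which.max(ex_var), which(deltas == 0))
  # the decay of the explore variance follows exp(-2 delta^2 / sigma^2)
  expect_equal(ex_var[deltas == 1] / ex_var[deltas == 0], exp(-2),
               tolerance = 0.35)
})

test_that("legacy threshold rule switches Go/Explore/NoGo branches", {
  p <- legacy_gen_params(DA_hi = 0.1, chi = 0.25)
  expect_identical(gen_update_legacy(0.4, 0.1 + 1e-9, p), 0.4)
  expect_identical(gen_update_legacy(0.4, -0.1 - 1e-9, p), -0.4)
  set.seed(1)
  ex <- gen_update_legacy(0.4, 0, p)
  expect_equal(abs(ex), 0.25)
})

test_that("with no exploration the reference climbs a monotone utility", {
  us <- synthetic_surface(function(f) 0.05 * f) # strictly increasing U
  p <- gen_params(A_G = 0.9, A_N = 0.9, A_E = 0, lambda_G = 5,
                  lambda_N = -5, sigma_E = 1)
  tr <- run_gen(us, p, dopamine_condition("control"), alpha = 0,
                n_trials = 60, seed = 3, sgf_series = FALSE)
  f <- tr$F_Gref
  # after at most one initial reversal the sequence is non-decreasing
  first_up <- which(diff(f) > 0)[1]
  expect_true(all(diff(f[first_up:length(f)]) >= -1e-12))
})

test_that("a flat utility yields a bounded explore-driven random walk", {
  us <- synthetic_surface(function(f) rep(0.5, length(f)))
  p <- gen_params(1, 1, 1, lambda_G = 2, lambda_N = -2, sigma_E = 1)
  tr <- run_gen(us, p, dopamine_condition("control"), alpha = 0,
                n_trials = 300, seed = 8, sgf_series = FALSE)
  expect_true(all(tr$F_Gref >= 1 & tr$F_Gref <= 10))
  expect_gt(var(tr$F_Gref), 0) # it does move
  expect_true(all(abs(tr$delta_applied[-1]) < 1e-6))
})

test_that("traces are reproducible under a seed and record applied steps", {
  us <- synthetic_surface(function(f) 0.1 * f, function(f) 0.01 * f)
  p <- gen_params(0.5, 1.5, 0.4, 1.53, -7.18, 1)
  a <- run_gen(us, p, dopamine_condition("control"), 0.5, 40, seed = 6)
  b <- run_gen(us, p, dopamine_condition("control"), 0.5, 40, seed = 6)
  expect_identical(a$F_Gref, b$F_Gref)
  expect_equal(a$F_Gref[-1] - a$F_Gref[-40], a$dF[-1], tolerance = 1e-12)
  expect_true(all(a$F_Gref >= 1 & a$F_Gref <= 10))
  expect_error(run_gen(us, p, dopamine_condition("control"), 0.5, 1),
               "n_trials")
})

test_that("controls concentrate above the slip force on the real utility landscape", {
  us <- cached_surface("fellows", n_samples = 400, grid_n = 20)
  pars <- gen_param_table("table3", "control")
  cond <- dopamine_condition("control")
  term <- vapply(1:100, function(s) {
    tr <- run_gen(us, pars$gen, cond, pars$alpha, n_trials = 2000,
                  seed = s, sgf_series = FALSE)
    tr$F_Gref[2000]
  }, numeric(1))
  expect_gt(mean(term > us$slip_force), 0.9)
})
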