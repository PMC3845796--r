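test_that("calibration cost weights the mean error twice as much", {
  expect_identical(ce_gen(5, 5, 1, 1), 0)
  expect_identical(ce_gen(5, 4, 1, 1), 2)
  expect_identical(ce_gen(5, 4, 2, 1), 3)
})

test_that("median/Q3 and normal moments convert both ways", {
  m <- median_q3_to_moments(0, 0.6745)
  expect_equal(m$mean, 0); expect_equal(m$sd, 1)
  d <- median_q3_to_moments(5, 5)
  expect_equal(d$sd, 0)
  rt <- moments_to_median_q3(2.3, 1.7)
  back <- median_q3_to_moments(rt$median, rt$Q3)
  expect_equal(back$mean, 2.3); expect_equal(back$sd, 1.7)
  expect_error(median_q3_to_moments(3, 2), "Q3")
})

test_that("group statistics report both presentation conventions", {
  set.seed(9)
  x <- rnorm(30, 8, 1.5)
  gs <- group_stats(x)
  expect_equal(gs$mean, mean(x))
  expect_equal(gs$median, gs$mean)
  expect_equal(gs$Q3, gs$mean + 0.6745 * sqrt(gs$variance))
  expect_equal(gs$n, 30)
})

test_that("the parameter registry matches the published tables cell for cell", {
  t3c <- gen_param_table("table3", "control")
  t3p <- gen_param_table("table3", "pd_on")
  for (p in list(t3c, t3p)) {
    expect_identical(p$gen$lambda_G, 1.53)
    expect_identical(p$gen$lambda_N, -7.18)
    expect_identical(p$gen$sigma_E, 1.0)
    expect_identical(p$gen$A_G, 0.01)
    expect_identical(p$gen$A_N, 1.6)
    expect_identical(p$gen$A_E, 0.43)
  }
  expect_identical(t3c$alpha, 0.7)
  expect_identical(t3c$delta_lim, 1.0)
  expect_identical(t3c$delta_med, 0.0)
  expect_identical(t3p$alpha, 0.312)
  expect_identical(t3p$delta_lim, -0.5)
  expect_identical(t3p$delta_med, 0.427)

  for (g in c("control", "pd_off", "pd_on")) {
    p <- gen_param_table("table4", g)
    expect_identical(p$gen$lambda_G, 1.53)
    expect_identical(p$gen$lambda_N, -7.18)
    expect_identical(p$gen$sigma_E, 1.0)
    expect_identical(p$gen$A_G, 0.6)
    expect_identical(p$gen$A_N, 2.16)
    expect_identical(p$gen$A_E, 0.29)
  }
  expect_identical(gen_param_table("table4", "control")$alpha, 0.5)
  expect_identical(gen_param_table("table4", "pd_off")$alpha, 0.3)
  expect_identical(gen_param_table("table4", "pd_off")$delta_lim, 0.5)
  expect_identical(gen_param_table("table4", "pd_off")$delta_med, 0.0)
  expect_identical(gen_param_table("table4", "pd_on")$alpha, 0.3)
  expect_identical(gen_param_table("table4", "pd_on")$delta_lim, 0.5)
  expect_identical(gen_param_table("table4", "pd_on")$delta_med, 0.005)
  expect_error(gen_param_table("table3", "pd_off"), "not tabulated")
})

test_that("the genetic algorithm minimizes a sphere and keeps a monotone history", {
  cfg <- ga_config(rbind(c(-5, 5), c(-5, 5)), pop_size = 30,
                   generations = 50)
  res <- ga_optimize(function(x) sum(x^2), cfg, seed = 2)
  expect_lt(res$best_cost, 1e-2)
  expect_true(all(diff(res$history) <= 0))
  # determinism and seed sensitivity
  res2 <- ga_optimize(function(x) sum(x^2), cfg, seed = 2)
  expect_identical(res$best_params, res2$best_params)
  res3 <- ga_optimize(function(x) sum(x^2), cfg, seed = 3)
  expect_false(identical(res$history, res3$history))
  expect_true(all(diff(res3$history) <= 0))
})

test_that("elitism preserves an already optimal candidate and NaN costs are penalized", {
  cfg <- ga_config(rbind(c(0, 1)), pop_size = 8, generations = 5)
  # cost 0 on an entire sub-interval that the initial population hits
  res <- ga_optimize(function(x) max(0, x[1] - 0.9)^2, cfg, seed = 1)
  expect_identical(res$best_cost, 0)
  resn <- ga_optimize(function(x) if (x[1] < 0.5) NaN else x[1], cfg,
                      seed = 1)
  expect_gte(resn$best_cost, 0.5)
})

test_that("calibration optimizes the group-specific free parameters", {
  us <- synthetic_surface(function(f) logsig(f - 5),
                          function(f) 0.1 * exp(-(f - 5)^2))
  ctrl <- gen_param_table("table4", "control")
  target <- list(mean = 7, variance = 1)
  r_off <- calibrate_gen(us, "pd_off", target, fixed_params = ctrl,
                         runs = 3, n_trials = 10, ga = NULL, seed = 1)
  expect_identical(r_off$free, c("alpha", "delta_lim"))
  expect_length(r_off$best_params, 2)
  r_on <- calibrate_gen(us, "pd_on", target, fixed_params = ctrl,
                        runs = 3, n_trials = 10, seed = 1)
  expect_identical(r_on$free, c("alpha", "delta_lim", "delta_med"))
  expect_length(r_on$best_params, 3)
  expect_error(calibrate_gen(us, "pd_off", target), "fixed_params")
  expect_error(calibrate_gen(us, "control", list(mean = 7)), "variance")
})

test_that("calibration recovers the statistics of a known group (self-consistency)", {
  us <- synthetic_surface(function(f) logsig(2 * (f - 5)),
                          function(f) 0.1 * exp(-(f - 5)^2))
  ctrl <- gen_param_table("table4", "control")
  cond <- dopamine_condition("pd_off", delta_lim = 0.5)
  set.seed(33)
  seeds <- sample.int(1e6, 12)
  sgf <- vapply(seeds, function(s) {
    tr <- run_gen(us, ctrl$gen, cond, alpha = 0.3, n_trials = 30, seed = s,
                  sgf_series = FALSE)
    attr(tr, "terminal_SGF")
  }, numeric(1))
  target <- list(mean = mean(sgf), variance = var(sgf))
  res <- calibrate_gen(us, "pd_off", target, fixed_params = ctrl,
                       runs = 12, n_trials = 30,
                       ga = ga_config(rbind(c(0, 1), c(-1, 1)),
                                      pop_size = 10, generations = 8),
                       seed = 7)
  # the target is attainable, so the optimized cost should be near zero
  expect_lt(res$best_cost, 0.5)
})

test_that("the study driver reports group statistics and Welch comparisons", {
  us <- cached_surface("ingvarsson_sandpaper", n_samples = 120, grid_n = 12,
                       seed = 3)
  rep <- reproduce_study("ingvarsson_sandpaper", runs = 5, n_trials = 20,
                         seed = 2, surface = us)
  expect_named(rep$stats, c("control", "pd_off", "pd_on"))
  expect_named(rep$tests, c("pd_off", "pd_on"))
  expect_true(all(vapply(rep$sgf, length, 1L) == 5))
  expect_true(all(vapply(rep$tests, function(t) t$p.value, 1) >= 0))
  d <- tempfile()
  write_report(rep, d)
  expect_true(file.exists(file.path(d, "group_stats.json")))
  expect_true(file.exists(file.path(d, "sgf.csv")))
  js <- jsonlite::read_json(file.path(d, "group_stats.json"))
  expect_equal(js$stats$control$mean, rep$stats$control$mean)
})
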