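#' Calibration cost on group grip-force statistics
#'
#' Weighted squared error between simulated and experimental stable-grip-
#' force statistics, with double weight on the mean:
#' `2 (SGF_expt - SGF_sim)^2 + (sigma_expt - sigma_sim)^2`.
#'
#' @param sgf_expt_mean,sgf_sim_mean experimental / simulated mean SGF (N).
#' @param sigma_expt,sigma_sim experimental / simulated dispersion.
#' @return the cost (>= 0).
#' @examples
#' ce_gen(5, 4, 1, 1) # 2
#' @export
ce_gen <- function(sgf_expt_mean, sgf_sim_mean, sigma_expt, sigma_sim) {
  stopifnot(is.finite(c(sgf_expt_mean, sgf_sim_mean, sigma_expt, sigma_sim)))
  2 * (sgf_expt_mean - sgf_sim_mean)^2 + (sigma_expt - sigma_sim)^2
}

#' Convert median/Q3 summaries to normal moments (and back)
#'
#' Published results in median +/- Q3 form are mapped to mean and standard
#' deviation under a normality assumption: mean = median and
#' Q3 = mean + 0.6745 sd.
#'
#' @param median,Q3 reported median and third quartile (`Q3 >= median`).
#' @return `median_q3_to_moments`: list with `mean` and `sd`.
#' @examples
#' median_q3_to_moments(0, 0.6745) # mean 0, sd 1
#' @export
median_q3_to_moments <- function(median, Q3) {
  if (Q3 < median) stop("Q3 must not be below the median")
  list(mean = median, sd = (Q3 - median) / 0.6745)
}

#' @rdname median_q3_to_moments
#' @param mean,sd normal moments (`sd >= 0`).
#' @return `moments_to_median_q3`: list with `median` and `Q3`.
#' @export
moments_to_median_q3 <- function(mean, sd) {
  if (sd < 0) stop("sd must be non-negative")
  list(median = mean, Q3 = mean + 0.6745 * sd)
}

#' Group summary statistics for stable grip forces
#'
#' @param sgf numeric vector of per-subject stable grip forces (N).
#' @return an object of class `group_stats`: mean, variance, and the
#'   equivalent median/Q3 presentation.
#' @export
group_stats <- function(sgf) {
  stopifnot(is.numeric(sgf), length(sgf) >= 2)
  m <- mean(sgf); v <- var(sgf)
  mq <- moments_to_median_q3(m, sqrt(v))
  structure(list(mean = m, variance = v, median = mq$median, Q3 = mq$Q3,
                 n = length(sgf)),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("n = %d: mean %.3f N (var %.3f); median %.3f, Q3 %.3f\n",
              x$n, x$mean, x$variance, x$median, x$Q3))
  invisible(x)
}

#' Genetic-algorithm configuration
#'
#' @param pop_size population size (>= 4).
#' @param generations number of generations.
#' @param bounds numeric matrix with one row per parameter and columns
#'   `lower`, `upper`.
#' @param crossover_rate,blend_alpha blend (BLX-alpha) crossover settings.
#' @param mutation_rate per-gene Gaussian mutation probability.
#' @param mutation_sd mutation standard deviation as a fraction of each
#'   parameter's range.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(bounds, pop_size = 40, generations = 60,
                      crossover_rate = 0.9, blend_alpha = 0.5,
                      mutation_rate = 0.2, mutation_sd = 0.1) {
  bounds <- as.matrix(bounds)
  stopifnot(ncol(bounds) == 2, all(is.finite(bounds)),
            all(bounds[, 2] > bounds[, 1]), pop_size >= 4, generations >= 1)
  structure(list(bounds = bounds, pop_size = pop_size,
                 generations = generations, crossover_rate = crossover_rate,
                 blend_alpha = blend_alpha, mutation_rate = mutation_rate,
                 mutation_sd = mutation_sd),
            class = "ga_config")
}

#' Real-coded genetic-algorithm minimizer
#'
#' Tournament selection (size 2), blend crossover, Gaussian mutation and
#' single-elitism, deterministic under a fixed seed. Candidates whose cost
#' is `NaN` are assigned `+Inf`.
#'
#' @param cost_fn function taking a parameter vector, returning a scalar
#'   cost.
#' @param cfg a [ga_config()].
#' @param seed integer seed.
#' @return an object of class `calibration_result`: `best_params`,
#'   `best_cost`, and the per-generation best-cost `history`
#'   (non-increasing).
#' @export
ga_optimize <- function(cost_fn, cfg, seed = 1L) {
  stopifnot(inherits(cfg, "ga_config"))
  set.seed(seed)
  d <- nrow(cfg$bounds)
  lo <- cfg$bounds[, 1]; hi <- cfg$bounds[, 2]; span <- hi - lo
  evalc <- function(x) {
    v <- cost_fn(x)
    if (!is.finite(v)) Inf else v
  }
  pop <- matrix(runif(cfg$pop_size * d, lo, hi), ncol = d, byrow = TRUE)
  cost <- apply(pop, 1, evalc)
  history <- numeric(cfg$generations)
  for (g in seq_len(cfg$generations)) {
    elite_i <- which.min(cost)
    newpop <- matrix(0, cfg$pop_size, d)
    newpop[1, ] <- pop[elite_i, ]
    for (i in 2:cfg$pop_size) {
      pick <- function() {
        c2 <- sample.int(cfg$pop_size, 2)
        pop[c2[which.min(cost[c2])], ]
      }
      p1 <- pick(); p2 <- pick()
      child <- if (runif(1) < cfg$crossover_rate) {
        # BLX-alpha: sample each gene in the expanded parental interval
        cl <- pmin(p1, p2); cu <- pmax(p1, p2)
        ext <- cfg$blend_alpha * (cu - cl)
        runif(d, cl - ext, cu + ext)
      } else p1
      mut <- runif(d) < cfg$mutation_rate
      child[mut] <- child[mut] + rnorm(sum(mut), 0, cfg$mutation_sd * span[mut])
      newpop[i, ] <- pmin(hi, pmax(lo, child))
    }
    pop <- newpop
    cost <- apply(pop, 1, evalc)
    # elitism guarantees the running best never worsens
    history[g] <- min(cost)
    if (g > 1) history[g] <- min(history[g], history[g - 1])
  }
  best <- which.min(cost)
  structure(list(best_params = pop[best, ], best_cost = cost[best],
                 history = history),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("GA calibration: best cost %.6g after %d generations\n",
              x$best_cost, length(x$history)))
  cat("  best parameters:", paste(signif(x$best_params, 4), collapse = ", "),
      "\n")
  invisible(x)
}

# group sizes used for simulated cohorts, matching the experimental ones
.group_n <- function(study, group) {
  if (study == "fellows") { if (group == "control") 12L else 16L } else 10L
}

# simulate one group: n seeded runs, one terminal SGF per run
.simulate_group <- function(surface, table, group, runs, n_trials, seeds) {
  p <- gen_param_table(table, group)
  cond <- dopamine_condition(group, delta_lim = p$delta_lim,
                             delta_med = p$delta_med)
  vapply(seq_len(runs), function(i) {
    tr <- run_gen(surface, p$gen, cond, p$alpha, n_trials = n_trials,
                  seed = seeds[i], sgf_series = FALSE)
    attr(tr, "terminal_SGF")
  }, numeric(1))
}

#' Calibrate action-selection parameters against target group statistics
#'
#' Optimizes the free parameters by [ga_optimize()] so that the simulated
#' group's SGF mean and dispersion match `target_stats` under [ce_gen()].
#' For controls the free set is the six Go/Explore/NoGo parameters plus
#' `alpha`; for PD OFF only `alpha` and `delta_lim`; for PD ON `alpha`,
#' `delta_lim` and `delta_med` (the control-calibrated gains are held
#' fixed, passed via `fixed_params`).
#'
#' Experimental bar heights are not shipped with the package; typical use
#' is self-consistency (recovering the statistics of a group simulated
#' with known parameters) or a user-supplied target.
#'
#' @param surface a [build_utility()] surface.
#' @param group `"control"`, `"pd_off"` or `"pd_on"`.
#' @param target_stats a [group_stats()] (or list with `mean` and
#'   `variance`).
#' @param fixed_params for PD groups: list with a [gen_params()] in `$gen`
#'   (the control-calibrated gains).
#' @param runs simulated subjects per cost evaluation.
#' @param n_trials trials per run.
#' @param ga a [ga_config()]; a default box is used when `NULL`.
#' @param seed integer seed (GA and simulation).
#' @return a `calibration_result`; `$best_named` holds the named parameter
#'   vector.
#' @export
calibrate_gen <- function(surface, group, target_stats, fixed_params = NULL,
                          runs = 8, n_trials = 50, ga = NULL, seed = 1L) {
  stopifnot(inherits(surface, "utility_surface"))
  if (is.null(target_stats$mean) || is.null(target_stats$variance))
    stop("target_stats must provide mean and variance")
  free <- switch(group,
                 control = c("A_G", "A_N", "A_E", "lambda_G", "lambda_N",
                             "sigma_E", "alpha"),
                 pd_off = c("alpha", "delta_lim"),
                 pd_on = c("alpha", "delta_lim", "delta_med"),
                 stop("unknown group '", group, "'"))
  if (group != "control" && is.null(fixed_params))
    stop("PD calibration needs fixed_params (control-calibrated gains)")
  if (is.null(ga)) {
    b <- rbind(A_G = c(0, 2), A_N = c(0, 3), A_E = c(0, 1),
               lambda_G = c(0.1, 10), lambda_N = c(-10, -0.1),
               sigma_E = c(0.1, 3), alpha = c(0, 1),
               delta_lim = c(-1, 1), delta_med = c(0, 1))
    ga <- ga_config(b[free, , drop = FALSE], pop_size = 20, generations = 25)
  }
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, runs)
  target_sigma <- sqrt(target_stats$variance)
  cost_fn <- function(x) {
    names(x) <- free
    if (group == "control") {
      gp <- tryCatch(gen_params(x["A_G"], x["A_N"], x["A_E"], x["lambda_G"],
                                x["lambda_N"], x["sigma_E"]),
                     error = function(e) NULL)
      if (is.null(gp)) return(Inf)
      alpha <- x["alpha"]; dlim <- 1; dmed <- 0
    } else {
      gp <- fixed_params$gen
      alpha <- x["alpha"]
      dlim <- x["delta_lim"]
      dmed <- if (group == "pd_on") x["delta_med"] else 0
    }
    cond <- dopamine_condition(group, delta_lim = dlim, delta_med = dmed)
    sgf <- vapply(seq_len(runs), function(i) {
      tr <- run_gen(surface, gp, cond, alpha, n_trials = n_trials,
                    seed = run_seeds[i], sgf_series = FALSE)
      attr(tr, "terminal_SGF")
    }, numeric(1))
    ce_gen(target_stats$mean, mean(sgf), target_sigma, sqrt(var(sgf)))
  }
  res <- suppressMessages(ga_optimize(cost_fn, ga, seed = seed))
  names(res$best_params) <- free
  res$best_named <- res$best_params
  res$free <- free
  res
}

#' Reproduce a study's group-level grip-force statistics
#'
#' End-to-end driver: builds (or accepts) the utility surface for the
#' condition, runs seeded Go/Explore/NoGo sequences for each patient group
#' with the tabulated parameters, and reports per-group statistics in both
#' mean/variance and median/Q3 form together with Welch two-sample
#' comparisons of each PD group against controls.
#'
#' @param condition condition name (see [grip_condition()]).
#' @param params_table `"table3"` or `"table4"`; chosen automatically from
#'   the condition when `NULL`.
#' @param runs simulated subjects per group; defaults to the experimental
#'   cohort sizes (12 control / 16 PD for the light-object study, 10/10
#'   for the medication study).
#' @param n_trials trials per subject.
#' @param seed master seed.
#' @param surface optional pre-built [build_utility()] surface.
#' @param n_samples,grid_n forwarded to [build_utility()] when no surface
#'   is given.
#' @return an object of class `study_report`: per-group [group_stats()],
#'   the per-run SGF values, and the Welch test results.
#' @export
reproduce_study <- function(condition, params_table = NULL, runs = NULL,
                            n_trials = 50, seed = 1L, surface = NULL,
                            n_samples = 2500, grid_n = 25) {
  cond <- grip_condition(condition)
  if (is.null(params_table))
    params_table <- if (cond$name == "fellows") "table3" else "table4"
  if (is.null(surface))
    surface <- build_utility(cond, n_samples = n_samples, grid_n = grid_n,
                             seed = seed)
  groups <- unlist(cond$groups)
  set.seed(seed + 1L)
  sgf <- stats_by <- list()
  for (g in groups) {
    ng <- if (is.null(runs)) .group_n(cond$name, g) else runs
    seeds <- sample.int(.Machine$integer.max, ng)
    sgf[[g]] <- suppressMessages(
      .simulate_group(surface, params_table, g, ng, n_trials, seeds))
    stats_by[[g]] <- group_stats(sgf[[g]])
  }
  tests <- list()
  for (g in setdiff(groups, "control"))
    tests[[g]] <- t.test(sgf[[g]], sgf[["control"]])
  structure(list(condition = cond$name, params_table = params_table,
                 surface = surface, sgf = sgf, stats = stats_by,
                 tests = tests, n_trials = n_trials, seed = seed),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report: %s (%s), %d trials/run, seed %d\n",
              x$condition, x$params_table, x$n_trials, x$seed))
  for (g in names(x$stats)) {
    cat(sprintf("  %-8s ", g)); print(x$stats[[g]])
  }
  for (g in names(x$tests))
    cat(sprintf("  control vs %s: Welch t = %.3f, p = %.4f\n",
                g, x$tests[[g]]$statistic, x$tests[[g]]$p.value))
  invisible(x)
}

#' Write a study report to JSON and CSV
#'
#' @param report a [reproduce_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly. Writes `group_stats.json` and `sgf.csv`.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(condition = report$condition,
              params_table = report$params_table,
              stats = lapply(report$stats, unclass),
              tests = lapply(report$tests, function(t)
                list(statistic = unname(t$statistic),
                     p_value = t$p.value)))
  jsonlite::write_json(out, file.path(dir, "group_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  df <- do.call(rbind, lapply(names(report$sgf), function(g)
    data.frame(group = g, run = seq_along(report$sgf[[g]]),
               SGF = report$sgf[[g]])))
  utils::write.csv(df, file.path(dir, "sgf.csv"), row.names = FALSE)
  invisible(dir)
}
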