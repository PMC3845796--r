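#' Experimental condition presets
#'
#' Object mass, friction coefficient and grip-reference noise half-width for
#' the simulated experimental setups: the light-object lift study
#' (`"fellows"`: 0.33 kg, mu = 0.44) and the two surface conditions of the
#' medication study (`"ingvarsson_silk"`: 0.3 kg, mu = 0.44;
#' `"ingvarsson_sandpaper"`: 0.3 kg, mu = 0.94). Noise is wider for the
#' slippery (low-mu) surfaces, in proportion to the slip force.
#'
#' @param name condition name; `"-"` and `"_"` are interchangeable.
#' @return a list with `name`, `mass_kg`, `mu`, `nu_range_n` and `groups`
#'   (the patient groups simulated for that setup).
#' @examples
#' grip_condition("fellows")
#' @export
grip_condition <- function(name) {
  tab <- .load_table1()
  key <- gsub("-", "_", tolower(name))
  if (!key %in% names(tab))
    stop("unknown condition '", name, "'; available: ",
         paste(names(tab), collapse = ", "))
  c(list(name = key), tab[[key]])
}

.load_table1 <- function() {
  yaml::read_yaml(system.file("extdata", "table1.yaml", package = "gripsim",
                              mustWork = TRUE))
}

#' Configuration of one grip-lift trial
#'
#' @param plant a [plant_params()] object.
#' @param grip_spec a [design_grip_controller()] spec; default is the
#'   published design point (M_p = 1.25, T_p = 530 ms).
#' @param lift_gains list with `K_P`, `K_I`, `K_D`, `tau_s`.
#' @param X_ref target lift height in m.
#' @param duration trial duration in s.
#' @param dt integration step in s (overrides the plant's).
#' @param sgf_window two times (s) bounding the steady-state averaging
#'   window for the stable grip force and the position averages.
#' @param n_fingers number of fingers each applying the controller's lift
#'   force (total lift = `n_fingers * F_L`).
#' @return an object of class `trial_config`.
#' @export
trial_config <- function(plant,
                         grip_spec = design_grip_controller(1.25, 0.530),
                         lift_gains = list(K_P = 6.938, K_I = 14.484,
                                           K_D = 1.387, tau_s = 0.087),
                         X_ref = 0.05, duration = 5, dt = plant$dt,
                         sgf_window = c(4, 5), n_fingers = 2) {
  stopifnot(inherits(plant, "plant_params"),
            inherits(grip_spec, "grip_controller_spec"),
            X_ref > 0, duration > 0, dt > 0,
            length(sgf_window) == 2L, sgf_window[1] < sgf_window[2],
            sgf_window[1] >= 0, sgf_window[2] <= duration)
  need <- c("K_P", "K_I", "K_D", "tau_s")
  if (!all(need %in% names(lift_gains)))
    stop("lift_gains must contain ", paste(need, collapse = ", "))
  structure(list(plant = plant, grip_spec = grip_spec,
                 lift_gains = lift_gains, X_ref = X_ref, duration = duration,
                 dt = dt, sgf_window = sgf_window, n_fingers = n_fingers),
            class = "trial_config")
}

#' Trial configuration for a named experimental condition
#'
#' Convenience wrapper: [grip_condition()] -> [plant_params()] ->
#' [trial_config()].
#'
#' @param name condition name, see [grip_condition()].
#' @param ... passed on to [trial_config()].
#' @return a `trial_config`.
#' @export
condition_config <- function(name, ...) {
  cond <- grip_condition(name)
  trial_config(plant_params(mass_kg = cond$mass_kg, mu = cond$mu), ...)
}

#' Lift cost of a trial
#'
#' Symmetric quadratic cost on normalized slip and position error:
#' \deqn{CE = 0.5\left(\frac{\bar X_{fin} - \bar X_o}{\bar X_{fin}}\right)^2
#'      + 0.5\left(\frac{X_{ref} - \bar X_o}{X_{ref}}\right)^2}
#' where the bars are steady-window averages. A trial in which the finger
#' never moved (`X_fin_bar = 0`) is degenerate; both penalty terms are taken
#' as saturated and `CE = 1`.
#'
#' @param X_fin_bar,X_o_bar window-averaged finger and object positions (m).
#' @param X_ref target height (m), non-zero.
#' @return the cost (dimensionless, >= 0).
#' @examples
#' lift_cost(0.05, 0.04, 0.05) # 0.04
#' @export
lift_cost <- function(X_fin_bar, X_o_bar, X_ref) {
  if (X_ref == 0) stop("X_ref must be non-zero")
  if (X_fin_bar == 0) return(1)
  0.5 * ((X_fin_bar - X_o_bar) / X_fin_bar)^2 +
    0.5 * ((X_ref - X_o_bar) / X_ref)^2
}

#' Stable grip force from a grip-force series
#'
#' Arithmetic mean of the grip force over the steady window (by default the
#' final second of a 5 s trial, where the second-order transient has decayed).
#'
#' @param F_G grip-force samples (N).
#' @param t sample times (s), same length as `F_G`.
#' @param window two times (s); samples with `t` in `(window[1], window[2]]`
#'   are averaged.
#' @return mean grip force in N.
#' @export
compute_sgf <- function(F_G, t, window = c(4, 5)) {
  stopifnot(length(F_G) == length(t), length(window) == 2L)
  sel <- t > window[1] & t <= window[2] + 1e-12
  if (!any(sel)) stop("no samples fall inside the averaging window")
  mean(F_G[sel])
}

#' Simulate one closed-loop grip-lift trial
#'
#' Runs the full loop: the grip controller turns the step reference
#' `F_Gref` into a grip-force profile, the PID lift controller drives the
#' position error `X_ref - X_o` into a per-finger lift force, and the
#' stick-slip plant advances the object and fingers. Window averages give
#' the lift cost [lift_cost()], the stable grip force and the two success
#' criteria: slip distance (`X_fin_bar - X_o_bar`) below 5 mm and position
#' error (`X_ref - X_o_bar`) below 1 mm.
#'
#' @param F_Gref grip-force reference in N (>= 0).
#' @param cfg a [trial_config()].
#' @param keep_trajectory if `TRUE`, the result carries the full per-step
#'   trajectory as a data frame.
#' @param engine `"cpp"` (compiled loop, default) or `"r"` (reference loop
#'   built on [step_plant()] / [lift_controller_step()]; slower, used for
#'   cross-checking).
#' @return an object of class `trial_result`: list with `CE`, `SGF`,
#'   `slip_dist`, `pos_err`, `X_fin_bar`, `X_o_bar`, `success`, `blown`
#'   (numerical excursion beyond 10 m, reported as a flagged failure rather
#'   than an error) and optionally `trajectory`.
#' @examples
#' cfg <- condition_config("ingvarsson_sandpaper")
#' simulate_lift(10, cfg)
#' @export
simulate_lift <- function(F_Gref, cfg, keep_trajectory = FALSE,
                          engine = c("cpp", "r")) {
  stopifnot(inherits(cfg, "trial_config"))
  engine <- match.arg(engine)
  if (!is.finite(F_Gref) || F_Gref < 0) stop("F_Gref must be finite and >= 0")
  p <- cfg$plant; gs <- cfg$grip_spec; lg <- cfg$lift_gains
  if (engine == "cpp") {
    raw <- .lift_trial_cpp(F_Gref, p$M_o, p$m_fin, p$mu, p$g, p$c_damp,
                           gs$omega_n, gs$zeta, lg$K_P, lg$K_I, lg$K_D,
                           lg$tau_s, cfg$n_fingers, cfg$X_ref, cfg$duration,
                           cfg$dt, cfg$sgf_window[1], cfg$sgf_window[2],
                           keep_trajectory)
  } else {
    raw <- .lift_trial_r(F_Gref, cfg, keep_trajectory)
  }
  .trial_result(raw, F_Gref, cfg, keep_trajectory)
}

.trial_result <- function(raw, F_Gref, cfg, keep_trajectory) {
  ce <- lift_cost(raw$xf_bar, raw$xo_bar, cfg$X_ref)
  slip <- raw$xf_bar - raw$xo_bar
  perr <- cfg$X_ref - raw$xo_bar
  blown <- raw$max_abs_x > 10
  res <- list(F_Gref = F_Gref, CE = ce, SGF = raw$sgf,
              slip_dist = slip, pos_err = perr,
              X_fin_bar = raw$xf_bar, X_o_bar = raw$xo_bar,
              success = !blown && slip < 0.005 && perr < 0.001,
              blown = blown)
  if (keep_trajectory) {
    tr <- as.data.frame(raw$trajectory)
    names(tr) <- c("t_s", "X_o", "V_o", "A_o", "X_fin", "V_fin", "A_fin",
                   "F_G", "F_L", "F_f", "F_n", "mode")
    res$trajectory <- tr
  }
  structure(res, class = "trial_result")
}

# pure-R closed loop built from the exported per-step operations
.lift_trial_r <- function(F_Gref, cfg, keep_trajectory) {
  p <- cfg$plant
  n <- round(cfg$duration / cfg$dt)
  st <- plant_state()
  lc <- lift_controller(cfg$lift_gains$K_P, cfg$lift_gains$K_I,
                        cfg$lift_gains$K_D, cfg$lift_gains$tau_s,
                        e0 = cfg$X_ref)
  pp <- p; pp$dt <- cfg$dt
  w0 <- cfg$sgf_window[1]; w1 <- cfg$sgf_window[2]
  sxf <- sxo <- sfg <- 0; nw <- 0L; maxx <- 0
  traj <- if (keep_trajectory) matrix(0, n, 12) else NULL
  for (k in seq_len(n)) {
    t <- (k - 1) * cfg$dt
    FG <- grip_force_response(F_Gref, cfg$grip_spec, t)
    e <- cfg$X_ref - st$X_o
    lc <- lift_controller_step(lc, e, cfg$dt)
    FL <- cfg$n_fingers * lc$F_L
    out <- step_plant(st, FG, FL, pp)
    st <- out$state
    tk <- k * cfg$dt
    if (tk > w0 && tk <= w1 + 1e-12) {
      sxf <- sxf + st$X_fin; sxo <- sxo + st$X_o; sfg <- sfg + FG
      nw <- nw + 1L
    }
    maxx <- max(maxx, abs(st$X_o), abs(st$X_fin))
    if (keep_trajectory)
      traj[k, ] <- c(tk, st$X_o, st$V_o, st$A_o, st$X_fin, st$V_fin,
                     st$A_fin, FG, FL, out$forces$F_f, out$forces$F_n,
                     match(st$mode, c("resting", "stick", "slip")) - 1)
  }
  out <- list(xf_bar = sxf / nw, xo_bar = sxo / nw, sgf = sfg / nw,
              max_abs_x = maxx)
  if (keep_trajectory) out$trajectory <- traj
  out
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("Grip-lift trial, F_Gref = %.3g N: %s\n", x$F_Gref,
              if (x$blown) "FAILED (numerical excursion)"
              else if (x$success) "successful lift" else "failed lift"))
  cat(sprintf("  CE = %.4g, SGF = %.4g N\n", x$CE, x$SGF))
  cat(sprintf("  slip = %.4g m, position error = %.4g m\n",
              x$slip_dist, x$pos_err))
  invisible(x)
}

#' Write a trial trajectory to a tidy CSV
#'
#' @param result a [simulate_lift()] result produced with
#'   `keep_trajectory = TRUE`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(result, path) {
  stopifnot(inherits(result, "trial_result"))
  if (is.null(result$trajectory))
    stop("result has no trajectory; rerun simulate_lift(keep_trajectory = TRUE)")
  utils::write.csv(result$trajectory, path, row.names = FALSE)
  invisible(path)
}

# vectorized batch of trial summaries (compiled); used by the Monte-Carlo
# value/risk estimator where thousands of lifts are needed
.lift_batch <- function(F_Grefs, cfg) {
  p <- cfg$plant; gs <- cfg$grip_spec; lg <- cfg$lift_gains
  raw <- .lift_batch_cpp(F_Grefs, p$M_o, p$m_fin, p$mu, p$g, p$c_damp,
                         gs$omega_n, gs$zeta, lg$K_P, lg$K_I, lg$K_D,
                         lg$tau_s, cfg$n_fingers, cfg$X_ref, cfg$duration,
                         cfg$dt, cfg$sgf_window[1], cfg$sgf_window[2])
  ce <- mapply(lift_cost, raw$xf_bar, raw$xo_bar,
               MoreArgs = list(X_ref = cfg$X_ref))
  data.frame(F_Gref = F_Grefs, CE = ce, SGF = raw$sgf,
             X_fin_bar = raw$xf_bar, X_o_bar = raw$xo_bar,
             blown = raw$max_abs_x > 10)
}
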