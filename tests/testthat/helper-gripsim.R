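# Shared fixtures. Utility surfaces are expensive (hundreds of simulated
# lifts per grid point), so they are built once per test run and memoised.

.surface_cache <- new.env(parent = emptyenv())

cached_surface <- function(name, n_samples = 500, grid_n = 25, seed = 42L) {
  key <- paste(name, n_samples, grid_n, seed, sep = "|")
  if (is.null(.surface_cache[[key]]))
    .surface_cache[[key]] <- build_utility(name, n_samples = n_samples,
                                           grid_n = grid_n, seed = seed)
  .surface_cache[[key]]
}

# A hand-made utility surface with known analytic V and h, for tests of the
# action-selection dynamics that must not depend on simulated lifts. The
# surface carries no trial config, so stable grip forces equal the grip
# reference.
synthetic_surface <- function(Vfun, hfun = function(f) rep(0, length(f)),
                              grid = seq(1, 10, length.out = 25)) {
  structure(list(condition = list(name = "synthetic"),
                 grid = grid, V = Vfun(grid), h = hfun(grid),
                 V_model = fit_rbf(grid, Vfun(grid)),
                 h_model = fit_rbf(grid, hfun(grid), floor_zero = TRUE),
                 slip_force = NA_real_, cfg = NULL,
                 n_samples = 0L, seed = 0L),
            class = "utility_surface")
}

# simulate a constant-force scenario with the R reference plant
run_const_forces <- function(F_G, F_L, params, n_steps,
                             state = plant_state()) {
  Ff <- Fn <- xo <- xf <- numeric(n_steps)
  for (k in seq_len(n_steps)) {
    out <- step_plant(state, F_G, F_L, params)
    state <- out$state
    Ff[k] <- out$forces$F_f; Fn[k] <- out$forces$F_n
    xo[k] <- state$X_o; xf[k] <- state$X_fin
  }
  list(state = state, F_f = Ff, F_n = Fn, X_o = xo, X_fin = xf)
}
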