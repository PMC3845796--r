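#' Plant parameters for the grip-lift system
#'
#' Physical parameters of the two-body stick-slip plant: an object of mass
#' `mass_kg` resting on a table at position 0, gripped between two identical
#' fingers whose assembly contributes inertia `finger_mass_kg`. The finger
#' assembly's weight is assumed to be borne by the arm, so gravity acts on
#' the object only. The total tangential friction capacity of the grip is
#' `mu * F_G`, which makes the static hold threshold exactly
#' `mass_kg * g / mu` (see [slip_force()]).
#'
#' @param mass_kg object mass in kg.
#' @param mu friction coefficient (dimensionless), defined operationally as
#'   object weight / slip force.
#' @param finger_mass_kg effective inertia of the finger assembly in kg.
#' @param g gravitational acceleration in m/s^2.
#' @param dt_s integration step in s.
#' @param c_damp viscous damping coefficient in N s/m (0 = no damping).
#' @return an object of class `plant_params`.
#' @examples
#' plant_params(mass_kg = 0.33, mu = 0.44)
#' @export
plant_params <- function(mass_kg, mu, finger_mass_kg = 0.12, g = 9.81,
                         dt_s = 1e-3, c_damp = 0) {
  stopifnot(is.numeric(mass_kg), length(mass_kg) == 1L, mass_kg > 0,
            is.numeric(mu), length(mu) == 1L, mu > 0,
            finger_mass_kg > 0, g > 0, dt_s > 0, c_damp >= 0)
  structure(list(M_o = mass_kg, m_fin = finger_mass_kg, mu = mu, g = g,
                 dt = dt_s, c_damp = c_damp),
            class = "plant_params")
}

#' @export
print.plant_params <- function(x, ...) {
  cat("Grip-lift plant parameters\n")
  cat(sprintf("  object mass     : %.3f kg\n", x$M_o))
  cat(sprintf("  finger inertia  : %.3f kg\n", x$m_fin))
  cat(sprintf("  friction coef.  : %.2f  (slip force %.3f N)\n",
              x$mu, slip_force(x)))
  cat(sprintf("  g = %.2f m/s^2, dt = %g s, damping = %g N s/m\n",
              x$g, x$dt, x$c_damp))
  invisible(x)
}

#' Plant state
#'
#' Kinematic state of the object and the finger assembly, plus the contact
#' regime. In `"stick"` mode the two bodies share a velocity; in `"resting"`
#' mode the object sits on the table (position 0) and the fingers are held
#' static by friction.
#'
#' @param X_o,V_o,A_o object position (m), velocity (m/s), acceleration
#'   (m/s^2). The object cannot penetrate the table, so `X_o >= 0`.
#' @param X_fin,V_fin,A_fin finger position, velocity, acceleration.
#' @param mode contact regime: `"resting"`, `"stick"` or `"slip"`.
#' @return an object of class `plant_state`.
#' @export
plant_state <- function(X_o = 0, V_o = 0, A_o = 0, X_fin = 0, V_fin = 0,
                        A_fin = 0, mode = c("resting", "stick", "slip")) {
  mode <- match.arg(mode)
  stopifnot(X_o >= 0, is.finite(c(X_o, V_o, A_o, X_fin, V_fin, A_fin)))
  structure(list(X_o = X_o, V_o = V_o, A_o = A_o, X_fin = X_fin,
                 V_fin = V_fin, A_fin = A_fin, mode = mode),
            class = "plant_state")
}

#' Slip force: the static hold threshold
#'
#' The minimal grip force at which the object's weight can be supported by
#' friction, `M_o * g / mu`. Below it a static hold is impossible and the
#' object slides through the fingers.
#'
#' @param params a [plant_params()] object.
#' @return slip force in N.
#' @examples
#' slip_force(plant_params(0.3, 0.94)) # ~3.13 N
#' @export
slip_force <- function(params) {
  stopifnot(inherits(params, "plant_params"))
  if (params$mu <= 0) stop("mu must be positive")
  params$M_o * params$g / params$mu
}

#' Advance the stick-slip plant by one step
#'
#' Semi-implicit Euler step with explicit contact-mode switching.
#' Regimes:
#' \itemize{
#' \item resting: the object is on the table with no net upward drive; the
#'   normal force carries the remaining weight and friction holds the
#'   fingers static if it can (`|F_L| <= mu F_G`), else the fingers slip.
#' \item stick: fingers and object move together with acceleration
#'   `a = (F_L - M_o g - c_damp V) / (m_fin + M_o)`; stick persists while
#'   the friction force required to impart `a` to the object,
#'   `F_req = M_o (a + g) - F_n`, stays inside the friction cone
#'   `|F_req| <= mu F_G`.
#' \item slip: kinetic friction `mu F_G` acts along the relative velocity;
#'   the bodies integrate separately and re-stick at the common
#'   momentum-conserving velocity when the relative velocity crosses zero.
#' }
#'
#' `F_L` here is the total lift force applied to the finger assembly.
#'
#' @param state a [plant_state()].
#' @param F_G grip force in N (>= 0).
#' @param F_L total lift force applied to the finger assembly in N.
#' @param params a [plant_params()].
#' @return a list with `state` (the advanced [plant_state()]) and `forces`,
#'   a list with the total friction force on the object `F_f` (N, positive
#'   up) and the table normal force `F_n` (N, >= 0).
#' @examples
#' p <- plant_params(0.3, 0.44)
#' step_plant(plant_state(), F_G = 0, F_L = 0, p)$forces
#' @export
step_plant <- function(state, F_G, F_L, params) {
  stopifnot(inherits(state, "plant_state"), inherits(params, "plant_params"))
  if (!is.finite(F_G) || !is.finite(F_L)) stop("forces must be finite")
  if (F_G < 0) stop("F_G must be non-negative")
  if (params$dt <= 0) stop("dt must be positive")

  vtol <- 1e-9
  dt <- params$dt
  cap <- params$mu * F_G
  xo <- state$X_o; vo <- state$V_o
  xf <- state$X_fin; vf <- state$V_fin
  vrel <- vf - vo
  vo0 <- vo; vf0 <- vf
  Ff <- 0; Fn <- 0; ao <- 0; af <- 0
  done <- FALSE; s <- 0; mode <- "slip"

  if (abs(vrel) <= vtol) {
    mt <- params$m_fin + params$M_o
    Fcomb <- F_L - params$M_o * params$g - params$c_damp * vo
    if (xo <= 0 && vo <= vtol && Fcomb <= 0) {
      freq <- F_L
      if (abs(freq) <= cap) {
        vo <- 0; vf <- 0; vo0 <- 0; vf0 <- 0
        if (xo < 0) xo <- 0
        Ff <- freq; Fn <- params$M_o * params$g - Ff
        mode <- "resting"; done <- TRUE
      } else s <- sign(freq)
    } else {
      a <- Fcomb / mt
      Freq <- params$M_o * (a + params$g)
      if (abs(Freq) <= cap) {
        ao <- a; af <- a
        vo <- vo + a * dt; vf <- vo
        Ff <- Freq; Fn <- 0
        mode <- "stick"; done <- TRUE
      } else s <- sign(Freq)
    }
  } else s <- sign(vrel)

  if (!done) {
    Ff <- cap * s
    Fo <- Ff - params$M_o * params$g - params$c_damp * vo
    if (xo <= 0 && vo <= vtol && Fo <= 0) {
      vo <- 0; vo0 <- 0; xo <- 0; ao <- 0
      Fn <- params$M_o * params$g - Ff
    } else {
      Fn <- 0; ao <- Fo / params$M_o
    }
    af <- (F_L - Ff - params$c_damp * vf) / params$m_fin
    vf2 <- vf + af * dt; vo2 <- vo + ao * dt
    if (abs(vrel) > vtol && sign(vf2 - vo2) != sign(vrel)) {
      v <- (params$m_fin * vf2 + params$M_o * vo2) / (params$m_fin + params$M_o)
      if (xo <= 0 && v < 0) v <- 0
      vf2 <- v; vo2 <- v
    }
    vo <- vo2; vf <- vf2
    mode <- "slip"
  }

  # locally exact constant-acceleration position update (trapezoid in v)
  xo <- xo + 0.5 * (vo0 + vo) * dt; xf <- xf + 0.5 * (vf0 + vf) * dt
  if (xo < 0) { xo <- 0; if (vo < 0) vo <- 0 }

  list(state = plant_state(X_o = xo, V_o = vo, A_o = ao, X_fin = xf,
                           V_fin = vf, A_fin = af, mode = mode),
       forces = list(F_f = Ff, F_n = Fn))
}
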