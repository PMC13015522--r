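# Conceptual dual-pendulum model: a trunk-limb segment pivoting about the
# ankles, coupled to the rotating platform by linear stiffness/damping, and a
# head segment articulated at the neck by its own stiffness/damping. Small-
# angle, linear; used to illustrate platform-following vs stabilizing regimes
# and as the physics core of the synthetic-trial generator.

#' Dual-pendulum model parameters
#'
#' @param m1 Trunk mass, kg.
#' @param l1 Trunk centre-of-mass distance from the ankle pivot, m.
#' @param I1 Trunk moment of inertia about the ankles, kg m^2.
#' @param I2 Head moment of inertia about the neck, kg m^2.
#' @param k_platform,c_platform Trunk-platform coupling stiffness (N m/rad) and
#'   damping (N m s/rad).
#' @param k_neck,c_neck Head-trunk coupling stiffness and damping, same units.
#' @param g Gravitational acceleration, m/s^2.
#' @param gravity_sign Sign of the trunk gravity torque term
#'   `gravity_sign * m1 * g * l1 * theta1`. The model's printed form is
#'   restoring (a hanging-pendulum sign), i.e. `-1`; set `+1` for an
#'   inverted-pendulum sensitivity analysis.
#' @return An object of class `pendulum_params`.
#' @export
pendulum_params <- function(m1, l1, I1, I2, k_platform, c_platform,
                            k_neck, c_neck, g = 9.81, gravity_sign = -1) {
  for (nm in c("m1", "l1", "I1", "I2", "g")) {
    if (get(nm) <= 0) stop("validation error: ", nm, " must be > 0")
  }
  for (nm in c("k_platform", "c_platform", "k_neck", "c_neck")) {
    if (get(nm) < 0) stop("validation error: ", nm, " must be >= 0")
  }
  if (!gravity_sign %in% c(-1, 1)) stop("gravity_sign must be -1 or +1")
  structure(list(m1 = m1, l1 = l1, I1 = I1, I2 = I2,
                 k_platform = k_platform, c_platform = c_platform,
                 k_neck = k_neck, c_neck = c_neck, g = g,
                 gravity_sign = gravity_sign),
            class = "pendulum_params")
}

#' Named parameter profiles for the dual-pendulum model
#'
#' Representative rhesus segment values (trunk ~4.5 kg, COM ~0.18 m, head
#' inertia ~0.01 kg m^2); these are illustrative, not fits to any experimental
#' data. `"platform-following"` couples the trunk stiffly to the platform with
#' a compliant neck, so the body rides the platform and the head lags;
#' `"stabilizing"` couples the trunk weakly to the platform with a stiff,
#' damped neck, so head-in-space motion stays well below platform motion.
#'
#' @param name Profile name.
#' @return A [pendulum_params()] object.
#' @export
pendulum_profiles <- function(name = c("platform-following", "stabilizing",
                                       "default")) {
  name <- match.arg(name)
  switch(name,
    "platform-following" = pendulum_params(
      m1 = 4.5, l1 = 0.18, I1 = 0.2, I2 = 0.01,
      k_platform = 200, c_platform = 20, k_neck = 3, c_neck = 0.3),
    "stabilizing" = pendulum_params(
      m1 = 4.5, l1 = 0.18, I1 = 0.2, I2 = 0.01,
      k_platform = 4, c_platform = 2.5, k_neck = 40, c_neck = 2),
    "default" = pendulum_params(
      m1 = 4.5, l1 = 0.18, I1 = 0.2, I2 = 0.01,
      k_platform = 50, c_platform = 8, k_neck = 10, c_neck = 1)
  )
}

#' Torques on the trunk and head segments
#'
#' Trunk torque: `gravity_sign * m1 g l1 theta1 - k_platform (theta1 - phi)
#' - c_platform (omega1 - phidot)` (with the default `gravity_sign = -1` this
#' is the model's printed restoring form). Head torque:
#' `-k_neck (theta2 - theta1) - c_neck (omega2 - omega1)`; the head carries no
#' gravity or inertial-coupling term, a deliberate simplification of the
#' conceptual model.
#'
#' @param state Numeric vector or list with `theta1`, `theta2`, `omega1`,
#'   `omega2` (rad, rad/s).
#' @param phi Platform angle, rad.
#' @param phidot Platform angular velocity, rad/s.
#' @param params A [pendulum_params()].
#' @return Named numeric vector `c(tau1, tau2)`, N m.
#' @export
compute_torques <- function(state, phi, phidot, params) {
  s <- as.list(state)
  tau1 <- params$gravity_sign * params$m1 * params$g * params$l1 * s$theta1 -
    params$k_platform * (s$theta1 - phi) -
    params$c_platform * (s$omega1 - phidot)
  tau2 <- -params$k_neck * (s$theta2 - s$theta1) -
    params$c_neck * (s$omega2 - s$omega1)
  c(tau1 = tau1, tau2 = tau2)
}

#' Platform drive as functions of time
#'
#' @param phi Function of time returning platform angle, rad.
#' @param phidot Function of time returning platform angular velocity, rad/s;
#'   must be the derivative of `phi`.
#' @return An object of class `platform_drive`.
#' @export
platform_drive <- function(phi, phidot) {
  stopifnot(is.function(phi), is.function(phidot))
  structure(list(phi = phi, phidot = phidot), class = "platform_drive")
}

#' Drive from a perturbation condition
#'
#' Converts the analytic platform command of a condition (deg) to the radian
#' drive used by the model, using the same closed-form integration as the
#' waveform designer so the two stay consistent.
#'
#' @param spec A [perturbation_spec()].
#' @return A [platform_drive()].
#' @export
drive_from_spec <- function(spec) {
  prof <- waveform_profile(spec)
  d2r <- pi / 180
  platform_drive(phi = function(t) prof$pos(t) * d2r,
                 phidot = function(t) prof$vel(t) * d2r)
}

#' Constant platform-angle step drive
#'
#' @param phi0 Platform angle, rad, applied from t = 0.
#' @return A [platform_drive()].
#' @export
drive_step <- function(phi0) {
  platform_drive(phi = function(t) rep(phi0, length(t)),
                 phidot = function(t) rep(0, length(t)))
}

#' Closed-form static equilibrium under a constant platform angle
#'
#' Solving `tau1 = tau2 = 0` for a constant platform angle `phi0` gives
#' `theta1* = k_platform phi0 / (m1 g l1 + k_platform)` (for the restoring
#' gravity sign) and `theta2* = theta1*`, with zero rates. Serves as an
#' independent oracle for the simulated dynamics.
#'
#' @param params A [pendulum_params()].
#' @param phi0 Platform angle, rad.
#' @return Named numeric state vector `c(theta1, theta2, omega1, omega2)`.
#' @export
static_equilibrium <- function(params, phi0) {
  denom <- params$k_platform - params$gravity_sign * params$m1 * params$g * params$l1
  if (abs(denom) < 1e-12) {
    stop("degenerate equilibrium: k_platform - gravity_sign * m1*g*l1 is zero")
  }
  theta1 <- params$k_platform * phi0 / denom
  c(theta1 = theta1, theta2 = theta1, omega1 = 0, omega2 = 0)
}

#' Simulate the dual-pendulum response to a platform drive
#'
#' Integrates `theta1'' = tau1 / I1`, `theta2'' = tau2 / I2` with an adaptive
#' embedded Runge-Kutta scheme (Dormand-Prince 4/5) and dense output on a
#' uniform grid.
#'
#' @param params A [pendulum_params()].
#' @param drive A [platform_drive()].
#' @param init Initial state `c(theta1, theta2, omega1, omega2)`, rad and
#'   rad/s.
#' @param duration Simulation span, s (> 0).
#' @param output_rate Output grid rate, samples/s.
#' @param rtol,atol Integrator relative/absolute tolerances.
#' @return A data frame of class `pendulum_trajectory` with columns `time_s`,
#'   `theta1`, `theta2`, `omega1`, `omega2`, `tau1`, `tau2`.
#' @export
simulate_pendulum <- function(params, drive,
                              init = c(theta1 = 0, theta2 = 0,
                                       omega1 = 0, omega2 = 0),
                              duration, output_rate = 1000,
                              rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "pendulum_params"), inherits(drive, "platform_drive"))
  if (duration <= 0) stop("validation error: duration must be > 0")
  times <- seq(0, duration, by = 1 / output_rate)
  deriv <- function(t, y, parms) {
    tau <- compute_torques(
      list(theta1 = y[1], theta2 = y[2], omega1 = y[3], omega2 = y[4]),
      drive$phi(t), drive$phidot(t), params)
    list(c(y[3], y[4], tau[[1]] / params$I1, tau[[2]] / params$I2))
  }
  sol <- deSolve::ode(y = unname(init), times = times, func = deriv,
                      parms = NULL, method = "ode45", rtol = rtol, atol = atol)
  if (anyNA(sol) || nrow(sol) < length(times)) {
    t_fail <- if (nrow(sol) > 0) sol[nrow(sol), 1] else 0
    stop("integrator failure near t = ", signif(t_fail, 6), " s")
  }
  out <- data.frame(time_s = sol[, 1], theta1 = sol[, 2], theta2 = sol[, 3],
                    omega1 = sol[, 4], omega2 = sol[, 5])
  taus <- mapply(function(th1, th2, om1, om2, t) {
    compute_torques(list(theta1 = th1, theta2 = th2, omega1 = om1, omega2 = om2),
                    drive$phi(t), drive$phidot(t), params)
  }, out$theta1, out$theta2, out$omega1, out$omega2, out$time_s)
  out$tau1 <- taus[1, ]
  out$tau2 <- taus[2, ]
  class(out) <- c("pendulum_trajectory", "data.frame")
  out
}
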