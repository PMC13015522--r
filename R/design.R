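# Perturbation waveform design: trapezoidal angular-velocity profiles that set
# peak acceleration A and peak velocity V independently while holding total
# displacement D fixed.

.AXIS_DIRECTIONS <- list(
  pitch = c("forward", "backward"),
  roll  = c("leftward", "rightward")
)

#' Sign convention for perturbation directions
#'
#' Forward pitch and leftward roll are positive; backward pitch and rightward
#' roll are negative. All downstream sign handling (waveform polarity, response
#' inversion when pooling mirrored directions) routes through this function.
#'
#' @param direction One of `"forward"`, `"backward"`, `"leftward"`,
#'   `"rightward"`.
#' @return `+1` or `-1`.
#' @export
direction_sign <- function(direction) {
  ifelse(direction %in% c("forward", "leftward"), 1, -1)
}

#' Define one rotational perturbation condition
#'
#' A condition is a platform tilt about one axis with a trapezoidal (or, at the
#' feasibility boundary, triangular) angular-velocity profile: a constant
#' acceleration block of amplitude `peak_accel`, a constant-velocity plateau at
#' `peak_vel`, and a mirrored deceleration block, integrating to exactly
#' `displacement` degrees.
#'
#' @param axis `"pitch"` (forward/backward tilt) or `"roll"` (left/right tilt).
#' @param direction Tilt direction, compatible with `axis`: pitch takes
#'   `"forward"`/`"backward"`, roll takes `"leftward"`/`"rightward"`.
#' @param peak_accel Peak angular acceleration, deg/s^2 (> 0).
#' @param peak_vel Peak angular velocity, deg/s (> 0).
#' @param displacement Total platform rotation, deg (> 0). The profile is
#'   feasible only if `peak_vel^2 / peak_accel <= displacement`; otherwise the
#'   velocity trapezoid cannot reach `peak_vel` within the displacement budget.
#' @param command_rate Platform command sample rate, samples/s.
#' @return An object of class `perturbation_spec`.
#' @examples
#' base <- perturbation_spec("pitch", "forward", peak_accel = 500, peak_vel = 40)
#' @export
perturbation_spec <- function(axis, direction, peak_accel, peak_vel,
                              displacement = 10, command_rate = 100) {
  axis <- match.arg(axis, names(.AXIS_DIRECTIONS))
  direction <- match.arg(direction, unlist(.AXIS_DIRECTIONS, use.names = FALSE))
  if (!direction %in% .AXIS_DIRECTIONS[[axis]]) {
    stop("direction '", direction, "' is not compatible with axis '", axis, "'")
  }
  for (nm in c("peak_accel", "peak_vel", "displacement", "command_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("validation error: ", nm, " must be a single positive finite number")
    }
  }
  if (peak_vel^2 / peak_accel > displacement + 1e-12) {
    stop("infeasible perturbation: peak_vel^2 / peak_accel = ",
         signif(peak_vel^2 / peak_accel, 6), " deg exceeds displacement = ",
         displacement, " deg (constraint peak_vel^2/peak_accel <= displacement)")
  }
  structure(
    list(axis = axis, direction = direction, peak_accel = peak_accel,
         peak_vel = peak_vel, displacement = displacement,
         command_rate = command_rate),
    class = "perturbation_spec"
  )
}

#' @export
print.perturbation_spec <- function(x, ...) {
  cat(sprintf("<perturbation_spec> %s %s: A = %g deg/s^2, V = %g deg/s, D = %g deg\n",
              x$axis, x$direction, x$peak_accel, x$peak_vel, x$displacement))
  invisible(x)
}

#' Block durations of a trapezoidal perturbation profile
#'
#' @param spec A [perturbation_spec()].
#' @return List with `d1` (acceleration and deceleration block duration, s),
#'   `d2` (constant-velocity plateau duration, s; 0 at the triangular
#'   feasibility boundary) and `total` (total motion duration, s).
#' @export
phase_durations <- function(spec) {
  A <- spec$peak_accel; V <- spec$peak_vel; D <- spec$displacement
  d1 <- V / A
  d2 <- max((D - V^2 / A) / V, 0)
  list(d1 = d1, d2 = d2, total = 2 * d1 + d2)
}

#' Closed-form continuous-time perturbation profile
#'
#' Returns vectorised functions of time (s) for the signed angular
#' acceleration, velocity and position of the platform command, built in
#' continuous time with exact block durations and integrated analytically.
#' Outside `[0, total]` the profile is at rest (position 0 before onset, at the
#' signed displacement after offset).
#'
#' @param spec A [perturbation_spec()].
#' @return List of functions `accel(t)` (deg/s^2), `vel(t)` (deg/s), `pos(t)`
#'   (deg), plus the [phase_durations()] of the profile.
#' @export
waveform_profile <- function(spec) {
  ph <- phase_durations(spec)
  A <- spec$peak_accel; V <- spec$peak_vel; D <- spec$displacement
  d1 <- ph$d1; d2 <- ph$d2; TT <- ph$total
  sgn <- direction_sign(spec$direction)
  t2 <- d1 + d2                        # start of deceleration block
  p1 <- A * d1^2 / 2                   # position at end of acceleration block
  p2 <- p1 + V * d2                    # position at start of deceleration

  accel <- function(t) {
    a <- numeric(length(t))
    a[t >= 0 & t < d1] <- A
    a[t >= t2 & t < TT] <- -A
    sgn * a
  }
  vel <- function(t) {
    v <- numeric(length(t))
    i1 <- t >= 0 & t < d1
    i2 <- t >= d1 & t < t2
    i3 <- t >= t2 & t < TT
    v[i1] <- A * t[i1]
    v[i2] <- V
    v[i3] <- V - A * (t[i3] - t2)
    sgn * v
  }
  pos <- function(t) {
    p <- numeric(length(t))
    i1 <- t >= 0 & t < d1
    i2 <- t >= d1 & t < t2
    i3 <- t >= t2 & t < TT
    p[i1] <- A * t[i1]^2 / 2
    p[i2] <- p1 + V * (t[i2] - d1)
    dt <- t[i3] - t2
    p[i3] <- p2 + V * dt - A * dt^2 / 2
    p[t >= TT] <- D
    sgn * p
  }
  list(accel = accel, vel = vel, pos = pos, durations = ph)
}

#' Construct the platform command waveform for a perturbation condition
#'
#' Builds the acceleration/velocity/position command by sampling the
#' continuous-time profile on the command grid. Because block durations are
#' handled analytically (not snapped to the grid), the sampled position reaches
#' the requested displacement exactly even when a block duration is not a grid
#' multiple. A grid-quantized variant (block durations rounded to whole command
#' samples, then discretely integrated) is available for fidelity studies of a
#' platform that can only realise grid-aligned steps.
#'
#' @param spec A [perturbation_spec()].
#' @param rate Sample rate of the returned series; defaults to the spec's
#'   command rate.
#' @param quantized If `TRUE`, snap block durations to the command grid and
#'   integrate discretely instead of analytically.
#' @return A data frame of class `waveform` with columns `time_s`,
#'   `accel_dps2`, `vel_dps`, `pos_deg`, and the spec stored as attribute
#'   `"spec"`.
#' @examples
#' w <- design_waveform(perturbation_spec("pitch", "forward", 500, 40))
#' tail(w$pos_deg, 1)  # 10 deg
#' @export
design_waveform <- function(spec, rate = spec$command_rate, quantized = FALSE) {
  stopifnot(inherits(spec, "perturbation_spec"))
  prof <- waveform_profile(spec)
  TT <- prof$durations$total
  n_end <- ceiling(TT * rate - 1e-9)
  time <- (0:n_end) / rate
  if (quantized) {
    d1q <- round(prof$durations$d1 * rate) / rate
    d2q <- round(prof$durations$d2 * rate) / rate
    a <- numeric(length(time))
    a[time < d1q] <- spec$peak_accel
    a[time >= d1q + d2q & time < 2 * d1q + d2q] <- -spec$peak_accel
    a <- direction_sign(spec$direction) * a
    v <- pracma::cumtrapz(time, a)[, 1]
    p <- pracma::cumtrapz(time, v)[, 1]
    w <- data.frame(time_s = time, accel_dps2 = a, vel_dps = v, pos_deg = p)
  } else {
    w <- data.frame(time_s = time,
                    accel_dps2 = prof$accel(time),
                    vel_dps = prof$vel(time),
                    pos_deg = prof$pos(time))
  }
  attr(w, "spec") <- spec
  class(w) <- c("waveform", "data.frame")
  w
}

#' The study perturbation protocol
#'
#' Velocity set \{20, 40, 60\} deg/s at 500 deg/s^2 and acceleration set
#' \{200, 500, 1000\} deg/s^2 at 40 deg/s, sharing the base profile
#' (500 deg/s^2, 40 deg/s), all with 10 deg total displacement, delivered in
#' four directions (forward/backward pitch, leftward/rightward roll).
#'
#' @param velocity_set Peak velocities, deg/s, paired with `base_accel`.
#' @param accel_set Peak accelerations, deg/s^2, paired with `base_vel`.
#' @param base_accel,base_vel The shared base profile.
#' @param displacement Total displacement, deg, common to every condition.
#' @param command_rate Platform command rate, samples/s.
#' @return A list of class `protocol_config`.
#' @export
default_protocol <- function(velocity_set = c(20, 40, 60),
                             accel_set = c(200, 500, 1000),
                             base_accel = 500, base_vel = 40,
                             displacement = 10, command_rate = 100) {
  structure(list(velocity_set = velocity_set, accel_set = accel_set,
                 base_accel = base_accel, base_vel = base_vel,
                 displacement = displacement, command_rate = command_rate),
            class = "protocol_config")
}

#' Enumerate the perturbation condition grid of a protocol
#'
#' Crosses the de-duplicated set of (acceleration, velocity) profiles with the
#' four directions; the base profile, shared between the velocity and
#' acceleration sets, appears once per direction. The study protocol yields
#' 5 unique profiles x 4 directions = 20 conditions.
#'
#' @param protocol A [default_protocol()]-style config.
#' @param directions Directions to include (default all four).
#' @return A list of [perturbation_spec()] objects.
#' @export
enumerate_conditions <- function(protocol = default_protocol(),
                                 directions = c("forward", "backward",
                                                "leftward", "rightward")) {
  stopifnot(inherits(protocol, "protocol_config"))
  profiles <- rbind(
    if (length(protocol$velocity_set)) {
      data.frame(accel = protocol$base_accel, vel = protocol$velocity_set)
    },
    if (length(protocol$accel_set)) {
      data.frame(accel = protocol$accel_set, vel = protocol$base_vel)
    }
  )
  if (is.null(profiles) || nrow(profiles) == 0L) {
    stop("protocol defines no perturbation profiles")
  }
  profiles <- unique(profiles)
  conds <- list()
  for (dir in directions) {
    axis <- if (dir %in% .AXIS_DIRECTIONS$pitch) "pitch" else "roll"
    for (i in seq_len(nrow(profiles))) {
      conds[[length(conds) + 1L]] <- perturbation_spec(
        axis, dir, profiles$accel[i], profiles$vel[i],
        displacement = protocol$displacement,
        command_rate = protocol$command_rate
      )
    }
  }
  conds
}

#' Validate a sampled waveform against its defining spec
#'
#' Checks that the peak sampled velocity matches `peak_vel`, the final position
#' matches the signed displacement, and no acceleration sample exceeds
#' `peak_accel`.
#'
#' @param w A `waveform` data frame.
#' @param spec The [perturbation_spec()] it should realise.
#' @param tol_pos Displacement tolerance, deg.
#' @param tol_vel Velocity tolerance, deg/s; the default of one acceleration
#'   step per command sample accounts for the plateau possibly falling between
#'   grid points.
#' @return A data frame of class `validation_report` with one row per check
#'   (`check`, `value`, `target`, `tol`, `pass`).
#' @export
validate_waveform <- function(w, spec, tol_pos = 1e-9,
                              tol_vel = spec$peak_accel / spec$command_rate) {
  if (!all(c("time_s", "accel_dps2", "vel_dps", "pos_deg") %in% names(w))) {
    stop("structural error: waveform must have columns time_s, accel_dps2, vel_dps, pos_deg")
  }
  n <- vapply(w[c("time_s", "accel_dps2", "vel_dps", "pos_deg")], length, 1L)
  if (length(unique(n)) != 1L || n[1] == 0L) {
    stop("structural error: waveform series are empty or length-mismatched")
  }
  checks <- data.frame(
    check = c("peak_velocity", "final_position", "peak_acceleration"),
    value = c(max(abs(w$vel_dps)), w$pos_deg[nrow(w)], max(abs(w$accel_dps2))),
    target = c(spec$peak_vel, direction_sign(spec$direction) * spec$displacement,
               spec$peak_accel),
    tol = c(tol_vel, tol_pos, 1e-9)
  )
  checks$pass <- abs(checks$value - checks$target) <= checks$tol
  # peak acceleration may legitimately be *below* target on a quantized grid;
  # it must never exceed it
  checks$pass[3] <- checks$value[3] <= checks$target[3] + checks$tol[3]
  class(checks) <- c("validation_report", "data.frame")
  checks
}
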