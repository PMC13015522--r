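# Trial records: one perturbation trial's head kinematics (IMU), footplate
# forces and metadata on a uniform analysis grid with t = 0 at perturbation
# onset.

#' Construct a trial record
#'
#' @param trial_id Character identifier.
#' @param animal_id Character identifier of the subject.
#' @param condition The [perturbation_spec()] delivered on this trial.
#' @param time Time, s, uniform grid with t = 0 at perturbation onset; must
#'   span at least 500 ms before onset.
#' @param head_angvel Data frame with columns `pitch`, `roll`, `yaw`, deg/s.
#' @param head_linacc Data frame with columns `fore_aft`, `lateral`,
#'   `vertical`, m/s^2.
#' @param forces Data frame with columns `F_FL`, `F_FR`, `F_HL`, `F_HR`, N.
#' @param mass Animal mass, kg.
#' @param step_response_flag Logical; `TRUE` when post-hoc video review found a
#'   step response (produced by an external pose pipeline, consumed here as a
#'   boolean).
#' @param motion_end End of the platform motion, s; defaults to the analytic
#'   end time of the condition's waveform.
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(trial_id, animal_id, condition, time,
                         head_angvel, head_linacc, forces, mass,
                         step_response_flag = FALSE,
                         motion_end = phase_durations(condition)$total) {
  stopifnot(inherits(condition, "perturbation_spec"))
  n <- length(time)
  if (n < 2L) stop("structural error: trial needs at least two samples")
  dt <- diff(time)
  if (max(abs(dt - dt[1])) > 1e-9) {
    stop("structural error: trial time grid is not uniform")
  }
  for (df in list(head_angvel, head_linacc, forces)) {
    if (nrow(df) != n) stop("structural error: channel length mismatch")
  }
  structure(
    list(trial_id = trial_id, animal_id = animal_id, condition = condition,
         time = time, head_angvel = head_angvel, head_linacc = head_linacc,
         forces = forces, mass = mass, step_response_flag = step_response_flag,
         motion_end = motion_end),
    class = "trial_record"
  )
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> %s (%s) %s %s A=%g V=%g, %d samples [%g, %g] s\n",
              x$trial_id, x$animal_id, x$condition$axis, x$condition$direction,
              x$condition$peak_accel, x$condition$peak_vel, length(x$time),
              min(x$time), max(x$time)))
  invisible(x)
}

# channel names used throughout the analysis; the axis-relevant response
# channels of a trial are picked by axis_channels()
.CHANNELS <- c("pitch_vel", "roll_vel", "yaw_vel",
               "fa_acc", "lat_acc", "vert_acc", "cop_lat", "cop_ap")

#' All analysis channels of a trial as named vectors
#'
#' Angular-velocity channels in deg/s, linear accelerations in m/s^2, CoP in
#' N/kg (computed from the footplate forces).
#'
#' @param trial A [trial_record()].
#' @return Named list of numeric vectors (one per channel) plus `time`.
#' @export
trial_channels <- function(trial) {
  cop <- compute_cop(cbind(time_s = trial$time, trial$forces), trial$mass)
  list(time = trial$time,
       pitch_vel = trial$head_angvel$pitch,
       roll_vel = trial$head_angvel$roll,
       yaw_vel = trial$head_angvel$yaw,
       fa_acc = trial$head_linacc$fore_aft,
       lat_acc = trial$head_linacc$lateral,
       vert_acc = trial$head_linacc$vertical,
       cop_lat = cop$cop_lat,
       cop_ap = cop$cop_ap)
}

#' Axis-relevant response channels
#'
#' For pitch perturbations the response channels are head pitch velocity,
#' fore-aft linear acceleration and fore-aft CoP; for roll, head roll velocity,
#' lateral acceleration and lateral CoP.
#'
#' @param axis `"pitch"` or `"roll"`.
#' @return Named character vector mapping `head_vel`, `head_acc`, `cop` to
#'   channel names.
#' @export
axis_channels <- function(axis) {
  axis <- match.arg(axis, c("pitch", "roll"))
  if (axis == "pitch") {
    c(head_vel = "pitch_vel", head_acc = "fa_acc", cop = "cop_ap")
  } else {
    c(head_vel = "roll_vel", head_acc = "lat_acc", cop = "cop_lat")
  }
}
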