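# Footplate kinetics: mass-normalized centre-of-pressure signals from the four
# load cells, and the stance-symmetry criteria used to gate trial starts.

#' Centre of pressure from four footplate forces
#'
#' Lateral CoP is `((F_FL + F_HL) - (F_FR + F_HR)) / m` and fore-aft CoP is
#' `((F_FL + F_FR) - (F_HL + F_HR)) / m`, where FL/FR/HL/HR are the front-left,
#' front-right, hind-left and hind-right plates and `m` the animal mass.
#' Units are N/kg (a mass-normalized force difference, not a metric position:
#' the footplate geometry is not part of the model). No filtering is applied
#' unless `lowpass_hz` is given.
#'
#' @param forces Data frame with columns `time_s`, `F_FL`, `F_FR`, `F_HL`,
#'   `F_HR` (N) on a uniform grid.
#' @param mass Animal mass, kg (> 0).
#' @param lowpass_hz Optional cutoff of a 2nd-order zero-phase Butterworth
#'   low-pass applied to each force channel before the CoP computation.
#' @return Data frame of class `cop_trace` with columns `time_s`, `cop_lat`,
#'   `cop_ap` (N/kg).
#' @examples
#' f <- data.frame(time_s = 0:1, F_FL = 30, F_FR = 20, F_HL = 30, F_HR = 20)
#' compute_cop(f, mass = 10)  # lat = 2, ap = 0
#' @export
compute_cop <- function(forces, mass, lowpass_hz = NULL) {
  need <- c("time_s", "F_FL", "F_FR", "F_HL", "F_HR")
  if (!all(need %in% names(forces))) {
    stop("structural error: forces must have columns ", paste(need, collapse = ", "))
  }
  if (!is.numeric(mass) || length(mass) != 1L || !is.finite(mass) || mass <= 0) {
    stop("validation error: mass must be a single positive number")
  }
  F <- forces[c("F_FL", "F_FR", "F_HL", "F_HR")]
  if (!is.null(lowpass_hz)) {
    rate <- 1 / stats::median(diff(forces$time_s))
    F[] <- lapply(F, .butter_lowpass, rate = rate, cutoff = lowpass_hz)
  }
  out <- data.frame(
    time_s = forces$time_s,
    cop_lat = ((F$F_FL + F$F_HL) - (F$F_FR + F$F_HR)) / mass,
    cop_ap  = ((F$F_FL + F$F_FR) - (F$F_HL + F$F_HR)) / mass
  )
  class(out) <- c("cop_trace", "data.frame")
  out
}

# zero-phase 2nd-order Butterworth low-pass
.butter_lowpass <- function(x, rate, cutoff) {
  bf <- signal::butter(2, 2 * cutoff / rate, type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

#' Stance-symmetry trial-start check
#'
#' A trial may start only when weight is balanced across the plate halves
#' (< 10 N difference front vs hind and left vs right) and the head is level
#' and facing straight ahead (deviation < 10 deg in every axis). Thresholds
#' are strict inequalities.
#'
#' @param forces Named numeric vector with `F_FL`, `F_FR`, `F_HL`, `F_HR` (N)
#'   at a single time sample.
#' @param head_orientation Named numeric vector of head-axis deviations, deg.
#' @param force_thresh,head_thresh Criterion thresholds (N, deg).
#' @return List of class `stance_check` with per-criterion booleans
#'   (`fore_aft_ok`, `lateral_ok`, `head_ok`), the measured differences, and
#'   overall `pass`.
#' @export
stance_check <- function(forces, head_orientation,
                         force_thresh = 10, head_thresh = 10) {
  need <- c("F_FL", "F_FR", "F_HL", "F_HR")
  if (!all(need %in% names(forces))) {
    stop("structural error: forces must be named ", paste(need, collapse = ", "))
  }
  fa_diff <- (forces[["F_FL"]] + forces[["F_FR"]]) -
    (forces[["F_HL"]] + forces[["F_HR"]])
  lat_diff <- (forces[["F_FL"]] + forces[["F_HL"]]) -
    (forces[["F_FR"]] + forces[["F_HR"]])
  res <- list(
    fore_aft_ok = abs(fa_diff) < force_thresh,
    lateral_ok = abs(lat_diff) < force_thresh,
    head_ok = all(abs(head_orientation) < head_thresh),
    fore_aft_diff_N = unname(fa_diff),
    lateral_diff_N = unname(lat_diff),
    max_head_dev_deg = max(abs(head_orientation))
  )
  res$pass <- res$fore_aft_ok && res$lateral_ok && res$head_ok
  class(res) <- "stance_check"
  res
}
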