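# Response metrics: window means over the short-latency (0-100 ms) and
# medium-latency (100-200 ms) windows, RMS-threshold onset latency,
# displacement integrals over the platform-motion span, trial averaging, and
# mirrored-direction pooling.

#' Default analysis windows
#'
#' Short-latency window `[0, 0.1)` s and medium-latency window `[0.1, 0.2)` s
#' after perturbation onset. Windows are half-open so the 100 ms boundary
#' sample is not double-counted.
#'
#' @return Named list of `c(start, end)` windows, s.
#' @export
analysis_windows <- function() {
  list(short = c(0, 0.1), medium = c(0.1, 0.2))
}

#' Mean of a trace over a half-open time window
#'
#' @param time Time, s.
#' @param x Trace values, same length as `time`.
#' @param window `c(t_start, t_end)`, s; samples with
#'   `t_start <= t < t_end` are averaged.
#' @return Scalar mean.
#' @export
window_mean <- function(time, x, window) {
  stopifnot(length(time) == length(x), length(window) == 2L)
  mask <- time >= window[1] & time < window[2]
  if (!any(mask)) {
    stop("empty window [", window[1], ", ", window[2], ") for this trace")
  }
  mean(x[mask])
}

#' Response onset latency via the baseline-RMS threshold
#'
#' The detection threshold is the RMS of the mean-subtracted trace over the
#' baseline window (the pre-onset "RMS error"), floored at `eps_floor` to keep
#' the noiseless-baseline case well defined. Onset is the first post-onset time
#' at which `|x - baseline mean|` exceeds the threshold for `consecutive`
#' samples in a row.
#'
#' @param time Time, s, with t = 0 at perturbation onset.
#' @param x Trace values.
#' @param baseline_window `c(start, end)`, s, pre-onset; default the 500 ms
#'   before onset.
#' @param eps_floor Threshold floor, channel units.
#' @param consecutive Number of consecutive suprathreshold samples required.
#' @return Latency in ms, or `NA_real_` when the trace never crosses the
#'   threshold (not-detected). The threshold used is attached as attribute
#'   `"threshold"`.
#' @export
onset_latency <- function(time, x, baseline_window = c(-0.5, 0),
                          eps_floor = 1e-9, consecutive = 1L) {
  stopifnot(length(time) == length(x))
  base_mask <- time >= baseline_window[1] & time < baseline_window[2]
  if (!any(base_mask)) stop("baseline window has no samples")
  bmean <- mean(x[base_mask])
  thr <- max(sqrt(mean((x[base_mask] - bmean)^2)), eps_floor)
  post <- which(time >= 0)
  above <- abs(x[post] - bmean) > thr
  idx <- NA_integer_
  if (consecutive <= 1L) {
    hit <- which(above)
    if (length(hit)) idx <- hit[1]
  } else {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    k <- which(r$values & r$lengths >= consecutive)
    if (length(k)) idx <- ends[k[1]] - r$lengths[k[1]] + 1L
  }
  lat <- if (is.na(idx)) NA_real_ else time[post[idx]] * 1000
  attr(lat, "threshold") <- thr
  lat
}

#' Displacement integrals over a time span
#'
#' Total angular displacement is the trapezoidal integral of angular velocity;
#' total linear displacement the double trapezoidal integral of linear
#' acceleration; CoP trajectory length the cumulated absolute sample-to-sample
#' change of the CoP trace (path length; the literal signed cumulative sum is
#' available via `cop_mode = "signed"`). All integrals run over `span`,
#' normally the platform-motion span `[0, motion end]`.
#'
#' @param time Time, s.
#' @param angvel Angular velocity, deg/s, or `NULL`.
#' @param linacc Linear acceleration, m/s^2, or `NULL`.
#' @param cop CoP trace, N/kg, or `NULL`.
#' @param span `c(start, end)`, s; must lie within the trace.
#' @param cop_mode `"path"` (default) or `"signed"`.
#' @return List with `angular_deg`, `linear_m`, `cop_path` (elements `NA` for
#'   channels not supplied).
#' @export
displacement_integrals <- function(time, angvel = NULL, linacc = NULL,
                                   cop = NULL, span,
                                   cop_mode = c("path", "signed")) {
  cop_mode <- match.arg(cop_mode)
  if (span[1] < min(time) - 1e-9 || span[2] > max(time) + 1e-9) {
    stop("span mismatch: [", span[1], ", ", span[2],
         "] s is not covered by the trace")
  }
  mask <- time >= span[1] & time <= span[2]
  tm <- time[mask]
  out <- list(angular_deg = NA_real_, linear_m = NA_real_, cop_path = NA_real_)
  if (!is.null(angvel)) {
    out$angular_deg <- pracma::trapz(tm, angvel[mask])
  }
  if (!is.null(linacc)) {
    v <- pracma::cumtrapz(tm, linacc[mask])[, 1]
    out$linear_m <- pracma::trapz(tm, v)
  }
  if (!is.null(cop)) {
    out$cop_path <- if (cop_mode == "path") {
      sum(abs(diff(cop[mask])))
    } else {
      sum(cop[mask])
    }
  }
  out
}

#' Displacement metrics of one trial
#'
#' Applies [displacement_integrals()] to the trial's axis-relevant channels
#' over the platform-motion span.
#'
#' @param trial A [trial_record()].
#' @param span Integration span, s; defaults to `[0, motion_end]`.
#' @param cop_mode See [displacement_integrals()].
#' @return List with `angular_deg`, `linear_m`, `cop_path`.
#' @export
displacements <- function(trial, span = c(0, trial$motion_end),
                          cop_mode = c("path", "signed")) {
  ch <- trial_channels(trial)
  ax <- axis_channels(trial$condition$axis)
  displacement_integrals(ch$time, angvel = ch[[ax["head_vel"]]],
                         linacc = ch[[ax["head_acc"]]], cop = ch[[ax["cop"]]],
                         span = span, cop_mode = match.arg(cop_mode))
}

#' Average synchronized trials of one condition
#'
#' Trials must share the condition and the analysis grid (synchronized at
#' t = 0, the perturbation onset). Returns the pointwise mean and standard
#' error (sample SD / sqrt(n); 0 when n = 1) of every channel.
#'
#' @param trials List of [trial_record()]s.
#' @return List of class `condition_average` with `time`, `mean` and `sem`
#'   (named lists of traces per channel), `n_trials` and `condition`.
#' @export
average_condition <- function(trials) {
  if (length(trials) == 0L) stop("no trials to average")
  c0 <- trials[[1]]$condition
  same <- vapply(trials, function(tr) {
    identical(tr$condition$axis, c0$axis) &&
      identical(tr$condition$direction, c0$direction) &&
      tr$condition$peak_accel == c0$peak_accel &&
      tr$condition$peak_vel == c0$peak_vel
  }, TRUE)
  if (!all(same)) stop("mixed conditions: all trials must share one condition")
  t0 <- trials[[1]]$time
  if (!all(vapply(trials, function(tr) {
    length(tr$time) == length(t0) && max(abs(tr$time - t0)) < 1e-9
  }, TRUE))) {
    stop("structural error: trials are not on a shared time grid")
  }
  chans <- lapply(trials, trial_channels)
  n <- length(trials)
  mean_tr <- list(); sem_tr <- list()
  for (nm in .CHANNELS) {
    m <- vapply(chans, function(ch) ch[[nm]], numeric(length(t0)))
    m <- matrix(m, nrow = length(t0))
    mean_tr[[nm]] <- rowMeans(m)
    sem_tr[[nm]] <- if (n == 1L) rep(0, length(t0)) else {
      apply(m, 1, stats::sd) / sqrt(n)
    }
  }
  structure(list(time = t0, mean = mean_tr, sem = sem_tr, n_trials = n,
                 condition = c0),
            class = "condition_average")
}

#' Invert one direction and pool mirrored-direction trials
#'
#' For a pair of mirrored directions of the same profile (e.g. leftward and
#' rightward roll), inverts the direction-odd channels of the
#' negative-direction trials and concatenates the two sets, so 20 + 20 trials
#' become one pooled set of 40. Inversion negates the axis-relevant head
#' channels and mirrors the footplate forces (left/right swap for roll,
#' front/hind swap for pitch), which flips the corresponding CoP channel.
#'
#' @param trials_a,trials_b Trial lists for the two opposite directions of one
#'   axis and profile. If one side is empty the other is returned unchanged
#'   with a warning.
#' @return List of pooled [trial_record()]s, all labelled with the
#'   positive direction of the axis.
#' @export
invert_and_pool <- function(trials_a, trials_b) {
  if (length(trials_a) == 0L || length(trials_b) == 0L) {
    warning("one direction has no trials; returning the other side unchanged")
    return(c(trials_a, trials_b))
  }
  ca <- trials_a[[1]]$condition; cb <- trials_b[[1]]$condition
  if (!identical(ca$axis, cb$axis) || ca$peak_accel != cb$peak_accel ||
      ca$peak_vel != cb$peak_vel || identical(ca$direction, cb$direction)) {
    stop("non-mirror conditions: need opposite directions of one axis and profile")
  }
  flip_one <- function(trial) {
    if (direction_sign(trial$condition$direction) > 0) return(trial)
    mirrored <- trial
    ax <- trial$condition$axis
    if (ax == "roll") {
      mirrored$head_angvel$roll <- -trial$head_angvel$roll
      mirrored$head_linacc$lateral <- -trial$head_linacc$lateral
      mirrored$forces <- data.frame(F_FL = trial$forces$F_FR,
                                    F_FR = trial$forces$F_FL,
                                    F_HL = trial$forces$F_HR,
                                    F_HR = trial$forces$F_HL)
    } else {
      mirrored$head_angvel$pitch <- -trial$head_angvel$pitch
      mirrored$head_linacc$fore_aft <- -trial$head_linacc$fore_aft
      mirrored$forces <- data.frame(F_FL = trial$forces$F_HL,
                                    F_FR = trial$forces$F_HR,
                                    F_HL = trial$forces$F_FL,
                                    F_HR = trial$forces$F_FR)
    }
    pos_dir <- setdiff(.AXIS_DIRECTIONS[[ax]],
                       trial$condition$direction)
    mirrored$condition <- perturbation_spec(
      ax, pos_dir, trial$condition$peak_accel, trial$condition$peak_vel,
      trial$condition$displacement, trial$condition$command_rate)
    mirrored$inverted <- TRUE
    mirrored
  }
  c(lapply(trials_a, flip_one), lapply(trials_b, flip_one))
}

#' Per-trial response metrics as a tidy table
#'
#' One row per (trial, response channel): window means over the short- and
#' medium-latency windows, onset latency, and the channel's displacement
#' measure (angular displacement for head velocity, linear displacement for
#' head acceleration, CoP path length for CoP).
#'
#' @param trials List of [trial_record()]s.
#' @param windows Analysis windows, see [analysis_windows()].
#' @return Data frame with columns `trial_id`, `animal_id`, `axis`,
#'   `direction`, `peak_accel`, `peak_vel`, `channel`, `short_mean`,
#'   `medium_mean`, `onset_ms`, `displacement`.
#' @export
metrics_table <- function(trials, windows = analysis_windows()) {
  rows <- lapply(trials, function(trial) {
    ch <- trial_channels(trial)
    ax <- axis_channels(trial$condition$axis)
    disp <- displacements(trial)
    dval <- c(head_vel = disp$angular_deg, head_acc = disp$linear_m,
              cop = disp$cop_path)
    do.call(rbind, lapply(names(ax), function(role) {
      x <- ch[[ax[[role]]]]
      data.frame(
        trial_id = trial$trial_id, animal_id = trial$animal_id,
        axis = trial$condition$axis, direction = trial$condition$direction,
        peak_accel = trial$condition$peak_accel,
        peak_vel = trial$condition$peak_vel,
        channel = role,
        short_mean = window_mean(ch$time, x, windows$short),
        medium_mean = window_mean(ch$time, x, windows$medium),
        onset_ms = as.numeric(onset_latency(ch$time, x)),
        displacement = dval[[role]]
      )
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
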