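# Trial quality control: the exclusion rules applied to head-velocity traces
# and the per-trial step-response flag from video review.

#' QC thresholds
#'
#' Defaults follow the study rules: exclude a trial if head velocity exceeds
#' 20 deg/s anywhere in the 500 ms before perturbation onset (quiet-baseline
#' rule), or exceeds 400 deg/s anywhere in the trial including 500 ms before
#' onset and after motion offset (head-shake rule). Both are strict
#' ("exceeds") comparisons.
#'
#' @param baseline_vel Baseline velocity limit, deg/s.
#' @param peak_vel Whole-trial velocity limit, deg/s.
#' @param baseline_window Pre-onset span inspected by both rules, s.
#' @param tail Post-offset span inspected by the peak rule, s.
#' @param norm `"per-axis"` applies the limits to `|velocity|` of each IMU axis
#'   separately (the default; IMU channels are per-axis); `"vector"` applies
#'   them to the Euclidean norm across axes.
#' @return List of class `qc_thresholds`.
#' @export
qc_thresholds <- function(baseline_vel = 20, peak_vel = 400,
                          baseline_window = 0.5, tail = 0.5,
                          norm = c("per-axis", "vector")) {
  structure(list(baseline_vel = baseline_vel, peak_vel = peak_vel,
                 baseline_window = baseline_window, tail = tail,
                 norm = match.arg(norm)),
            class = "qc_thresholds")
}

#' Apply the trial-exclusion rules to one trial
#'
#' A trial is excluded if its step-response flag is set, if baseline head
#' velocity exceeds the quiet-baseline limit, or if head velocity anywhere in
#' the inspected span exceeds the head-shake limit. Every violated rule is
#' reported.
#'
#' @param trial A [trial_record()].
#' @param thresholds A [qc_thresholds()].
#' @return List of class `qc_result` with `keep` (boolean) and `reasons`
#'   (character vector of failed rules, empty iff `keep`).
#' @export
qc_trial <- function(trial, thresholds = qc_thresholds()) {
  stopifnot(inherits(trial, "trial_record"))
  t <- trial$time
  if (min(t) > -thresholds$baseline_window + 1e-9) {
    stop("structural error: trial '", trial$trial_id, "' has less than ",
         thresholds$baseline_window * 1000, " ms of pre-onset data")
  }
  v <- as.matrix(trial$head_angvel)
  mag <- if (thresholds$norm == "vector") {
    matrix(sqrt(rowSums(v^2)), ncol = 1)
  } else {
    abs(v)
  }
  base_mask <- t >= -thresholds$baseline_window & t < 0
  full_mask <- t >= -thresholds$baseline_window &
    t <= trial$motion_end + thresholds$tail
  reasons <- character(0)
  if (isTRUE(trial$step_response_flag)) reasons <- c(reasons, "step-response")
  if (max(mag[base_mask, ]) > thresholds$baseline_vel) {
    reasons <- c(reasons, "baseline-velocity")
  }
  if (max(mag[full_mask, ]) > thresholds$peak_vel) {
    reasons <- c(reasons, "peak-velocity")
  }
  structure(list(trial_id = trial$trial_id, animal_id = trial$animal_id,
                 keep = length(reasons) == 0L, reasons = reasons),
            class = "qc_result")
}

#' Summarize exclusions across a trial set
#'
#' @param results List of [qc_trial()] results.
#' @return Data frame of class `exclusion_summary` with one row per animal
#'   (plus a pooled `"(all)"` row): trials, exclusions, exclusion fraction, and
#'   per-reason counts.
#' @export
summarize_exclusions <- function(results) {
  if (length(results) == 0L) stop("no QC results to summarize")
  df <- data.frame(
    animal_id = vapply(results, function(r) r$animal_id, ""),
    keep = vapply(results, function(r) r$keep, TRUE),
    step = vapply(results, function(r) "step-response" %in% r$reasons, TRUE),
    baseline = vapply(results, function(r) "baseline-velocity" %in% r$reasons, TRUE),
    peak = vapply(results, function(r) "peak-velocity" %in% r$reasons, TRUE)
  )
  one <- function(d, label) {
    data.frame(animal_id = label, n_trials = nrow(d),
               n_excluded = sum(!d$keep),
               frac_excluded = mean(!d$keep),
               n_step = sum(d$step), n_baseline = sum(d$baseline),
               n_peak = sum(d$peak))
  }
  out <- do.call(rbind, c(
    lapply(split(df, df$animal_id), function(d) one(d, d$animal_id[1])),
    list(one(df, "(all)"))
  ))
  rownames(out) <- NULL
  class(out) <- c("exclusion_summary", "data.frame")
  out
}
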