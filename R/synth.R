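# Synthetic-trial generator. Emulates the study's data structure so every
# pipeline stage is testable without animal data: per-condition trial sets
# whose short-latency response scales with stimulus acceleration and whose
# medium-latency response scales with peak velocity, with per-animal gain
# offsets, direction-dependent gain asymmetry, additive noise, QC-violating
# contamination, and footplate forces consistent with a target CoP trace.

# cache for per-condition deterministic bases (waveform samples, pendulum
# simulations); everything cached is a pure function of its key
.synth_cache <- new.env(parent = emptyenv())

#' Synthetic-data generator specification
#'
#' Defaults encode the study conditions: the 20-condition protocol, 20 trials
#' per condition per animal, three animals with scalar gain offsets averaging
#' one, and roughly 10% of trials contaminated with QC-violating artifacts.
#' The injected ground truth is the dissociation structure itself: the
#' short-latency window amplitude of every response channel is
#' `short_accel_gain * peak_accel * animal gain * direction gain` (times the
#' channel's unit scale) and the medium-latency amplitude is
#' `medium_vel_gain * peak_vel * ...`. Pitch trials ride a platform-following
#' head-velocity base (head velocity = platform command); roll trials sit on a
#' stabilized base from the dual-pendulum model's stabilizing profile.
#'
#' @param conditions List of [perturbation_spec()]s; defaults to the study
#'   grid.
#' @param n_trials Trials per condition per animal.
#' @param animals Data frame with `animal_id` and `gain` (multiplicative
#'   per-animal response offsets).
#' @param short_accel_gain Short-window CoP response per unit stimulus
#'   acceleration, (N/kg) / (deg/s^2).
#' @param medium_vel_gain Medium-window CoP response per unit peak velocity,
#'   (N/kg) / (deg/s).
#' @param channel_gain Unit scale of each response channel relative to the CoP
#'   channel (head velocity in deg/s, head acceleration in m/s^2).
#' @param onset_s Response onset per channel, s.
#' @param ramp_s Raised-cosine edge duration of the response windows, s.
#' @param noise_sd Additive white-noise SD per channel (deg/s, m/s^2, N/kg).
#' @param direction_asymmetry Multiplicative gain applied to
#'   negative-direction (backward/rightward) responses; 1 = mirror-symmetric.
#' @param contamination_rate Fraction of trials given QC-violating artifacts
#'   (baseline drift > 20 deg/s or velocity spikes > 400 deg/s).
#' @param mass_kg Animal mass used for the force synthesis.
#' @param analysis_rate Analysis grid rate, samples/s.
#' @param pre_s,post_s Pre-onset and post-offset spans, s.
#' @param pendulum_profile Parameter profile for the roll-axis stabilized
#'   base.
#' @param seed Master seed; per-trial substreams are derived by counter so
#'   any subset regenerates identically.
#' @return List of class `generator_spec`.
#' @export
generator_spec <- function(conditions = enumerate_conditions(),
                           n_trials = 20,
                           animals = data.frame(
                             animal_id = c("E", "B", "D"),
                             gain = c(1.00, 0.85, 1.15)),
                           short_accel_gain = 2e-3,
                           medium_vel_gain = 2.5e-2,
                           channel_gain = c(head_vel = 4, head_acc = 0.12,
                                            cop = 1),
                           onset_s = c(head_vel = 0.025, head_acc = 0.030,
                                       cop = 0.045),
                           ramp_s = 0.02,
                           noise_sd = c(head_vel = 2, head_acc = 0.06,
                                        cop = 0.3),
                           direction_asymmetry = 1,
                           contamination_rate = 0.1,
                           mass_kg = 7,
                           analysis_rate = 1000,
                           pre_s = 0.5, post_s = 0.5,
                           pendulum_profile = "stabilizing",
                           seed = 1) {
  stopifnot(length(conditions) >= 1L,
            all(vapply(conditions, inherits, TRUE, "perturbation_spec")))
  if (contamination_rate < 0 || contamination_rate > 1) {
    stop("contamination_rate must lie in [0, 1]")
  }
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0")
  if (!all(is.finite(c(short_accel_gain, medium_vel_gain, channel_gain,
                       direction_asymmetry)))) {
    stop("gains must be finite")
  }
  structure(list(conditions = conditions, n_trials = n_trials,
                 animals = animals, short_accel_gain = short_accel_gain,
                 medium_vel_gain = medium_vel_gain,
                 channel_gain = channel_gain, onset_s = onset_s,
                 ramp_s = ramp_s, noise_sd = noise_sd,
                 direction_asymmetry = direction_asymmetry,
                 contamination_rate = contamination_rate, mass_kg = mass_kg,
                 analysis_rate = analysis_rate, pre_s = pre_s, post_s = post_s,
                 pendulum_profile = pendulum_profile, seed = seed),
            class = "generator_spec")
}

#' Footplate forces realising a target CoP trace
#'
#' Inverts the CoP equations: the lateral and fore-aft force differences
#' required by the target are split equally across the two plates of each
#' half, on top of an equal baseline load per plate. `compute_cop()` of the
#' result recovers the target exactly.
#'
#' @param cop_target Data frame with `time_s`, `cop_lat`, `cop_ap` (N/kg).
#' @param mass Animal mass, kg.
#' @param baseline_load Per-plate baseline load, N; defaults to a quarter of
#'   the animal's weight. Must be large enough to keep every force >= 0.
#' @return Data frame with `time_s`, `F_FL`, `F_FR`, `F_HL`, `F_HR`.
#' @export
generate_force_traces <- function(cop_target, mass,
                                  baseline_load = mass * 9.81 / 4) {
  if (baseline_load <= 0) stop("baseline_load must be > 0")
  dl <- mass * cop_target$cop_lat / 4   # left-right split per plate
  da <- mass * cop_target$cop_ap / 4    # front-hind split per plate
  f <- data.frame(time_s = cop_target$time_s,
                  F_FL = baseline_load + dl + da,
                  F_FR = baseline_load - dl + da,
                  F_HL = baseline_load + dl - da,
                  F_HR = baseline_load - dl - da)
  if (min(f$F_FL, f$F_FR, f$F_HL, f$F_HR) < 0) {
    stop("infeasible CoP target: a footplate force would be negative; ",
         "increase baseline_load")
  }
  f
}

# raised-cosine step from 0 to 1 over [t0, t0 + ramp] (unit step when ramp = 0)
.rc_step <- function(t, t0, ramp) {
  if (ramp <= 0) return(as.numeric(t >= t0))
  u <- (t - t0) / ramp
  ifelse(u <= 0, 0, ifelse(u >= 1, 1, (1 - cos(pi * u)) / 2))
}

# window-response basis: u1 occupies the short window, u2 the medium window,
# with complementary raised-cosine crossfades; returns the basis matrix and
# the plateau levels that make the grid window means hit (m_short, m_medium)
# exactly
.window_response <- function(time, onset, ramp, windows) {
  up1 <- .rc_step(time, onset, ramp)
  x12 <- .rc_step(time, windows$short[2], ramp)   # crossfade short -> medium
  dn2 <- .rc_step(time, windows$medium[2], ramp)  # fall at medium end
  u1 <- up1 * (1 - x12)
  u2 <- x12 * (1 - dn2)
  w1 <- time >= windows$short[1] & time < windows$short[2]
  w2 <- time >= windows$medium[1] & time < windows$medium[2]
  A <- rbind(c(mean(u1[w1]), mean(u2[w1])),
             c(mean(u1[w2]), mean(u2[w2])))
  list(u1 = u1, u2 = u2, A = A)
}

# deterministic per-condition base: analysis-grid time, platform velocity
# command, and (for roll) the stabilized head velocity from the pendulum model
.condition_base <- function(cond, spec) {
  key <- paste(cond$axis, cond$direction, cond$peak_accel, cond$peak_vel,
               cond$displacement, spec$analysis_rate, spec$pre_s, spec$post_s,
               spec$pendulum_profile, sep = "|")
  if (!is.null(.synth_cache[[key]])) return(.synth_cache[[key]])
  TT <- phase_durations(cond)$total
  rate <- spec$analysis_rate
  time <- seq(-round(spec$pre_s * rate), round((TT + spec$post_s) * rate)) / rate
  prof <- waveform_profile(cond)
  platform_vel <- prof$vel(time)
  head_vel_base <- if (cond$axis == "pitch") {
    platform_vel                      # ride-the-platform regime
  } else {
    # stabilized regime: head velocity from the dual-pendulum model, with the
    # magnitude-profile simulation cached across directions via the sign flip
    sgn <- direction_sign(cond$direction)
    mag_cond <- cond
    mag_cond$direction <- "leftward"
    traj <- simulate_pendulum(pendulum_profiles(spec$pendulum_profile),
                              drive_from_spec(mag_cond),
                              duration = round((TT + spec$post_s) * rate) / rate,
                              output_rate = rate)
    om2 <- traj$omega2 * 180 / pi
    sgn * c(rep(0, sum(time < 0)), om2[seq_len(sum(time >= 0))])
  }
  base <- list(time = time, platform_vel = platform_vel,
               head_vel_base = head_vel_base, motion_end = TT)
  assign(key, base, envir = .synth_cache)
  base
}

# derive a 32-bit per-trial seed from the master seed and trial counter
.trial_seed <- function(seed, counter) {
  (seed %% 65011) * 33029 + counter * 2 + 1
}

#' Generate a synthetic trial set
#'
#' For every (condition, animal, trial) triple, builds head kinematic channels
#' as delayed, noisy window responses superposed on the axis-appropriate base
#' (platform-following for pitch, pendulum-stabilized for roll), and footplate
#' forces whose CoP recovers the target CoP trace exactly. Plateau levels are
#' solved so that, before noise, the short- and medium-window means of each
#' response channel equal the injected targets exactly on the analysis grid.
#' Contaminated trials receive either baseline drift above the quiet-baseline
#' QC limit or a velocity spike above the head-shake limit; ground truth is
#' recorded per trial. Fully reproducible from the master seed via per-trial
#' counter-derived substreams.
#'
#' @param spec A [generator_spec()].
#' @return List of [trial_record()]s. Each trial carries a `truth` element
#'   (contamination flag and type, animal gain, injected window targets per
#'   channel); the set carries the spec and a truth summary data frame as
#'   attributes `"spec"` and `"truth"`.
#' @export
generate_trial_set <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  windows <- analysis_windows()
  roles <- c("head_vel", "head_acc", "cop")
  trials <- vector("list", length(spec$conditions) * nrow(spec$animals) *
                     spec$n_trials)
  truth_rows <- vector("list", length(trials))
  counter <- 0L
  for (ci in seq_along(spec$conditions)) {
    cond <- spec$conditions[[ci]]
    base <- .condition_base(cond, spec)
    time <- base$time
    sgn <- direction_sign(cond$direction)
    dir_gain <- if (sgn > 0) 1 else spec$direction_asymmetry
    # per-channel basis (channels differ only in onset)
    basis <- lapply(roles, function(role) {
      .window_response(time, spec$onset_s[[role]], spec$ramp_s, windows)
    })
    names(basis) <- roles
    ax <- axis_channels(cond$axis)
    for (ai in seq_len(nrow(spec$animals))) {
      an_id <- spec$animals$animal_id[ai]
      an_gain <- spec$animals$gain[ai]
      m_short_cop <- spec$short_accel_gain * cond$peak_accel * an_gain * dir_gain
      m_med_cop <- spec$medium_vel_gain * cond$peak_vel * an_gain * dir_gain
      for (k in seq_len(spec$n_trials)) {
        counter <- counter + 1L
        set.seed(.trial_seed(spec$seed, counter))
        contaminated <- stats::runif(1) < spec$contamination_rate
        contam_type <- if (contaminated) {
          sample(c("baseline-drift", "spike"), 1)
        } else {
          NA_character_
        }
        resp <- list(); targets <- list()
        for (role in roles) {
          cg <- spec$channel_gain[[role]]
          m1 <- sgn * cg * m_short_cop
          m2 <- sgn * cg * m_med_cop
          lv <- solve(basis[[role]]$A, c(m1, m2))
          resp[[role]] <- lv[1] * basis[[role]]$u1 + lv[2] * basis[[role]]$u2
          targets[[role]] <- c(short = m1, medium = m2)
        }
        noise <- function(role) stats::rnorm(length(time), 0,
                                             spec$noise_sd[[role]])
        angvel <- data.frame(pitch = noise("head_vel"),
                             roll = noise("head_vel"),
                             yaw = noise("head_vel"))
        linacc <- data.frame(fore_aft = noise("head_acc"),
                             lateral = noise("head_acc"),
                             vertical = noise("head_acc"))
        cop <- data.frame(time_s = time,
                          cop_lat = noise("cop"), cop_ap = noise("cop"))
        # superpose base + response on the axis-relevant channels
        if (cond$axis == "pitch") {
          angvel$pitch <- angvel$pitch + base$head_vel_base + resp$head_vel
          linacc$fore_aft <- linacc$fore_aft + resp$head_acc
          cop$cop_ap <- cop$cop_ap + resp$cop
        } else {
          angvel$roll <- angvel$roll + base$head_vel_base + resp$head_vel
          linacc$lateral <- linacc$lateral + resp$head_acc
          cop$cop_lat <- cop$cop_lat + resp$cop
        }
        if (contaminated) {
          axis_col <- if (cond$axis == "pitch") "pitch" else "roll"
          if (contam_type == "baseline-drift") {
            drift <- 25 + stats::runif(1, 0, 10)
            angvel[[axis_col]][time < 0] <-
              angvel[[axis_col]][time < 0] + drift
          } else {
            t_spike <- base$motion_end + stats::runif(1, 0.1, 0.4)
            in_spike <- time >= t_spike & time < t_spike + 0.02
            angvel[[axis_col]][in_spike] <-
              angvel[[axis_col]][in_spike] + 420 + stats::runif(1, 0, 60)
          }
        }
        forces <- generate_force_traces(cop, spec$mass_kg)
        trial <- trial_record(
          trial_id = sprintf("%s_c%02d_t%03d", an_id, ci, k),
          animal_id = an_id, condition = cond, time = time,
          head_angvel = angvel, head_linacc = linacc,
          forces = forces[c("F_FL", "F_FR", "F_HL", "F_HR")],
          mass = spec$mass_kg, motion_end = base$motion_end)
        trial$truth <- list(contaminated = contaminated,
                            contamination_type = contam_type,
                            animal_gain = an_gain, targets = targets)
        trials[[counter]] <- trial
        truth_rows[[counter]] <- data.frame(
          trial_id = trial$trial_id, animal_id = an_id, condition_index = ci,
          contaminated = contaminated, contamination_type = contam_type)
      }
    }
  }
  attr(trials, "spec") <- spec
  attr(trials, "truth") <- do.call(rbind, truth_rows)
  trials
}
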