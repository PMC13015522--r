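# Shared fixtures and independent oracles, built in code at test time.

# random feasible perturbation spec (draws until the trapezoid constraint holds)
random_feasible_spec <- function() {
  repeat {
    A <- runif(1, 100, 1500)
    V <- runif(1, 10, 80)
    D <- runif(1, 5, 20)
    if (V^2 / A <= D) {
      dirs <- c("forward", "backward", "leftward", "rightward")
      dir <- sample(dirs, 1)
      axis <- if (dir %in% c("forward", "backward")) "pitch" else "roll"
      return(perturbation_spec(axis, dir, A, V, D))
    }
  }
}

# brute-force onset scan: literal sample-by-sample walk of the RMS criterion
onset_scan_oracle <- function(time, x, baseline_window = c(-0.5, 0),
                              eps_floor = 1e-9) {
  bm <- mean(x[time >= baseline_window[1] & time < baseline_window[2]])
  thr <- max(sqrt(mean((x[time >= baseline_window[1] & time < baseline_window[2]] - bm)^2)),
             eps_floor)
  for (i in seq_along(time)) {
    if (time[i] >= 0 && abs(x[i] - bm) > thr) return(time[i] * 1000)
  }
  NA_real_
}

# exhaustive pair-enumeration oracle for the asymmetry index (symmetric MAPE)
asymmetry_oracle <- function(dir1, dir2) {
  mape_sym <- function(a, b) 100 * mean(abs(a - b)) / ((mean(abs(a)) + mean(abs(b))) / 2)
  enum <- function(traces) {
    out <- c()
    n <- length(traces)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j > i) out <- c(out, mape_sym(traces[[i]], traces[[j]]))
      }
    }
    out
  }
  within <- c(enum(dir1), enum(dir2))
  pooled <- c(dir1, lapply(dir2, function(x) -x))
  across <- enum(pooled)
  mean(across) - mean(within)
}

# small generator spec for one mirrored roll condition pair
mirrored_roll_spec <- function(n_trials = 20, seed = 1, asym = 1,
                               contamination = 0, noise = NULL) {
  conds <- list(perturbation_spec("roll", "leftward", 500, 40),
                perturbation_spec("roll", "rightward", 500, 40))
  args <- list(conditions = conds, n_trials = n_trials,
               animals = data.frame(animal_id = "E", gain = 1),
               direction_asymmetry = asym, contamination_rate = contamination,
               seed = seed)
  if (!is.null(noise)) args$noise_sd <- noise
  do.call(generator_spec, args)
}

# quiet synthetic trial on a standard grid, for QC and metric tests
quiet_trial <- function(cond = perturbation_spec("pitch", "forward", 500, 40),
                        pitch = NULL, rate = 1000) {
  TT <- phase_durations(cond)$total
  time <- seq(-500, round((TT + 0.5) * rate)) / rate
  n <- length(time)
  zeros <- rep(0, n)
  if (is.null(pitch)) pitch <- zeros
  trial_record(
    trial_id = "t1", animal_id = "E", condition = cond, time = time,
    head_angvel = data.frame(pitch = pitch, roll = zeros, yaw = zeros),
    head_linacc = data.frame(fore_aft = zeros, lateral = zeros, vertical = zeros),
    forces = data.frame(F_FL = rep(17, n), F_FR = rep(17, n),
                        F_HL = rep(17, n), F_HR = rep(17, n)),
    mass = 7)
}
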