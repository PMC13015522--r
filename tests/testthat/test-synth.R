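# Synthetic-trial generator: force/CoP inversion, injected ground truth,
# contamination bookkeeping, determinism.

test_that("force synthesis inverts the CoP equations exactly", {
  set.seed(151)
  t <- seq(0, 0.3, by = 1e-3)
  target <- data.frame(time_s = t,
                       cop_lat = rnorm(length(t), 0, 0.5),
                       cop_ap = rnorm(length(t), 0, 0.5))
  f <- generate_force_traces(target, mass = 7)
  back <- compute_cop(f, mass = 7)
  expect_equal(back$cop_lat, target$cop_lat, tolerance = 1e-12)
  expect_equal(back$cop_ap, target$cop_ap, tolerance = 1e-12)
})

test_that("zero and lateral-only CoP targets give the expected force structure", {
  t <- seq(0, 0.1, by = 1e-2)
  zero <- data.frame(time_s = t, cop_lat = 0, cop_ap = 0)
  f0 <- generate_force_traces(zero, mass = 8)
  expect_equal(f0$F_FL, f0$F_FR)
  expect_equal(f0$F_FL, f0$F_HL)
  expect_equal(unique(f0$F_FL), 8 * 9.81 / 4)
  lat <- data.frame(time_s = t, cop_lat = sin(t * 10), cop_ap = 0)
  fl <- generate_force_traces(lat, mass = 8)
  expect_equal(fl$F_FL, fl$F_HL, tolerance = 1e-12)   # front/hind symmetric
  b <- 8 * 9.81 / 4
  expect_equal(fl$F_FL - b, -(fl$F_FR - b), tolerance = 1e-12)  # left/right antisymmetric
})

test_that("infeasible CoP targets raise an error instead of negative forces", {
  t <- c(0, 0.01)
  big <- data.frame(time_s = t, cop_lat = 100, cop_ap = 0)
  expect_error(generate_force_traces(big, mass = 7), "infeasible")
  expect_error(generate_force_traces(big, mass = 7, baseline_load = -1),
               "baseline_load")
})

test_that("noiseless trials hit the injected window amplitudes exactly", {
  conds <- list(perturbation_spec("pitch", "forward", 500, 40))
  zero_noise <- c(head_vel = 0, head_acc = 0, cop = 0)
  # default smooth construction: solved plateau levels make grid window means exact
  gs <- generator_spec(conditions = conds, n_trials = 1,
                       animals = data.frame(animal_id = "E", gain = 1),
                       noise_sd = zero_noise, contamination_rate = 0, seed = 5)
  tr <- generate_trial_set(gs)[[1]]
  ch <- trial_channels(tr)
  w <- analysis_windows()
  expect_equal(window_mean(ch$time, ch$cop_ap, w$short),
               gs$short_accel_gain * 500, tolerance = 1e-10)
  expect_equal(window_mean(ch$time, ch$cop_ap, w$medium),
               gs$medium_vel_gain * 40, tolerance = 1e-10)
  # crisp mode (onset 0, no ramp): plateau equals the amplitude everywhere
  gs0 <- generator_spec(conditions = conds, n_trials = 1,
                        animals = data.frame(animal_id = "E", gain = 1),
                        noise_sd = zero_noise, contamination_rate = 0,
                        onset_s = c(head_vel = 0, head_acc = 0, cop = 0),
                        ramp_s = 0, seed = 5)
  tr0 <- generate_trial_set(gs0)[[1]]
  ch0 <- trial_channels(tr0)
  expect_equal(window_mean(ch0$time, ch0$cop_ap, w$short),
               gs$short_accel_gain * 500, tolerance = 1e-12)
  short_mask <- ch0$time >= 0 & ch0$time < 0.1
  expect_equal(unique(round(ch0$cop_ap[short_mask], 12)),
               gs$short_accel_gain * 500)
})

test_that("animal offsets and direction asymmetry scale the injected response", {
  conds <- list(perturbation_spec("roll", "leftward", 500, 40),
                perturbation_spec("roll", "rightward", 500, 40))
  gs <- generator_spec(conditions = conds, n_trials = 1,
                       animals = data.frame(animal_id = c("E", "B"),
                                            gain = c(1, 0.5)),
                       noise_sd = c(head_vel = 0, head_acc = 0, cop = 0),
                       contamination_rate = 0, direction_asymmetry = 2,
                       seed = 9)
  trials <- generate_trial_set(gs)
  w <- analysis_windows()
  sm <- vapply(trials, function(tr) {
    ch <- trial_channels(tr)
    window_mean(ch$time, ch$cop_lat, w$short)
  }, 0)
  base <- gs$short_accel_gain * 500
  # order: (left, E), (left, B), (right, E), (right, B)
  expect_equal(sm, c(base, 0.5 * base, -2 * base, -base), tolerance = 1e-10)
})

test_that("pitch trials ride the platform and roll trials are stabilized", {
  conds <- list(perturbation_spec("pitch", "forward", 500, 40),
                perturbation_spec("roll", "leftward", 500, 40))
  gs <- generator_spec(conditions = conds, n_trials = 1,
                       animals = data.frame(animal_id = "E", gain = 1),
                       noise_sd = c(head_vel = 0, head_acc = 0, cop = 0),
                       channel_gain = c(head_vel = 0, head_acc = 0, cop = 1),
                       contamination_rate = 0, seed = 3)
  trials <- generate_trial_set(gs)
  pitch <- trials[[1]]; roll <- trials[[2]]
  prof <- waveform_profile(conds[[1]])
  expect_equal(pitch$head_angvel$pitch, prof$vel(pitch$time), tolerance = 1e-9)
  # stabilized roll base stays well below the platform peak velocity
  expect_lt(max(abs(roll$head_angvel$roll)), 40)
  expect_gt(max(abs(roll$head_angvel$roll)), 0)
})

test_that("contaminated trials are exactly the ones QC excludes", {
  conds <- list(perturbation_spec("pitch", "forward", 500, 40))
  gs <- generator_spec(conditions = conds, n_trials = 200,
                       animals = data.frame(animal_id = "E", gain = 1),
                       contamination_rate = 0.1, seed = 33)
  trials <- generate_trial_set(gs)
  truth <- attr(trials, "truth")
  qc <- vapply(trials, function(tr) qc_trial(tr)$keep, TRUE)
  expect_identical(!qc, truth$contaminated)
  # contamination fraction is near its target
  expect_lt(abs(mean(truth$contaminated) - 0.1),
            3 * sqrt(0.1 * 0.9 / 200))
})

test_that("generation is byte-identical under a fixed seed", {
  gs <- mirrored_roll_spec(n_trials = 3, seed = 77, contamination = 0.2)
  t1 <- generate_trial_set(gs)
  t2 <- generate_trial_set(gs)
  expect_identical(t1, t2)
  t3 <- generate_trial_set(mirrored_roll_spec(n_trials = 3, seed = 78,
                                              contamination = 0.2))
  expect_false(identical(t1[[1]]$head_angvel, t3[[1]]$head_angvel))
})

test_that("generator validation rejects out-of-range parameters", {
  expect_error(generator_spec(contamination_rate = 1.5), "contamination_rate")
  expect_error(generator_spec(noise_sd = c(head_vel = -1, head_acc = 0,
                                           cop = 0)), "noise_sd")
})
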