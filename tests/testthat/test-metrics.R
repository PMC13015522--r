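# Window means, onset latency, displacement integrals, averaging and pooling.

test_that("window means average half-open windows", {
  t <- seq(0, 0.999, by = 1e-3)
  expect_equal(window_mean(t, rep(3.5, 1000), c(0, 0.1)), 3.5)
  # ramp 0..100 over [0, 100) ms at 1 kHz: samples 0..99 -> mean 49.5
  ramp <- 1000 * t
  expect_equal(window_mean(t, ramp, c(0, 0.1)), 49.5)
  # zero before 100 ms, 5 after
  x <- ifelse(t < 0.1, 0, 5)
  expect_equal(window_mean(t, x, c(0.1, 0.2)), 5)
  expect_error(window_mean(t, ramp, c(2, 3)), "empty window")
})

test_that("window_mean is affine-equivariant", {
  set.seed(2)
  t <- seq(-0.5, 0.5, by = 1e-3)
  x <- rnorm(length(t))
  for (w in list(c(0, 0.1), c(0.1, 0.2), c(-0.3, -0.1))) {
    expect_equal(window_mean(t, 3 * x + 2, w),
                 3 * window_mean(t, x, w) + 2, tolerance = 1e-12)
  }
})

test_that("onset latency detects a noiseless step at its onset", {
  t <- seq(-0.5, 0.5, by = 1e-3)
  x <- ifelse(t >= 0.03, 1, 0)
  expect_equal(as.numeric(onset_latency(t, x)), 30)
  expect_true(is.na(onset_latency(t, rep(0, length(t)))))
  # nonzero but flat trace: deviation from baseline mean never exceeds floor
  expect_true(is.na(onset_latency(t, rep(2.5, length(t)))))
})

test_that("onset latency matches the brute-force scan on seeded noisy traces", {
  set.seed(99)
  t <- seq(-0.5, 0.3, by = 1e-3)
  for (i in 1:200) {
    x <- rnorm(length(t))
    slope <- runif(1, 2, 30)
    x[t >= 0] <- x[t >= 0] + slope * t[t >= 0]
    expect_identical(as.numeric(onset_latency(t, x)), onset_scan_oracle(t, x))
  }
})

test_that("requiring consecutive suprathreshold samples suppresses single-sample blips", {
  t <- seq(-0.5, 0.5, by = 1e-3)
  x <- rep(0, length(t))
  x[t >= -0.5 & t < 0] <- rnorm(500, 0, 1)
  x[which(t >= 0.02)[1]] <- 50          # isolated blip
  x[t >= 0.2] <- 50                     # sustained response
  lat1 <- onset_latency(t, x)
  lat3 <- onset_latency(t, x, consecutive = 3)
  expect_equal(as.numeric(lat1), 20)
  expect_equal(as.numeric(lat3), 200)
})

test_that("platform waveforms reproduce their design displacement", {
  for (cs in enumerate_conditions(directions = "forward")) {
    prof <- waveform_profile(cs)
    TT <- phase_durations(cs)$total
    t <- seq(0, ceiling(TT * 1000)) / 1000
    d <- displacement_integrals(t, angvel = prof$vel(t), span = c(0, max(t)))
    expect_equal(d$angular_deg, 10, tolerance = 1e-3)
  }
  # base profile: all breakpoints on-grid, integral exact
  base <- perturbation_spec("pitch", "forward", 500, 40)
  prof <- waveform_profile(base)
  t <- seq(0, 0.33, by = 1e-3)
  d <- displacement_integrals(t, angvel = prof$vel(t), span = c(0, 0.33))
  expect_equal(d$angular_deg, 10, tolerance = 1e-9)
})

test_that("displacement integrals handle zero traces and constant acceleration", {
  t <- seq(0, 0.5, by = 1e-3)
  z <- displacement_integrals(t, angvel = rep(0, 501), linacc = rep(0, 501),
                              cop = rep(0, 501), span = c(0, 0.5))
  expect_equal(unlist(z), c(angular_deg = 0, linear_m = 0, cop_path = 0))
  a <- displacement_integrals(t, linacc = rep(2, 501), span = c(0, 0.5))
  expect_equal(a$linear_m, 2 * 0.5^2 / 2, tolerance = 1e-9)
  expect_error(displacement_integrals(t, angvel = rep(1, 501), span = c(0, 2)),
               "span mismatch")
})

test_that("CoP path length dominates the net CoP change", {
  set.seed(21)
  t <- seq(0, 0.33, by = 1e-3)
  for (i in 1:20) {
    cop <- cumsum(rnorm(length(t), 0, 0.05))
    d <- displacement_integrals(t, cop = cop, span = c(0, 0.33))
    expect_gte(d$cop_path, abs(cop[length(cop)] - cop[1]) - 1e-12)
  }
})

test_that("condition averages give pointwise means and SEMs", {
  tr0 <- quiet_trial()
  tr2 <- quiet_trial()
  tr2$head_angvel$pitch <- rep(2, length(tr2$time))
  avg <- average_condition(list(tr0, tr2))
  expect_equal(unique(avg$mean$pitch_vel), 1)
  expect_equal(unique(avg$sem$pitch_vel), 1)
  expect_equal(avg$n_trials, 2)
  # n identical trials: mean = trial, SEM = 0
  avg1 <- average_condition(list(tr2, tr2, tr2))
  expect_equal(avg1$mean$pitch_vel, tr2$head_angvel$pitch)
  expect_equal(unique(avg1$sem$pitch_vel), 0)
  # single trial: SEM defined as 0
  expect_equal(unique(average_condition(list(tr0))$sem$pitch_vel), 0)
  # mixed conditions refuse to average
  tr3 <- quiet_trial(perturbation_spec("pitch", "backward", 500, 40))
  expect_error(average_condition(list(tr0, tr3)), "mixed conditions")
})

test_that("condition-averaged synthetic trials track the generator mean", {
  gs <- mirrored_roll_spec(n_trials = 20, seed = 31)
  trials <- generate_trial_set(gs)
  left <- trials[1:20]
  avg <- average_condition(left)
  # noiseless reference trace = regenerate with zero noise
  gs0 <- mirrored_roll_spec(n_trials = 1, seed = 31,
                            noise = c(head_vel = 0, head_acc = 0, cop = 0))
  ref <- generate_trial_set(gs0)[[1]]
  m <- avg$mean$cop_lat
  s <- pmax(avg$sem$cop_lat, 1e-9)
  ref_cop <- trial_channels(ref)$cop_lat
  frac_within <- mean(abs(m - ref_cop) <= 3 * s)
  expect_gte(frac_within, 0.99)
})

test_that("mirrored directions pool with inversion: 20 + 20 -> 40", {
  gs <- mirrored_roll_spec(n_trials = 20, seed = 13)
  trials <- generate_trial_set(gs)
  left <- trials[1:20]; right <- trials[21:40]
  pooled <- invert_and_pool(left, right)
  expect_length(pooled, 40)
  expect_true(all(vapply(pooled, function(tr) tr$condition$direction, "") ==
                    "leftward"))
  # an empty side returns the other unchanged, with a warning
  expect_warning(one_sided <- invert_and_pool(left, list()), "no trials")
  expect_length(one_sided, 20)
})

test_that("pooling inverts direction-odd channels so signed responses align", {
  gs <- mirrored_roll_spec(n_trials = 4, seed = 17,
                           noise = c(head_vel = 0, head_acc = 0, cop = 0))
  trials <- generate_trial_set(gs)
  left <- trials[1:4]; right <- trials[5:8]
  # raw right-side CoP is negative-signed; after pooling it matches the left
  raw_right <- trial_channels(right[[1]])$cop_lat
  pooled <- invert_and_pool(left, right)
  flipped <- trial_channels(pooled[[5]])$cop_lat
  expect_equal(flipped, -raw_right, tolerance = 1e-12)
  expect_equal(flipped, trial_channels(left[[1]])$cop_lat, tolerance = 1e-12)
  # non-mirror conditions refuse to pool
  other <- generate_trial_set(generator_spec(
    conditions = list(perturbation_spec("roll", "rightward", 500, 60)),
    n_trials = 2, animals = data.frame(animal_id = "E", gain = 1),
    contamination_rate = 0, seed = 1))
  expect_error(invert_and_pool(left, other), "non-mirror")
})

test_that("the tidy metrics table carries one row per trial and channel", {
  gs <- mirrored_roll_spec(n_trials = 3, seed = 23)
  trials <- generate_trial_set(gs)
  m <- metrics_table(trials)
  expect_equal(nrow(m), length(trials) * 3)
  expect_setequal(unique(m$channel), c("head_vel", "head_acc", "cop"))
  expect_false(anyNA(m$short_mean))
})
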