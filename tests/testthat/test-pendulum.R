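# Dual-pendulum model: torque equations, closed-form equilibrium, integration.

test_that("torques evaluate the printed expressions", {
  p <- pendulum_params(m1 = 1, l1 = 1, I1 = 1, I2 = 1, k_platform = 90,
                       c_platform = 0, k_neck = 5, c_neck = 0, g = 10)
  zero <- list(theta1 = 0, theta2 = 0, omega1 = 0, omega2 = 0)
  expect_equal(unname(compute_torques(zero, 0, 0, p)), c(0, 0))
  # m1*g*l1 = 10, k_platform = 90, theta1 = 0.09, phi = 0.1, rates 0:
  # tau1 = -10*0.09 - 90*(-0.01) = 0
  s <- list(theta1 = 0.09, theta2 = 0.09, omega1 = 0, omega2 = 0)
  expect_equal(compute_torques(s, 0.1, 0, p)[["tau1"]], 0)
  # k_neck = 5, theta2 - theta1 = 0.2 -> tau2 = -1
  s2 <- list(theta1 = 0, theta2 = 0.2, omega1 = 0, omega2 = 0)
  expect_equal(compute_torques(s2, 0, 0, p)[["tau2"]], -1)
})

test_that("static equilibrium solves tau1 = tau2 = 0", {
  p <- pendulum_params(m1 = 1, l1 = 1, I1 = 1, I2 = 1, k_platform = 90,
                       c_platform = 1, k_neck = 5, c_neck = 1, g = 10)
  eq <- static_equilibrium(p, 0.1)
  expect_equal(unname(eq[c("theta1", "theta2")]), c(0.09, 0.09))
  expect_equal(unname(static_equilibrium(p, 0)), rep(0, 4))
  p0 <- pendulum_params(m1 = 1, l1 = 1, I1 = 1, I2 = 1, k_platform = 0,
                        c_platform = 1, k_neck = 5, c_neck = 1, g = 10)
  expect_equal(static_equilibrium(p0, 0.3)[["theta1"]], 0)
})

test_that("equilibrium residual is zero for random parameters", {
  set.seed(7)
  for (i in 1:20) {
    p <- pendulum_params(m1 = runif(1, 1, 10), l1 = runif(1, 0.05, 0.5),
                         I1 = runif(1, 0.05, 1), I2 = runif(1, 0.005, 0.1),
                         k_platform = runif(1, 0, 300),
                         c_platform = runif(1, 0, 30),
                         k_neck = runif(1, 0, 100), c_neck = runif(1, 0, 10))
    phi0 <- runif(1, -0.3, 0.3)
    tau <- compute_torques(as.list(static_equilibrium(p, phi0)), phi0, 0, p)
    expect_lt(max(abs(tau)), 1e-12)
  }
})

test_that("zero drive from rest stays at rest", {
  traj <- simulate_pendulum(pendulum_profiles("stabilizing"), drive_step(0),
                            duration = 1)
  expect_equal(max(abs(as.matrix(traj[-1]))), 0)
})

test_that("a damped step drive converges to the closed-form equilibrium", {
  p <- pendulum_profiles("stabilizing")
  traj <- simulate_pendulum(p, drive_step(0.1), duration = 6)
  eq <- static_equilibrium(p, 0.1)
  expect_lt(abs(tail(traj$theta1, 1) - eq[["theta1"]]), 1e-6)
  expect_lt(abs(tail(traj$theta2, 1) - eq[["theta2"]]), 1e-6)
  expect_lt(abs(tail(traj$omega1, 1)), 1e-6)
})

test_that("undamped, undriven trunk conserves mechanical energy", {
  p <- pendulum_params(m1 = 4.5, l1 = 0.18, I1 = 0.2, I2 = 0.01,
                       k_platform = 50, c_platform = 0, k_neck = 0, c_neck = 0)
  init <- c(theta1 = 0.1, theta2 = 0, omega1 = 0, omega2 = 0)
  traj <- simulate_pendulum(p, drive_step(0), init = init, duration = 5)
  keff <- p$m1 * p$g * p$l1 + p$k_platform
  E <- 0.5 * p$I1 * traj$omega1^2 + 0.5 * keff * traj$theta1^2
  expect_lt(diff(range(E)) / E[1], 1e-6)
})

test_that("the linear system responds linearly to drive scaling", {
  p <- pendulum_profiles("platform-following")
  spec <- perturbation_spec("pitch", "forward", 500, 40)
  d1 <- drive_from_spec(spec)
  d2 <- platform_drive(phi = function(t) 2 * d1$phi(t),
                       phidot = function(t) 2 * d1$phidot(t))
  t1 <- simulate_pendulum(p, d1, duration = 0.8)
  t2 <- simulate_pendulum(p, d2, duration = 0.8)
  expect_equal(t2$theta1, 2 * t1$theta1, tolerance = 1e-6)
  expect_equal(t2$theta2, 2 * t1$theta2, tolerance = 1e-6)
})

test_that("output grids at 1x and 2x rate agree at shared times", {
  p <- pendulum_profiles("stabilizing")
  spec <- perturbation_spec("roll", "leftward", 500, 40)
  a <- simulate_pendulum(p, drive_from_spec(spec), duration = 0.8,
                         output_rate = 500)
  b <- simulate_pendulum(p, drive_from_spec(spec), duration = 0.8,
                         output_rate = 1000)
  shared <- match(round(a$time_s * 1000), round(b$time_s * 1000))
  expect_lt(max(abs(a$theta1 - b$theta1[shared])), 1e-6)
  expect_lt(max(abs(a$theta2 - b$theta2[shared])), 1e-6)
})

test_that("stiffening the neck locks the head to the trunk", {
  base <- pendulum_profiles("platform-following")
  spec <- perturbation_spec("pitch", "forward", 500, 40)
  dev <- vapply(c(1, 100, 1e4), function(k) {
    p <- pendulum_params(base$m1, base$l1, base$I1, base$I2,
                         base$k_platform, base$c_platform, k, base$c_neck)
    traj <- simulate_pendulum(p, drive_from_spec(spec), duration = 0.6)
    max(abs(traj$theta2 - traj$theta1))
  }, 0)
  expect_true(all(diff(dev) < 0))
})

test_that("stiff, damped platform coupling makes the trunk follow the platform", {
  spec <- perturbation_spec("pitch", "forward", 500, 40)
  drive <- drive_from_spec(spec)
  dev_for_k <- function(k, cc) {
    p <- pendulum_params(4.5, 0.18, 0.2, 0.01, k, cc, 10, 1)
    traj <- simulate_pendulum(p, drive, duration = 0.6)
    max(abs(traj$theta1 - drive$phi(traj$time_s)))
  }
  expect_lt(dev_for_k(1e4, 100) / dev_for_k(10, 1), 0.05)
})

test_that("validation rejects bad parameters and durations", {
  expect_error(pendulum_params(-1, 1, 1, 1, 1, 1, 1, 1), "m1")
  expect_error(pendulum_params(1, 1, 1, 1, -1, 1, 1, 1), "k_platform")
  expect_error(simulate_pendulum(pendulum_profiles(), drive_step(0),
                                 duration = -1), "duration")
})
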