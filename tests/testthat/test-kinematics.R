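test_that("terminal speed is exact on affine depth records", {
  t <- seq(0, 10, 0.05)
  est <- estimate_terminal_speed(trajectory(t, x = 0, z = 10 * t))
  expect_equal(est$speed, 10)
  # lateral flutter must not matter
  est2 <- estimate_terminal_speed(
    trajectory(t, x = 3 * sin(2 * pi * 1.5 * t), z = 10 * t))
  expect_equal(est2$speed, 10)
})

test_that("terminal speed recovers the analytic transient trajectory", {
  t <- seq(0, 10, 0.02); v <- 12; tau <- 0.5
  z <- v * (t - tau * (1 - exp(-t / tau)))
  est <- estimate_terminal_speed(trajectory(t, 0, z))
  expect_equal(est$speed, v, tolerance = 0.01)
  expect_gt(est$steady_window[1], 0) # transient excluded
})

test_that("degenerate and invalid trajectories raise typed errors", {
  t <- seq(0, 10, 0.05)
  expect_error(estimate_terminal_speed(trajectory(t, 0, rep(5, length(t)))),
               "non-terminal")
  expect_error(trajectory(1:5, 0, 1:5), "20 samples")
  expect_error(trajectory(rev(t), 0, t), "strictly increasing")
  expect_error(trajectory(t, c(NA, rep(0, length(t) - 1)), t), "finite")
})

test_that("speed recovery across simulated trajectories is accurate", {
  errs <- vapply(1:60, function(s) {
    v <- 8 + (s %% 5)
    tr <- simulate_trajectory(v, seed = s)
    abs(estimate_terminal_speed(tr)$speed - v) / v
  }, 0)
  expect_lt(median(errs), 0.02)
})

test_that("trial aggregation reproduces sampling theory", {
  agg <- aggregate_trials(c(10, 10, 10))
  expect_equal(agg$mean_speed, 10)
  expect_equal(agg$sem, 0)

  set.seed(3)
  speeds <- rnorm(25, mean = 10, sd = 1.5)
  agg2 <- aggregate_trials(speeds)
  # (sigma/mu)/sqrt(n) = 0.15/5 = 3% relative error on the mean
  # (sampling noise of the sd itself allows ~1 point of slack)
  expect_equal(agg2$relative_sem, 0.03, tolerance = 1 / 3)
  expect_equal(agg2$sem, sd(speeds) / 5)

  agg3 <- aggregate_trials(rep(8.5, 5), control_mean = 10)
  expect_equal(agg3$relative_speed, 0.85)
  expect_error(aggregate_trials(numeric(0)), "no trial")
})

test_that("Reynolds bookkeeping follows Re = v D / nu", {
  expect_equal(reynolds_number(0.01), 100)
  expect_equal(reynolds_number(0), 0)
  expect_equal(reynolds_number(0.02), 200)
  ctx <- fluid_context(kinematic_viscosity = 2e-6,
                       characteristic_size = 0.02)
  expect_equal(reynolds_number(0.01, ctx), 100)
  expect_error(reynolds_number(-1), "non-negative")
  # the aggregate carries Re of the mean speed (mm/s -> m/s)
  expect_equal(aggregate_trials(c(10, 10))$reynolds, 100)
})
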