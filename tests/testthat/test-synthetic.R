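test_that("the settling model encodes the two-regime calibration", {
  expect_equal(settling_speed_model(1, 0), 1)
  expect_equal(settling_speed_model(0.9, 0.2), 0.90)
  # below threshold the model is flat in L
  expect_equal(settling_speed_model(0.6, 0.05),
               settling_speed_model(0.6, 0.35))
  expect_equal(settling_speed_model(0.6, 0.05), 0.775)
  # high branch clipped to +-10% of the control
  expect_gte(settling_speed_model(0.99, 0.4), 0.9)
  expect_error(settling_speed_model(1.2, 0), "S must")
  expect_error(settling_speed_model(0.9, 1), "L must")
  # logistic blend stays between the branches
  v <- settling_speed_model(0.75, 0.1, blend = TRUE)
  expect_gt(v, 0.775); expect_lt(v, 1)
})

test_that("trajectory simulation is seeded and recovers its input", {
  a <- simulate_trajectory(10, seed = 5)
  b <- simulate_trajectory(10, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a$z_mm, simulate_trajectory(10, seed = 6)$z_mm))

  # noiseless, short transient: slope equals the true speed
  cfg <- trajectory_sim_config(transient_tau = 0.01,
                               position_noise_sd = 0)
  tr <- simulate_trajectory(10, cfg)
  expect_equal(estimate_terminal_speed(tr)$speed, 10, tolerance = 1e-3)

  tr2 <- simulate_trajectory(10, seed = 1)
  expect_equal(estimate_terminal_speed(tr2)$speed, 10, tolerance = 0.02)

  expect_error(trajectory_sim_config(duration = 1, transient_tau = 0.5),
               "duration")
})

test_that("a synthetic study is internally consistent", {
  st <- make_synthetic_study(n_random = 3, trials_per_shape = 4, seed = 11)
  # 1 control + 10 ideal + 6 parametric + 3 random
  expect_length(st$shapes, 20)
  expect_equal(nrow(st$truth), 20)
  expect_equal(nrow(st$trajectories), 20 * 4 * 501)

  ctrl <- st$truth[st$truth$shape_id == "disc_control", ]
  expect_equal(ctrl$true_relative_speed, 1)
  expect_equal(ctrl$true_speed, 10)

  for (o in st$shapes)
    expect_equal(polygon_area(o), 100, tolerance = 1e-9)

  # truth obeys the model for every non-control shape
  rest <- st$truth[st$truth$shape_id != "disc_control", ]
  expect_equal(rest$true_relative_speed,
               settling_speed_model(rest$S, rest$L, st$params))

  st2 <- make_synthetic_study(n_random = 3, trials_per_shape = 4, seed = 11)
  expect_identical(st$trajectories, st2$trajectories)
})

test_that("25 trials at CV 0.15 pin the mean within about 3%", {
  rel_sems <- vapply(1:12, function(i) {
    base <- leafsettle:::shape_seed(0, i)
    speeds <- leafsettle:::with_preserved_seed(base, {
      rnorm(25, mean = 10, sd = 1.5)
    })
    aggregate_trials(speeds)$relative_sem
  }, 0)
  expect_equal(mean(rel_sems), 0.03, tolerance = 0.2)
})
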