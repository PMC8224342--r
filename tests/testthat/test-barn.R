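test_that("config invariants reject impossible barns", {
  expect_s3_class(barn_config(), "barn_config")
  expect_error(barn_config(n_sows = 12), "does not fit")
  expect_error(barn_config(inlet_temp_c = 39), "cooler than the sow")
  expect_error(barn_config(sow_area_m2 = -1), "positive")
  expect_error(barn_config(noise_sd_temp_c = -0.1), "non-negative")
})

test_that("simulation is deterministic given the seed", {
  a <- simulate_barn(seed = 7)
  b <- simulate_barn(seed = 7)
  expect_identical(a$sows, b$sows)
  expect_identical(a$samples, b$samples)
  c <- simulate_barn(seed = 8)
  expect_false(identical(a$samples$temp_c, c$samples$temp_c))
})

test_that("air warms monotonically along the sow row and stays in the contour bounds", {
  sim <- simulate_barn(seed = 1)
  expect_equal(nrow(sim$sows), 10)
  expect_true(all(diff(sim$sows$zone_temp_c) > 0))
  cfg <- sim$config
  expect_true(all(sim$sows$temp_c >= cfg$inlet_temp_c &
                    sim$sows$temp_c <= cfg$max_temp_c))
  expect_true(all(sim$samples$temp_c >= cfg$inlet_temp_c &
                    sim$samples$temp_c <= cfg$max_temp_c))
  expect_true(all(sim$sows$vel_ms >= 0 &
                    sim$sows$vel_ms <= cfg$outlet_velocity_ms))
  expect_true(all(sim$sows$rh_pct == cfg$inlet_rh_pct))
})

test_that("the marching scheme conserves energy to within 1% absent clamping", {
  sim <- simulate_barn(seed = 1)
  expect_false(sim$clamped)
  carried <- sim$mass_flow_kg_s * sim$config$cp_j_kg_k *
    (sim$exit_temp_c - sim$config$inlet_temp_c)
  expect_lt(abs(sum(sim$sows$q_conv_w) - carried) / sum(sim$sows$q_conv_w),
            0.01)
})

test_that("dissipation decreases along the row: cool fast air near the inlet removes more heat", {
  sim <- simulate_barn(seed = 1)
  expect_true(all(diff(sim$sows$q_conv_w) < 0))
  expect_true(all(sim$sows$q_conv_w > 0))
})

test_that("noise-free runs collapse the sampling points onto the zone values", {
  cfg <- barn_config(noise_sd_temp_c = 0, noise_sd_vel_ms = 0)
  sim <- simulate_barn(cfg, seed = 1)
  expect_equal(sim$sows$temp_c, sim$sows$zone_temp_c, tolerance = 1e-12)
  expect_equal(sim$sows$vel_ms, sim$sows$zone_vel_ms, tolerance = 1e-12)
})

test_that("local states are component-wise means of the four sampling points", {
  sim <- simulate_barn(seed = 3)
  pts <- sim$samples[sim$samples$sow_index == 4, ]
  expect_equal(nrow(pts), 4)
  st <- sample_local_state(pts)
  expect_equal(st$temp_c, mean(pts$temp_c))
  expect_equal(st$vel_ms, mean(pts$vel_ms))
  expect_equal(st$rh_pct, 60)
  # identical points average to themselves
  same <- pts[rep(1, 4), ]
  expect_equal(sample_local_state(same)$temp_c, pts$temp_c[1])
  # symmetric perturbations cancel
  sym <- data.frame(temp_c = 31 + c(-0.2, 0.2, -0.05, 0.05),
                    rh_pct = 60, vel_ms = 0.5 + c(-0.01, 0.01, 0, 0))
  expect_equal(sample_local_state(sym)$temp_c, 31)
  expect_equal(sample_local_state(sym)$vel_ms, 0.5)
})

test_that("local velocities span the inlet-jet-to-still-air gradient", {
  sim <- simulate_barn(seed = 1)
  expect_true(all(diff(sim$sows$zone_vel_ms) < 0))
  expect_gt(sim$sows$zone_vel_ms[1], 0.5)
  expect_lt(sim$sows$zone_vel_ms[10], 0.25)
})
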