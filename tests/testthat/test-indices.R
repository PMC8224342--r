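test_that("the twelve indices carry the right input requirements", {
  expect_length(index_ids(), 12)
  expect_setequal(index_ids()[sapply(index_ids(), index_uses_velocity)],
                  c("ET", "ETIS"))
  expect_setequal(index_ids()[sapply(index_ids(), index_uses_pressure)],
                  "H")
})

test_that("index formulas reproduce the published winter references and spot values", {
  # winter barn: 10 degC, 60% RH, still air
  expect_equal(compute_index("ET", 10, 60, vel_ms = 0), 21.2,
               tolerance = 0.05 / 21.2)
  expect_equal(compute_index("ETIS", 10, 60, vel_ms = 0), 18.6,
               tolerance = 0.1 / 18.6)
  # THI2(22, 70) = 17.6 + 5.32 + 46.4
  expect_equal(compute_index("THI2", 22, 70), 69.32, tolerance = 1e-9)
  # H with no humidity reduces to its dry-air term
  expect_equal(compute_index("H", 46, 0), 1.006 * 46)
  expect_equal(compute_index("H", 46, 0), 46.276, tolerance = 1e-9)
})

test_that("ET correction terms vanish at RH 50% and v 0.2 m/s", {
  for (t in c(10, 22, 30, 40))
    expect_equal(compute_index("ET", t, 50, vel_ms = 0.2), t,
                 tolerance = 1e-12)
})

test_that("THI7 collapses to dry-bulb temperature at saturation", {
  # coefficient (0.55 - 0.0055*100) is exactly zero
  for (t in c(10, 25, 40))
    expect_identical(compute_index("THI7", t, 100), t)
})

test_that("ETIS is velocity-independent exactly at the sow surface temperature", {
  vals <- compute_index("ETIS", 38, 60, vel_ms = c(0, 0.5, 1, 2, 4))
  expect_equal(vals, rep(vals[1], 5), tolerance = 1e-12)
})

test_that("missing velocity or pressure raises for the indices that need them", {
  expect_error(compute_index("ET", 25, 60), "velocity")
  expect_error(compute_index("ETIS", 25, 60), "velocity")
  expect_error(compute_index("H", 25, 60, pm_mmhg = NA), "pressure")
  expect_silent(compute_index("THI1", 25, 60)) # velocity not required
})

test_that("compute_all_indices returns every evaluable index", {
  all12 <- compute_all_indices(22, 70, vel_ms = 0)
  expect_length(all12, 12)
  expect_named(all12, index_ids())
  expect_true(all(is.finite(all12)))
  expect_message(ten <- compute_all_indices(22, 70), "omitting ET, ETIS")
  expect_length(ten, 10)
  expect_message(res <- compute_all_indices(10, 60, vel_ms = 0), NA)
  expect_equal(unname(res["ET"]), 21.2, tolerance = 0.05 / 21.2)
})

test_that("every index rises with temperature on the analysis range", {
  t <- seq(10, 40, by = 0.25)
  for (id in setdiff(index_ids(), "ETIS")) {
    for (v in c(0, 1))
      expect_true(all(diff(compute_index(id, t, 60, vel_ms = v)) > 0),
                  label = sprintf("%s increasing in T at v=%g", id, v))
  }
  # the quartic radiation term turns ETIS over at high temperature
  # (~35.7 degC in still air, later at higher velocity); assert on the
  # common monotone range
  t_etis <- seq(10, 35, by = 0.25)
  for (v in c(0, 1))
    expect_true(all(diff(compute_index("ETIS", t_etis, 60, vel_ms = v)) > 0))
})

test_that("humidity raises every index at 30 degC except THI6, which falls", {
  rh <- seq(5, 95, by = 5)
  for (id in setdiff(index_ids(), "THI6")) {
    vals <- compute_index(id, 30, rh, vel_ms = 1)
    expect_true(all(diff(vals) > 0), label = sprintf("%s rising in RH", id))
  }
  expect_true(all(diff(compute_index("THI6", 30, rh)) < 0))
  # THI6's humidity term is decreasing whenever T > 14.4 degC
  for (t in c(15, 20, 35))
    expect_lt(index_partials("THI6", t, 50)["dRH"], 0)
})

test_that("threshold tables classify published boundary cases", {
  expect_equal(classify_index("THI2", c(73.9, 74, 77.9, 78, 82)),
               c("suitable", "mild", "mild", "moderate", "severe"))
  expect_equal(classify_index("ETIS", 18.6), "suitable")
  expect_equal(classify_index("ETIS", c(33.1, 35.9)), c("mild", "severe"))
  # published gap between the THI5 moderate and severe zones
  expect_equal(classify_index("THI5", 80), "unclassified")
  expect_equal(classify_index("THI5", c(75, 83)), c("moderate", "severe"))
  # THI1 zones are open-below, closed-above
  expect_equal(classify_index("THI1", c(61, 65, 73, 73.1)),
               c("unclassified", "thermal comfort", "heat stress",
                 "unclassified"))
  # THI6 zones are closed-above (contrast with THI2)
  expect_equal(classify_index("THI6", c(74, 78, 84, 84.1)),
               c("suitable", "mild", "moderate", "severe"))
  # the single-threshold heat-stress rule sits in the THI3 row
  expect_equal(classify_index("THI3", c(27.9, 28)),
               c("unclassified", "heat stress"))
})

test_that("indices without a published threshold division refuse to classify", {
  for (id in c("THI4", "THI7", "THI8", "BGHI", "ET", "H"))
    expect_error(classify_index(id, 50), "no thresholds",
                 label = sprintf("classify(%s)", id))
  expect_error(index_thresholds("nonsense"))
})

test_that("threshold intervals are sorted and non-overlapping", {
  for (id in c("THI1", "THI2", "THI3", "THI5", "THI6", "ETIS")) {
    tab <- index_thresholds(id)
    expect_true(all(tab$lower < tab$upper))
    if (nrow(tab) > 1)
      expect_true(all(tab$lower[-1] >= tab$upper[-nrow(tab)]))
  }
})
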