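test_that("identity case: unchanged humidity returns the starting temperature", {
  for (id in c("THI2", "H", "ETIS"))
    expect_identical(solve_matched_temperature(id, 27.3, 55, 55), 27.3)
})

test_that("matched temperature agrees with closed-form inversion for THI7", {
  # THI7(t2, 0) = t2 - 0.55*(t2 - 14.5) = 0.45*t2 + 7.975
  closed_form <- (compute_index("THI7", 22, 70) - 7.975) / 0.45
  expect_equal(closed_form, 28.41667, tolerance = 1e-5)
  expect_equal(solve_matched_temperature("THI7", 22, 70, 0), closed_form,
               tolerance = 1e-8)
})

test_that("enthalpy humidity rise 50->60% compensates like a >1.5 degC warming", {
  t2 <- solve_matched_temperature("H", 25, 50, 60)
  expect_equal(t2, 23.2046, tolerance = 1e-4)
  expect_gt(equivalent_temperature_change("H", 25, 50, 60), 1.5)
  expect_gt(equivalent_temperature_change("H", 30, 50, 60), 1.73)
})

test_that("THI6 is the lone index where humidity acts like cooling", {
  expect_lt(equivalent_temperature_change("THI6", 30, 50, 60), 0)
  tab <- equivalence_table()
  expect_equal(nrow(tab), 48) # 12 indices x 4 temperatures
  expect_true(all(tab$status == "ok"))
  expect_true(all(tab$t_equ[tab$index == "THI6"] < 0))
  expect_true(all(tab$t_equ[tab$index != "THI6"] > 0))
})

test_that("held-index residual is below solver tolerance for every table row", {
  tab <- equivalence_table()
  resid <- mapply(function(id, t1, t2)
    abs(compute_index(id, t2, 60, vel_ms = 1) -
          compute_index(id, t1, 50, vel_ms = 1)),
    tab$index, tab$t1, tab$t2)
  expect_true(all(resid <= 1e-9))
})

test_that("ETIS equivalent-temperature change grows with temperature", {
  tab <- equivalence_table(ids = "ETIS")
  expect_true(all(diff(tab$t_equ[order(tab$t1)]) > 0))
})

test_that("THI1, THI3, THI5 and ET trends are nearly parallel across 25-40 degC", {
  tab <- equivalence_table(ids = c("THI1", "THI3", "THI5", "ET"))
  for (id in unique(tab$index)) {
    tq <- tab$t_equ[tab$index == id]
    expect_true(all(abs(tq - mean(tq)) < 1),
                label = sprintf("%s spread about its mean", id))
  }
})

test_that("bisection agrees with the grid-scan oracle for every default solve", {
  tab <- equivalence_table()
  for (i in seq_len(nrow(tab))) {
    id <- tab$index[i]
    t1 <- tab$t1[i]
    target <- compute_index(id, t1, 50, vel_ms = 1)
    hi <- min(t1 + 15, if (id == "ETIS") 42 else 50)
    oracle <- grid_scan_root(
      function(t) compute_index(id, t, 60, vel_ms = 1) - target,
      t1 - 15, hi, step = 0.001)
    expect_lt(abs(tab$t2[i] - oracle), 0.002,
              label = sprintf("%s at %g degC vs oracle", id, t1))
  }
})

test_that("equivalence solves match Brent's method as a second, independent root finder", {
  for (id in c("H", "THI2", "BGHI")) {
    target <- compute_index(id, 30, 50, vel_ms = 1)
    brent <- stats::uniroot(
      function(t) compute_index(id, t, 60, vel_ms = 1) - target,
      c(15, 45), tol = 1e-12)$root
    expect_equal(solve_matched_temperature(id, 30, 50, 60), brent,
                 tolerance = 1e-7)
  }
})

test_that("a bracket without a compensating temperature reports failure", {
  # drying saturated air at constant enthalpy needs ~40 degC of warming,
  # far outside the +/-15 degC bracket
  expect_error(solve_matched_temperature("H", 25, 100, 0),
               "no compensating temperature")
  tab <- equivalence_table(ids = "H", temps = 25, rh1 = 100, rh2 = 0)
  expect_equal(tab$status, "no root")
  expect_true(is.na(tab$t2))
})
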