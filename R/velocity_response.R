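#' Winter reference value of a velocity-aware index
#'
#' The winter baseline is the index value in a cold, still barn: 10 degC,
#' 60% relative humidity, 0 m/s. Summer velocity curves are compared against
#' it to ask whether raising the air speed can make a hot environment "feel"
#' like winter. Always recomputed from the formula, never hard-coded.
#'
#' @param id `"ET"` or `"ETIS"` (the two velocity-aware indices).
#' @return The reference index value, degrees Celsius.
#' @examples
#' winter_reference("ET")   # about 21.2
#' winter_reference("ETIS") # about 18.6
#' @export
winter_reference <- function(id) {
  id <- match.arg(id, c("ET", "ETIS"))
  compute_index(id, 10, 60, vel_ms = 0)
}

#' Index response curve over air velocity
#'
#' Evaluates ET or ETIS on a velocity grid at fixed temperature and humidity.
#' Below the body-reference temperature both indices fall with velocity
#' (chilling); ETIS flips to rising above 38 degC, where faster air heats
#' the sow, and is exactly velocity-independent at 38 degC.
#'
#' @param id `"ET"` or `"ETIS"`.
#' @param temp_c Dry-bulb temperature, degrees Celsius.
#' @param rh_pct Relative humidity, percent.
#' @param vel_grid Velocity grid, m/s; default 0 to 4 in steps of 0.01.
#' @return A data.frame with columns `index`, `temp_c`, `rh_pct`, `vel_ms`,
#'   `value`.
#' @examples
#' cv <- velocity_curve("ET", 25, 60)
#' range(cv$value)
#' @export
velocity_curve <- function(id, temp_c, rh_pct = 60,
                           vel_grid = seq(0, 4, by = 0.01)) {
  id <- match.arg(id, c("ET", "ETIS"))
  stopifnot(!is.unsorted(vel_grid, strictly = TRUE))
  data.frame(
    index = id, temp_c = temp_c, rh_pct = rh_pct, vel_ms = vel_grid,
    value = compute_index(id, temp_c, rh_pct, vel_ms = vel_grid)
  )
}

#' Velocity at which an index curve crosses a reference value
#'
#' Bisection solve of `index(temp_c, rh_pct, v) = reference` for the velocity
#' `v` on `[0, 4]` m/s. Absence of a crossing is a valid result (returned as
#' `NA`): for instance the ETIS summer curves never reach the ETIS winter
#' baseline.
#'
#' @inheritParams velocity_curve
#' @param reference Index value to cross, e.g. [winter_reference()].
#' @param vel_range Velocity search interval, m/s.
#' @return The crossing velocity in m/s, or `NA_real_` when the curve does
#'   not cross the reference on the interval.
#' @examples
#' find_crossing_velocity("ET", 25, 60, winter_reference("ET"))  # about 0.45
#' find_crossing_velocity("ETIS", 30, 60, winter_reference("ETIS")) # NA
#' @export
find_crossing_velocity <- function(id, temp_c, rh_pct, reference,
                                   vel_range = c(0, 4)) {
  id <- match.arg(id, c("ET", "ETIS"))
  f <- function(v) compute_index(id, temp_c, rh_pct, vel_ms = v) - reference
  tryCatch(bisect(f, vel_range[1], vel_range[2], f_tol = 1e-9, x_tol = 1e-9),
           error = function(e) NA_real_)
}
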