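#' Reference value of an index at the standard psychrometric anchor
#'
#' All iso-index lines pass through a common anchor state: 22 degC, 70%
#' relative humidity, still air (0 m/s for ET and ETIS), 760 mmHg.
#'
#' @param id Index identifier, one of `index_ids()`.
#' @param temp_c,rh_pct Anchor state (defaults 22 degC, 70%).
#' @param pm_mmhg Barometric pressure, mmHg.
#' @return Index value at the anchor, in the index's units.
#' @examples
#' iso_reference_value("H")    # about 46.28 kJ/kg
#' iso_reference_value("THI7") # about 20.76
#' @export
iso_reference_value <- function(id, temp_c = 22, rh_pct = 70,
                                pm_mmhg = 760) {
  compute_index(id, temp_c, rh_pct, vel_ms = 0, pm_mmhg = pm_mmhg)
}

#' Dry-bulb temperature on an iso-index line at a given humidity
#'
#' Solves `index(T, rh_pct) = reference` for the temperature by bisection on
#' [0, 50] degC (capped at 42 degC for ETIS, above which its temperature
#' derivative changes sign). Velocity is held at 0 m/s.
#'
#' @inheritParams iso_reference_value
#' @param rh_pct Relative humidity at which to solve, percent.
#' @param reference Index value the line holds constant; defaults to the
#'   standard anchor via [iso_reference_value()].
#' @return Temperature in degrees Celsius, or `NA_real_` when no root exists
#'   in the bracket (a gap in the line).
#' @examples
#' iso_temperature_at("H", 0)    # about 46
#' iso_temperature_at("THI8", 0) # about 37.4
#' iso_temperature_at("THI7", 70) # 22: the anchor is on its own line
#' @export
iso_temperature_at <- function(id, rh_pct,
                               reference = iso_reference_value(id),
                               pm_mmhg = 760) {
  id <- match.arg(id, index_ids())
  stopifnot(rh_pct >= 0, rh_pct <= 100)
  upper <- if (id == "ETIS") 42 else 50
  f <- function(t) compute_index(id, t, rh_pct, vel_ms = 0,
                                 pm_mmhg = pm_mmhg) - reference
  tryCatch(bisect(f, 0, upper), error = function(e) NA_real_)
}

#' Trace an iso-index line across the psychrometric plane
#'
#' Applies [iso_temperature_at()] over a relative-humidity grid, producing
#' the locus of (RH, T) pairs on which the index equals its value at the
#' standard anchor (22 degC, 70% RH). Grid points with no solution in the
#' temperature bracket are kept with `temp_c = NA` (gaps); points where the
#' solved temperature leaves the 10-46 degC calibration range of the
#' empirical psychrometric fits are kept but flagged.
#'
#' @inheritParams iso_reference_value
#' @param rh_grid Relative-humidity grid, percent; default 0 to 100 in 1%
#'   steps.
#' @return A data.frame with columns `index`, `rh_pct`, `temp_c`,
#'   `reference_value`, `in_calibration` (logical flag).
#' @examples
#' line <- trace_iso_line("THI7", rh_grid = seq(0, 100, by = 10))
#' line[line$rh_pct == 70, "temp_c"] # 22
#' @export
trace_iso_line <- function(id, rh_grid = 0:100, pm_mmhg = 760) {
  id <- match.arg(id, index_ids())
  ref <- iso_reference_value(id, pm_mmhg = pm_mmhg)
  temps <- vapply(rh_grid, function(rh)
    iso_temperature_at(id, rh, reference = ref, pm_mmhg = pm_mmhg),
    numeric(1))
  data.frame(
    index = id, rh_pct = rh_grid, temp_c = temps, reference_value = ref,
    in_calibration = !is.na(temps) & temps >= 10 & temps <= 46
  )
}
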