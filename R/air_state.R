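#' Construct a table of moist-air states
#'
#' An air state is the argument of every thermal index: dry-bulb temperature,
#' relative humidity, air velocity and barometric pressure. The constructor
#' recycles its arguments, validates physical bounds and warns when the
#' dry-bulb temperature leaves the validity window of the empirical
#' psychrometric fits.
#'
#' @param temp_c Dry-bulb air temperature, degrees Celsius.
#' @param rh_pct Relative humidity, percent (0-100 scale).
#' @param vel_ms Air velocity, m/s; `NA` when unknown (indices that need it
#'   are then unavailable).
#' @param pm_mmhg Barometric pressure, mmHg. Defaults to a standard
#'   atmosphere, 760 mmHg.
#'
#' @return A `data.frame` of class `air_state` with columns `temp_c`,
#'   `rh_pct`, `vel_ms`, `pm_mmhg`.
#'
#' @examples
#' air_state(22, 70)
#' air_state(temp_c = c(25, 30), rh_pct = 50, vel_ms = 1)
#' @export
air_state <- function(temp_c, rh_pct, vel_ms = NA_real_, pm_mmhg = 760) {
  n <- max(length(temp_c), length(rh_pct), length(vel_ms), length(pm_mmhg))
  st <- data.frame(
    temp_c = rep_len(as.numeric(temp_c), n),
    rh_pct = rep_len(as.numeric(rh_pct), n),
    vel_ms = rep_len(as.numeric(vel_ms), n),
    pm_mmhg = rep_len(as.numeric(pm_mmhg), n)
  )
  if (any(st$rh_pct < 0 | st$rh_pct > 100, na.rm = TRUE))
    stop("relative humidity must lie in [0, 100] %", call. = FALSE)
  if (any(st$vel_ms < 0, na.rm = TRUE))
    stop("air velocity must be non-negative", call. = FALSE)
  if (any(st$pm_mmhg <= 0, na.rm = TRUE))
    stop("barometric pressure must be positive", call. = FALSE)
  check_validity_window(st$temp_c)
  class(st) <- c("air_state", "data.frame")
  st
}

# Validity window of the empirical psychrometric fits; outside it the
# conversions extrapolate uncalibrated regressions, so operations warn.
.VALIDITY_WINDOW_C <- c(-10, 50)

check_validity_window <- function(temp_c) {
  out <- temp_c < .VALIDITY_WINDOW_C[1] | temp_c > .VALIDITY_WINDOW_C[2]
  if (any(out, na.rm = TRUE))
    warning(sprintf(
      "dry-bulb temperature outside the [%g, %g] degC validity window of the empirical fits",
      .VALIDITY_WINDOW_C[1], .VALIDITY_WINDOW_C[2]), call. = FALSE)
  invisible(any(out, na.rm = TRUE))
}
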