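#' Dew-point temperature from dry-bulb temperature and relative humidity
#'
#' Empirical linear fit used by the index formulas (notably BGHI). The fit is
#' applied exactly as published: at RH = 0 it returns the finite value
#' `0.84 * temp_c - 19.2` rather than diverging to -Inf, which is physically
#' wrong in the limit but is what the index definitions consume.
#'
#' @param temp_c Dry-bulb temperature, degrees Celsius.
#' @param rh_pct Relative humidity, percent.
#' @return Dew-point temperature, degrees Celsius.
#' @examples
#' dew_point_temperature(22, 70) # 15.758
#' @export
dew_point_temperature <- function(temp_c, rh_pct) {
  check_validity_window(temp_c)
  (0.198 + 0.0017 * temp_c) * rh_pct + 0.84 * temp_c - 19.2
}

#' Wet-bulb temperature from dry-bulb temperature and relative humidity
#'
#' Empirical rational fit: a degree-3 polynomial numerator in temperature and
#' humidity divided by a degree-3 polynomial denominator, evaluated as one
#' fraction. Near saturation the fit can exceed the dry-bulb temperature by a
#' few tenths of a degree; that is a property of the regression, not clamped.
#'
#' @inheritParams dew_point_temperature
#' @return Wet-bulb temperature, degrees Celsius.
#' @examples
#' wet_bulb_temperature(22, 70) # 18.282
#' @export
wet_bulb_temperature <- function(temp_c, rh_pct) {
  check_validity_window(temp_c)
  num <- -5.86154 + 0.58174 * temp_c + 0.1485 * rh_pct -
    0.00191 * rh_pct^2 + 1.01768e-5 * rh_pct^3
  den <- 1 + 0.0036 * temp_c - 9.79822e-5 * temp_c^2 + 9.26824e-7 * temp_c^3 -
    0.00899 * rh_pct + 4.38111e-5 * rh_pct^2
  if (any(den <= 0, na.rm = TRUE))
    stop("wet-bulb fit denominator is non-positive; input outside the calibrated range",
         call. = FALSE)
  num / den
}

#' Black-globe temperature from dry-bulb temperature and relative humidity
#'
#' Closed-form estimate folding the radiant load into a globe temperature via
#' the saturation vapour pressure (Magnus form, 6.105 hPa scale).
#'
#' @inheritParams dew_point_temperature
#' @return Black-globe temperature, degrees Celsius.
#' @examples
#' black_globe_temperature(22, 70) # 23.667
#' @export
black_globe_temperature <- function(temp_c, rh_pct) {
  check_validity_window(temp_c)
  e <- (rh_pct / 100) * 6.105 * exp(17.27 * temp_c / (237.7 + temp_c))
  0.567 * temp_c + 0.393 * e + 3.94
}

#' Celsius/Fahrenheit conversion
#'
#' @param temp_c Temperature in degrees Celsius.
#' @return Temperature in degrees Fahrenheit.
#' @examples
#' celsius_to_fahrenheit(22) # 71.6
#' @export
celsius_to_fahrenheit <- function(temp_c) 1.8 * temp_c + 32

#' @rdname celsius_to_fahrenheit
#' @param temp_f Temperature in degrees Fahrenheit.
#' @export
fahrenheit_to_celsius <- function(temp_f) (temp_f - 32) / 1.8
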