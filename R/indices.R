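#' The twelve thermal index identifiers
#'
#' Eight temperature-humidity index variants (suffixes 1-8 distinguish the
#' historical forms), the black globe-humidity index (BGHI), effective
#' temperature (ET), the equivalent temperature index of sows (ETIS), and
#' moist-air enthalpy (H). ET and ETIS are the only indices that use air
#' velocity; H is the only one that uses barometric pressure.
#'
#' @return Character vector of the twelve index identifiers, in canonical
#'   order (used for tie-breaking in rankings).
#' @examples
#' index_ids()
#' @export
index_ids <- function() {
  c("THI1", "THI2", "THI3", "THI4", "THI5", "THI6", "THI7", "THI8",
    "BGHI", "ET", "ETIS", "H")
}

#' @rdname index_ids
#' @param id Index identifier, one of `index_ids()`.
#' @return For the predicates, a logical scalar.
#' @export
index_uses_velocity <- function(id) {
  match.arg(id, index_ids()) %in% c("ET", "ETIS")
}

#' @rdname index_ids
#' @export
index_uses_pressure <- function(id) {
  match.arg(id, index_ids()) == "H"
}

#' Evaluate a thermal index at an air state
#'
#' Evaluates one of the twelve indices. All formulas take the dry-bulb
#' temperature in degrees Celsius; THI4 and THI6 convert to Fahrenheit
#' internally, as their definitions require. Wet-bulb, dew-point and
#' black-globe temperatures are derived from `temp_c` and `rh_pct` via the
#' empirical psychrometric fits.
#'
#' Units of the result: dimensionless for THI1-THI8 and BGHI; degrees Celsius
#' for ET and ETIS; kJ per kg dry air for H.
#'
#' ET subtracts a velocity chill term `(42 - T) * (v^0.66 - 0.2^0.66)`
#' (calibrated for growing pigs, body reference 42 degC). ETIS combines an RH
#' correction, a convective term `0.3132 * u^0.6827 * (38 - T)` around a
#' 38 degC sow body, a linear term `4.79 * (1.0086 * 38 - T)` and a quartic
#' (Stefan-Boltzmann-like) radiation term. Because of the quartic term the
#' ETIS derivative in temperature changes sign near 43 degC; solvers in this
#' package bracket ETIS below 42 degC.
#'
#' @param id Index identifier, one of `index_ids()`.
#' @param temp_c Dry-bulb temperature, degrees Celsius.
#' @param rh_pct Relative humidity, percent.
#' @param vel_ms Air velocity, m/s; required for ET and ETIS.
#' @param pm_mmhg Barometric pressure, mmHg; required for H (default 760).
#' @return Numeric vector of index values.
#' @examples
#' compute_index("ET", 10, 60, vel_ms = 0)    # winter reference, 21.2
#' compute_index("THI2", 22, 70)              # 69.32
#' compute_index("H", 22, 70)                 # 46.28 kJ/kg
#' @export
compute_index <- function(id, temp_c, rh_pct, vel_ms = NA_real_,
                          pm_mmhg = 760) {
  id <- match.arg(id, index_ids())
  if (index_uses_velocity(id) && any(is.na(vel_ms)))
    stop(sprintf("%s requires an air velocity (vel_ms)", id), call. = FALSE)
  if (index_uses_pressure(id) && any(is.na(pm_mmhg) | pm_mmhg <= 0))
    stop("H requires a positive barometric pressure (pm_mmhg)", call. = FALSE)
  check_validity_window(temp_c)
  t <- temp_c
  rh <- rh_pct
  switch(id,
    THI1 = t + 0.36 * wet_bulb_temperature(t, rh) + 41.5,
    THI2 = 0.8 * t + rh * (t - 14.4) / 100 + 46.4,
    THI3 = 0.65 * t + 0.35 * wet_bulb_temperature(t, rh),
    THI4 = {
      tf <- celsius_to_fahrenheit(t)
      tf - (0.55 - 0.0055 * rh) * (tf - 58)
    },
    THI5 = 0.72 * t + 0.72 * wet_bulb_temperature(t, rh) + 40.6,
    THI6 = {
      tf <- celsius_to_fahrenheit(t)
      tf - 0.55 * (rh / 100) * (tf - 58)
    },
    THI7 = t - (0.55 - 0.0055 * rh) * (t - 14.5),
    THI8 = 0.27 * t + 1.35 * wet_bulb_temperature(t, rh) + 34.07,
    BGHI = black_globe_temperature(t, rh) +
      0.36 * dew_point_temperature(t, rh) + 41.5,
    ET = t + 0.0015 * (rh - 50) * t -
      1.0 * (42 - t) * (vel_ms^0.66 - 0.2^0.66),
    ETIS = t + 0.0006 * (rh - 50) * t -
      0.3132 * vel_ms^0.6827 * (38 - t) -
      4.79 * (1.0086 * 38 - t) +
      4.8957e-8 * ((38 + 273.15)^4 - (t + 273.15)^4),
    H = 1.006 * t +
      (rh / pm_mmhg) * 10^(7.5 * t / (273.3 + t)) * (71.28 + 0.052 * t)
  )
}

#' Evaluate every available index at an air state
#'
#' Applies [compute_index()] for all twelve indices. Indices whose required
#' inputs are missing (ET/ETIS without a velocity, H without a pressure) are
#' omitted with a message rather than raising an error.
#'
#' @inheritParams compute_index
#' @return Named numeric vector (one element per state when the inputs are
#'   scalars; otherwise a data.frame with one column per available index).
#' @examples
#' compute_all_indices(22, 70, vel_ms = 0)
#' names(compute_all_indices(22, 70)) # 10 entries, no ET/ETIS
#' @export
compute_all_indices <- function(temp_c, rh_pct, vel_ms = NA_real_,
                                pm_mmhg = 760) {
  ids <- index_ids()
  skip <- character(0)
  if (any(is.na(vel_ms))) skip <- c(skip, "ET", "ETIS")
  if (any(is.na(pm_mmhg) | pm_mmhg <= 0)) skip <- c(skip, "H")
  if (length(skip))
    message("omitting ", paste(skip, collapse = ", "),
            ": required input missing")
  ids <- setdiff(ids, skip)
  vals <- lapply(ids, compute_index, temp_c = temp_c, rh_pct = rh_pct,
                 vel_ms = vel_ms, pm_mmhg = pm_mmhg)
  names(vals) <- ids
  n <- max(lengths(vals))
  if (n == 1L) unlist(vals) else as.data.frame(vals)
}

# Heat-stress threshold tables, encoded exactly as published, including
# boundary openness and gaps (gaps classify as "unclassified"). The THI3 row
# is published against the symbol THI2; it is read as THI3 (a typo: it sits
# in the THI3 row). Only six indices carry thresholds.
.THRESHOLDS <- list(
  THI1 = data.frame(
    zone = c("thermal comfort", "intermediate", "heat stress"),
    lower = c(61, 65, 69), upper = c(65, 69, 73),
    lower_closed = FALSE, upper_closed = TRUE
  ),
  THI2 = data.frame(
    zone = c("suitable", "mild", "moderate", "severe"),
    lower = c(-Inf, 74, 78, 82), upper = c(74, 78, 82, Inf),
    lower_closed = c(FALSE, TRUE, TRUE, TRUE),
    upper_closed = FALSE
  ),
  THI3 = data.frame(
    zone = "heat stress",
    lower = 28, upper = Inf, lower_closed = TRUE, upper_closed = FALSE
  ),
  THI5 = data.frame(
    zone = c("moderate", "severe"),
    lower = c(75, 83), upper = c(78, Inf),
    lower_closed = TRUE, upper_closed = FALSE
  ),
  THI6 = data.frame(
    zone = c("suitable", "mild", "moderate", "severe"),
    lower = c(-Inf, 74, 78, 84), upper = c(74, 78, 84, Inf),
    lower_closed = FALSE, upper_closed = c(TRUE, TRUE, TRUE, FALSE)
  ),
  ETIS = data.frame(
    zone = c("suitable", "mild", "moderate", "severe"),
    lower = c(-Inf, 33.1, 34.5, 35.9), upper = c(33.1, 34.5, 35.9, Inf),
    lower_closed = c(FALSE, TRUE, TRUE, TRUE),
    upper_closed = FALSE
  )
)

#' Heat-stress threshold table of an index
#'
#' @param id Index identifier; must be one of the six indices with a
#'   published threshold division (THI1, THI2, THI3, THI5, THI6, ETIS).
#' @return A data.frame with columns `zone`, `lower`, `upper`,
#'   `lower_closed`, `upper_closed` describing non-overlapping, sorted
#'   intervals. Gaps between intervals are legal and classify as
#'   "unclassified".
#' @examples
#' index_thresholds("THI2")
#' @export
index_thresholds <- function(id) {
  id <- match.arg(id, index_ids())
  tab <- .THRESHOLDS[[id]]
  if (is.null(tab))
    stop(sprintf("no thresholds defined for %s", id), call. = FALSE)
  tab
}

#' Classify an index value into a heat-stress zone
#'
#' @param id Index identifier with a threshold table (see
#'   [index_thresholds()]).
#' @param value Numeric vector of index values.
#' @return Character vector of zone labels; values falling in a gap or
#'   outside the covered range return "unclassified".
#' @examples
#' classify_index("THI2", c(73.9, 82))   # suitable, severe
#' classify_index("THI5", 80)            # unclassified (published gap)
#' @export
classify_index <- function(id, value) {
  tab <- index_thresholds(id)
  vapply(value, function(x) {
    if (is.na(x)) return(NA_character_)
    above <- ifelse(tab$lower_closed, x >= tab$lower, x > tab$lower)
    below <- ifelse(tab$upper_closed, x <= tab$upper, x < tab$upper)
    hit <- which(above & below)
    if (length(hit)) tab$zone[hit[1]] else "unclassified"
  }, character(1))
}
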