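#' Solve for the temperature that compensates a humidity change
#'
#' Holds an index constant while relative humidity moves from `rh1` to `rh2`
#' and solves for the dry-bulb temperature `t2` at which the index recovers
#' its original value: `index(t2, rh2) = index(t1, rh1)`. The root is found
#' by bisection on the bracket `[t1 - 15, t1 + 15]` degrees Celsius to a
#' residual below 1e-9 index units. The upper end is capped at 42 degC for
#' ETIS, protecting the solve from the derivative sign change its radiation
#' term causes (the other eleven indices are monotone in temperature far
#' beyond that, so they are only capped at the 50 degC edge of the
#' psychrometric fits' validity window).
#'
#' When comparing ET or ETIS against the velocity-free indices the air
#' velocity is conventionally fixed at 1 m/s (the default).
#'
#' @param id Index identifier, one of `index_ids()`.
#' @param t1 Initial dry-bulb temperature, degrees Celsius.
#' @param rh1,rh2 Initial and final relative humidity, percent.
#' @param vel_ms Air velocity held fixed during the solve, m/s.
#' @param pm_mmhg Barometric pressure, mmHg.
#' @return `solve_matched_temperature()` returns `t2` in degrees Celsius;
#'   `equivalent_temperature_change()` returns `t_equ = t1 - t2`, positive
#'   when rising humidity acts like rising temperature.
#' @examples
#' solve_matched_temperature("H", 25, 50, 60)       # about 23.2
#' equivalent_temperature_change("H", 25, 50, 60)   # about +1.8
#' equivalent_temperature_change("THI6", 30, 50, 60) # negative
#' @export
solve_matched_temperature <- function(id, t1, rh1, rh2, vel_ms = 1,
                                      pm_mmhg = 760) {
  id <- match.arg(id, index_ids())
  if (rh1 == rh2) return(t1)
  target <- compute_index(id, t1, rh1, vel_ms, pm_mmhg)
  lower <- t1 - 15
  upper <- min(t1 + 15, if (id == "ETIS") 42 else 50)
  root <- tryCatch(
    bisect(function(t) compute_index(id, t, rh2, vel_ms, pm_mmhg) - target,
           lower, upper),
    error = function(e)
      stop(sprintf("no compensating temperature in [%g, %g] degC for %s",
                   lower, upper, id), call. = FALSE)
  )
  root
}

#' @rdname solve_matched_temperature
#' @export
equivalent_temperature_change <- function(id, t1, rh1, rh2, vel_ms = 1,
                                          pm_mmhg = 760) {
  t1 - solve_matched_temperature(id, t1, rh1, rh2, vel_ms, pm_mmhg)
}

#' Equivalent-temperature-change table across indices and temperatures
#'
#' Runs the humidity-compensation experiment for every combination of index
#' and starting temperature. The defaults reproduce the study conditions:
#' temperatures 25, 30, 35, 40 degC, relative humidity rising from 50% to
#' 60%, velocity fixed at 1 m/s for ET and ETIS.
#'
#' @param ids Indices to evaluate (default: all twelve).
#' @param temps Starting dry-bulb temperatures, degrees Celsius.
#' @param rh1,rh2 Initial and final relative humidity, percent.
#' @param vel_ms Air velocity for ET and ETIS, m/s.
#' @param pm_mmhg Barometric pressure, mmHg.
#' @return A data.frame with one row per (index, temperature): columns
#'   `index`, `t1`, `rh1`, `rh2`, `vel_ms`, `t2`, `t_equ`, `index_value`,
#'   `status`. Solver failures are flagged in `status` ("no root"), not
#'   dropped.
#' @examples
#' tab <- equivalence_table(ids = c("H", "THI6"), temps = c(25, 30))
#' tab[, c("index", "t1", "t_equ")]
#' @export
equivalence_table <- function(ids = index_ids(), temps = c(25, 30, 35, 40),
                              rh1 = 50, rh2 = 60, vel_ms = 1,
                              pm_mmhg = 760) {
  grid <- expand.grid(index = ids, t1 = temps, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(match(grid$index, index_ids()), grid$t1), ]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    id <- grid$index[i]
    t1 <- grid$t1[i]
    t2 <- tryCatch(solve_matched_temperature(id, t1, rh1, rh2, vel_ms,
                                             pm_mmhg),
                   error = function(e) NA_real_)
    data.frame(
      index = id, t1 = t1, rh1 = rh1, rh2 = rh2, vel_ms = vel_ms,
      t2 = t2, t_equ = t1 - t2,
      index_value = compute_index(id, t1, rh1, vel_ms, pm_mmhg),
      status = if (is.na(t2)) "no root" else "ok"
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
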