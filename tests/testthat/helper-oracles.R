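# Brute-force grid-scan root oracle, independent of the package's bisection:
# evaluate on a fixed-step grid (f must be vectorized, as the index formulas
# are), return the midpoint of the first sign-changing step. Accurate to
# step/2 for a single simple root.
grid_scan_root <- function(f, lower, upper, step = 0.001) {
  xs <- seq(lower, upper, by = step)
  ys <- f(xs)
  flip <- which(diff(sign(ys)) != 0 | ys[-length(ys)] == 0)
  if (!length(flip)) return(NA_real_)
  i <- flip[1]
  if (ys[i] == 0) return(xs[i])
  (xs[i] + xs[i + 1]) / 2
}

# numerical partial derivatives of an index, central differences
index_partials <- function(id, temp_c, rh_pct, vel_ms = 0, h = 1e-4) {
  dT <- (compute_index(id, temp_c + h, rh_pct, vel_ms) -
           compute_index(id, temp_c - h, rh_pct, vel_ms)) / (2 * h)
  dRH <- (compute_index(id, temp_c, rh_pct + h, vel_ms) -
            compute_index(id, temp_c, rh_pct - h, vel_ms)) / (2 * h)
  c(dT = dT, dRH = dRH)
}
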