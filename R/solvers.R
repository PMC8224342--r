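# Bisection root finder used by every implicit solve in the package.
# Stops when the residual |f| drops below f_tol or the bracket width below
# x_tol; deterministic given the bracket. Kept explicit (rather than Brent)
# because the iso-line and equivalence solves only guarantee a sign change
# and monotonicity on the stated bracket, and the empirical wet-bulb fit is
# a rational function whose derivative is not worth trusting.
bisect <- function(f, lower, upper, f_tol = 1e-9, x_tol = 1e-12,
                   max_iter = 200L) {
  fl <- f(lower)
  fu <- f(upper)
  if (is.na(fl) || is.na(fu))
    stop("bisection bracket evaluates to NA", call. = FALSE)
  if (fl == 0) return(lower)
  if (fu == 0) return(upper)
  if (sign(fl) == sign(fu))
    stop("no sign change on the bracket", call. = FALSE)
  for (i in seq_len(max_iter)) {
    mid <- (lower + upper) / 2
    fm <- f(mid)
    if (abs(fm) < f_tol || (upper - lower) / 2 < x_tol) return(mid)
    if (sign(fm) == sign(fl)) {
      lower <- mid
      fl <- fm
    } else {
      upper <- mid
    }
  }
  (lower + upper) / 2
}
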