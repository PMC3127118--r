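# Independent mass-action oracle: solve (P0 - PL)(L0 - PL) = Kd * PL for PL
# by bisection on [0, min(P0, L0)], without the closed-form quadratic.
bisect_bound <- function(P0, L0, Kd, tol = 1e-14) {
  f <- function(pl) (P0 - pl) * (L0 - pl) - Kd * pl
  lo <- 0; hi <- min(P0, L0)
  if (hi == 0) return(0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol * max(hi, 1)) break
  }
  (lo + hi) / 2
}

# Analytic Gaussian emission band (for feature-extraction oracles).
gaussian_spectrum <- function(center, sigma, grid, scale = 1) {
  emission_spectrum(grid, scale * exp(-(grid - center)^2 / (2 * sigma^2)))
}
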