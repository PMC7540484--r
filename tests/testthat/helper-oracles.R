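# Independent oracles used across the suite.

# dense numerical scan for the crossing of two Gaussian densities inside the
# interval between the means
scan_gaussian_crossing <- function(m1, s1, m2, s2, n = 2e6) {
  lo <- min(m1, m2); hi <- max(m1, m2)
  xs <- seq(lo, hi, length.out = n)
  xs[which.min(abs(stats::dnorm(xs, m1, s1) - stats::dnorm(xs, m2, s2)))]
}

# analytic SASA of two equal spheres of accessible radius R at separation d
two_sphere_sasa <- function(R, d) {
  if (d >= 2 * R) return(2 * 4 * pi * R^2)
  h <- R - d / 2                     # buried-cap height on each sphere
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}

RT300 <- 8.314e-3 * 300
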