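# Continuum oracle, independent of the package's grid pipeline: radial
# profile of a uniform-concentration ball of radius R blurred by an
# isotropic Gaussian of standard deviation sigma, and integrals thereof.
# Used to freeze expected values for blur/quantification tests.

oracle_ball_profile <- function(r, R, sigma) {
  erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  out <- 0.5 * (erf((R - r) / (sigma * sqrt(2))) +
                  erf((R + r) / (sigma * sqrt(2)))) -
    sigma / (r * sqrt(2 * pi)) *
      (exp(-(r - R)^2 / (2 * sigma^2)) - exp(-(r + R)^2 / (2 * sigma^2)))
  small <- r < 1e-8
  out[small] <- erf(R / (sigma * sqrt(2))) -
    (R / sigma) * sqrt(2 / pi) * exp(-R^2 / (2 * sigma^2))
  out
}

# activity of the blurred unit-concentration ball within radius rho
oracle_activity_within <- function(rho, R, sigma) {
  stats::integrate(function(r) oracle_ball_profile(r, R, sigma) * 4 * pi * r^2,
                   0, rho, rel.tol = 1e-10)$value
}

oracle_shell_mean <- function(r1, r2, R, sigma) {
  num <- stats::integrate(function(r)
    oracle_ball_profile(r, R, sigma) * 4 * pi * r^2,
    r1, r2, rel.tol = 1e-10)$value
  num / (4 / 3 * pi * (r2^3 - r1^3))
}

# continuum true fraction of the expanded-VOI estimator, zero background
oracle_tf <- function(diameter, expansion, ring = 10, fwhm = 12) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  R <- diameter / 2
  Rout <- R + expansion / 2
  Rring <- Rout + ring / 2
  Atrue <- 4 / 3 * pi * R^3
  A2 <- oracle_activity_within(Rout, R, sigma)
  VSP <- 4 / 3 * pi * (Rout^3 - R^3)
  Bbar <- if (Rring > Rout) oracle_shell_mean(Rout, Rring, R, sigma) else 0
  (A2 - VSP * Bbar) / Atrue
}
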