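# independent oracles and shared fixtures for the test suite

# analytic sphere form factor (radius R), normalized to I(0) = 1
sphere_profile <- function(R, q = qgrid_default(), sigma_frac = 0.005) {
  FF <- (3 * (sin(q * R) - q * R * cos(q * R)) / (q * R)^3)^2
  saxs_profile(q, FF, sigma = rep(sigma_frac * max(FF), length(q)))
}

# closed-form sphere pair-distance distribution on a grid, scaled to i0
sphere_pddf_values <- function(r, R, i0 = 1) {
  x <- r / (2 * R)
  p <- ifelse(r <= 2 * R, r^2 * (1 - 1.5 * x + 0.5 * x^3), 0)
  p * i0 / (4 * pi * pracma::trapz(r, p))
}

# add seeded gaussian noise to a profile and record matching sigma
noisy_profile <- function(profile, frac = 0.01, seed = 1) {
  set.seed(seed)
  sg <- frac * abs(profile$I)
  saxs_profile(profile$q, profile$I + rnorm(length(sg), 0, sg), sg,
               salt = attr(profile, "salt"), sucrose = attr(profile, "sucrose"))
}

# moving-average smooth (for band-limited comparison of histograms)
ma_smooth <- function(x, k) {
  y <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  y[is.na(y)] <- x[is.na(y)]
  y
}

# relative L2 distance of two pddf-like curves on a common grid
rel_l2 <- function(r1, p1, r2, p2, lo, hi, smooth = 1) {
  g <- seq(lo, hi, by = 1)
  a <- approx(r1, ma_smooth(p1, smooth), g, rule = 2)$y
  b <- approx(r2, ma_smooth(p2, smooth), g, rule = 2)$y
  sqrt(sum((a - b)^2) / sum(a^2))
}

# rigid rotation + translation of a conformer
rigid_motion <- function(conf, angle = 0.7, shift = c(11, -5, 3)) {
  R <- matrix(c(cos(angle), -sin(angle), 0,
                sin(angle), cos(angle), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  xyz <- as.matrix(conf[, c("x", "y", "z")]) %*% t(R)
  out <- conf
  out$x <- xyz[, 1] + shift[1]
  out$y <- xyz[, 2] + shift[2]
  out$z <- xyz[, 3] + shift[3]
  out
}

# cached default pool (built once per test run)
default_pool <- local({
  pool <- NULL
  function() {
    if (is.null(pool)) pool <<- generate_pool()
    pool
  }
})

# cached pool profiles at the contrast-matched condition
default_pool_profiles <- local({
  pp <- NULL
  function() {
    if (is.null(pp)) pp <<- pool_profiles(default_pool(), sucrose = 0.5)
    pp
  }
})
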