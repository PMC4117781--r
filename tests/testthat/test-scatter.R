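test_that("contrast weights follow the three-phase model", {
  m <- contrast_model()
  # protein blanked at the 50% sucrose match point
  expect_equal(contrast_of("PROTEIN", sucrose = 0.5, model = m), 0)
  # DNA weight at 0% sucrose: (0.55 - 0.334) * 300 e
  expect_equal(contrast_of("DNA", sucrose = 0, model = m), 0.216 * 300)
  w50 <- contrast_of("DNA", sucrose = 0.5, model = m)
  expect_gt(w50, 0)
  expect_lt(w50, contrast_of("DNA", sucrose = 0, model = m))
  # NaCl raises solvent density
  expect_lt(contrast_of("DNA", sucrose = 0, nacl = 2, model = m),
            contrast_of("DNA", sucrose = 0, model = m))
  expect_error(contrast_of("DNA", sucrose = 0.7), "sucrose")
  expect_error(contrast_of("LIPID"), "phase")
  expect_error(contrast_model(rho_prot = 0.6), "rho_dna")
})

test_that("Debye sum reproduces closed forms for one and two beads", {
  one <- nucsaxs:::new_conformer(
    tibble::tibble(x = 0, y = 0, z = 0, phase = "DNA"), 1, 0, 0, "one")
  q <- qgrid_default(50)
  p1 <- debye_profile(one, q)
  w <- contrast_of("DNA")
  expect_equal(p1$I, rep(w^2, 50))

  two <- nucsaxs:::new_conformer(
    tibble::tibble(x = c(0, 7), y = 0, z = 0, phase = "DNA"), 1, 0, 0, "two")
  p2 <- debye_profile(two, q)
  expect_equal(p2$I, 2 * w^2 * (1 + sin(q * 7) / (q * 7)), tolerance = 1e-12)
})

test_that("Debye profiles are positive, bounded by I(0), and rigid-motion
           invariant", {
  w <- build_wrapped(147)
  p <- debye_profile(w)
  expect_true(all(p$I > 0))
  expect_true(all(p$I <= i0_of(w)))
  # low-q extrapolation consistent with the weight-sum I(0)
  q_lo <- qgrid_default(30, qmin = 1e-4, qmax = 1 / dmax_of(w))
  p_lo <- debye_profile(w, q_lo)
  fit <- lm(log(p_lo$I) ~ I(q_lo^2))
  expect_lt(abs(exp(coef(fit)[1]) / i0_of(w) - 1), 0.001)

  pm <- debye_profile(rigid_motion(w))
  expect_equal(pm$I, p$I, tolerance = 1e-9)
})

test_that("Guinier slope of the wrapped model recovers its Rg within 3%", {
  w <- build_wrapped(147)
  rg <- rg_of(w)
  q <- qgrid_default(60, qmin = 0.005, qmax = 1 / rg)
  p <- debye_profile(w, q)
  keep <- q * rg < 1
  fit <- lm(log(p$I[keep]) ~ I(q[keep]^2))
  rg_guinier <- sqrt(-3 * coef(fit)[2])
  expect_lt(abs(rg_guinier / rg - 1), 0.03)
})

test_that("protein blanking removes the core from the profile", {
  w <- build_wrapped(147)
  wc <- with_protein_core(w)
  p_matched <- debye_profile(wc, sucrose = 0.5)
  p_dna <- debye_profile(w, sucrose = 0.5)
  expect_equal(p_matched$I, p_dna$I, tolerance = 1e-12)
  # at 0% sucrose the core contributes by the squared-sum rule
  i_ncp <- i0_of(wc)
  i_dna <- i0_of(w)
  W_d <- sum(contrast_of(w$phase))
  W_p <- sum(contrast_of(rep("PROTEIN", 8)))
  expect_equal(i_ncp / i_dna, ((W_d + W_p) / W_d)^2)
  # all-phases-matched contrast is degenerate
  prot <- nucsaxs:::protein_only()
  expect_error(debye_profile(prot, sucrose = 0.5), "degenerate contrast")
  expect_error(i0_of(prot, sucrose = 0.5), "degenerate")
})

test_that("Kratky transform is pointwise and flattens 1/q^2 intensities", {
  q <- qgrid_default(40)
  p <- saxs_profile(q, 1 / q^2, sigma = 1 / q^2)
  k <- kratky(p)
  expect_equal(k$iq2, rep(1, 40))
  expect_equal(k$sigma_iq2, rep(1, 40))
  empty <- saxs_profile(numeric(0), numeric(0), numeric(0))
  expect_equal(nrow(kratky(empty)), 0)
  # globular model: a dominant interior peak followed by a deep trough;
  # extended duplex: rises toward a high-q plateau with no early peak
  kw <- kratky(debye_profile(build_wrapped(147)))
  kd <- kratky(debye_profile(build_duplex(149)))
  # (the coarse cross-section imposes a form-factor minimum near
  # q ~ pi/20 A^-1, so the comparison stays below it)
  at <- function(k, q0) k$iq2[which.min(abs(k$q - q0))] / max(k$iq2)
  expect_gt(at(kw, 0.035), 0.85)  # globular peak at ~sqrt(3)/Rg
  expect_lt(at(kd, 0.035), 0.70)  # rod still far below its plateau
  expect_gt(kd$q[which.max(kd$iq2)], 0.07)
  mid_w <- kw$q > 0.055 & kw$q < 0.08
  expect_lt(max(kw$iq2[mid_w]), 0.7 * max(kw$iq2))  # falls after its peak
  mid_d <- kd$q > 0.055 & kd$q < 0.08
  expect_gt(min(kd$iq2[mid_d]), 0.7 * max(kd$iq2))  # still climbing
})

test_that("profile container validates its invariants", {
  expect_error(saxs_profile(c(0.2, 0.1), c(1, 1)), "increasing")
  expect_error(saxs_profile(c(-0.1, 0.1), c(1, 1)), "positive")
  expect_error(saxs_profile(c(0.1, 0.2), c(1, 1), c(-1, 0)), "sigma")
  expect_error(saxs_profile(c(0.1, 0.2), 1), "equal length")
})
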