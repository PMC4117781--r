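test_that("model histogram reproduces closed forms on two beads", {
  two <- nucsaxs:::new_conformer(
    tibble::tibble(x = c(0, 40), y = 0, z = 0, phase = "DNA"), 1, 0, 0, "two")
  d <- pofr_from_model(two, bin_width = 1, smear_sigma = 0)
  expect_equal(attr(d, "dmax"), 40)
  # exact bead-model moment, self-correlation included: rg = d/2
  expect_equal(attr(d, "rg"), 20, tolerance = 1e-6)
  # single occupied bin at the bead separation
  expect_equal(d$r[which.max(d$p)], 40)
  expect_equal(sum(d$p > 0), 1)
  expect_error(pofr_from_model(two, bin_width = 0), "bin_width")
})

test_that("histogram normalization and moments match the Debye I(0) and
           coordinate Rg", {
  for (cf in list(build_wrapped(147), build_released(147, 74, 0))) {
    d <- pofr_from_model(cf)
    expect_lt(abs(attr(d, "i0") / i0_of(cf) - 1), 0.005)
    expect_lt(abs(attr(d, "rg") / rg_of(cf) - 1), 0.03)
  }
})

test_that("regularized inversion recovers the analytic sphere", {
  R <- 50
  p <- sphere_profile(R)
  f <- ift_regularized(p, dmax = 2 * R * 1.05)
  expect_lt(abs(attr(f, "rg") / (sqrt(3 / 5) * R) - 1), 0.01)
  pa <- sphere_pddf_values(f$r, R, i0 = attr(f, "i0"))
  expect_lt(sqrt(sum((f$p - pa)^2) / sum(pa^2)), 0.05)
  # invariants of the returned distribution
  expect_true(all(f$p >= 0))
  expect_equal(f$p[1], 0)
  expect_equal(f$p[nrow(f)], 0)
})

test_that("reciprocal-space and real-space routes agree (round trip)", {
  w <- build_wrapped(147)
  p <- noisy_profile(debye_profile(w, smear_sigma = 3), 0.01, seed = 4)
  f <- ift_regularized(p, dmax = 120)
  h <- pofr_from_model(w)
  # compare at the band-limited resolution of the measurement (~pi/qmax)
  expect_lt(rel_l2(h$r, h$p, f$r, f$p, 10, attr(h, "dmax"), smooth = 9),
            0.05)
  expect_lt(abs(attr(f, "rg") / rg_of(w) - 1), 0.03)
})

test_that("q-range truncation barely moves the recovered Rg", {
  w <- build_wrapped(147)
  p <- noisy_profile(debye_profile(w, smear_sigma = 3), 0.005, seed = 2)
  f_full <- ift_regularized(p, dmax = 120)
  trunc <- p[p$q <= 0.1, ]
  p_tr <- saxs_profile(trunc$q, trunc$I, trunc$sigma)
  f_tr <- ift_regularized(p_tr, dmax = 120)
  expect_lt(abs(attr(f_tr, "rg") / attr(f_full, "rg") - 1), 0.02)
})

test_that("misfit grows monotonically with regularization strength", {
  p <- noisy_profile(debye_profile(build_wrapped(147), smear_sigma = 3),
                     0.01, seed = 3)
  chi2 <- vapply(10^c(-6, -4, -2, 0, 2),
                 function(a) attr(ift_regularized(p, 120, alpha = a), "chi2"),
                 0)
  expect_true(all(diff(chi2) > -1e-8))
})

test_that("invalid uncertainties are rejected", {
  p <- debye_profile(build_wrapped(147))
  expect_error(ift_regularized(p, 120), "uncertainties")
})

test_that("Dmax scan selects the true extent of the wrapped model", {
  w <- build_wrapped(147)
  p <- noisy_profile(debye_profile(w, smear_sigma = 3), 0.01, seed = 5)
  s <- scan_dmax(p, seq(80, 200, by = 15))
  expect_lt(abs(attr(s, "dmax") / dmax_of(w) - 1), 0.10)
  expect_false("unstable" %in% attr(s, "flags"))
  expect_true(is.data.frame(attr(s, "scan")))
})

test_that("Dmax scan approaches the free-DNA length on extended profiles", {
  d <- build_duplex(149)
  p <- noisy_profile(debye_profile(d, sucrose = 0.5, nacl = 2,
                                   smear_sigma = 3), 0.005, seed = 9)
  s <- scan_dmax(p, seq(300, 620, by = 40))
  expect_gt(attr(s, "dmax"), 0.9 * 500)
  expect_lt(attr(s, "dmax"), 1.25 * 500)
})

test_that("Dmax scan flags candidates far below the true extent", {
  w <- build_wrapped(147)
  p <- noisy_profile(debye_profile(w, smear_sigma = 3), 0.01, seed = 6)
  s <- scan_dmax(p, c(40, 50, 60))
  expect_true("unstable" %in% attr(s, "flags"))
  expect_error(scan_dmax(p, c(100, 120)), ">= 3")
})

test_that("moments are stable to noise across seeds", {
  w <- build_wrapped(147)
  base <- debye_profile(w, smear_sigma = 3)
  rg <- vapply(1:10, function(s) {
    attr(ift_regularized(noisy_profile(base, 0.01, seed = s), 120), "rg")
  }, 0)
  expect_true(all(abs(rg / rg_of(w) - 1) < 0.05))
})

test_that("PDDF moments follow their definitions", {
  # narrow distribution at r = d: curve second moment gives rg = d/sqrt(2)
  r <- seq(0, 100, by = 0.5)
  p <- dnorm(r, 60, 0.5)
  d <- nucsaxs:::new_pddf(r, p, dmax = 100, method = "test")
  m <- rg_i0_from_pofr(d)
  expect_equal(m$rg, 60 / sqrt(2), tolerance = 1e-3)
  expect_equal(m$i0, attr(d, "i0"))
  # sphere closed form (continuous particle: self term infinitesimal)
  rs <- seq(0, 100, by = 0.5)
  ds <- nucsaxs:::new_pddf(rs, sphere_pddf_values(rs, 50), dmax = 100,
                           method = "test")
  expect_equal(rg_i0_from_pofr(ds)$rg, sqrt(3 / 5) * 50, tolerance = 1e-3)
})
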