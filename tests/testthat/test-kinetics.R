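test_that("stopped-flow mixing arithmetic is exact", {
  expect_equal(mixing_concentration(0.2, 3.0, c(2, 3)), 1.88)
  expect_equal(mixing_concentration(0.7, 0.7, c(5, 1)), 0.7)
  expect_equal(mixing_concentration(0.2, 3.0, c(1, 1)), 1.6)
  expect_error(mixing_concentration(-0.1, 1), "non-negative")
  expect_error(mixing_concentration(0.2, 3, c(0, 0)), "zero total volume")
})

test_that("time binning averages by inverse variance and conserves it", {
  q <- qgrid_default(40)
  prof <- function(t) saxs_profile(q, exp(-q * 20), sigma = rep(0.05, 40),
                                   time = t)
  ts <- saxs_series(purrr::map(1:8, prof), (1:8) * 0.02)
  b <- bin_time(ts, per_bin = 4)
  expect_equal(nrow(b), 2)
  # identical frames: same profile, sigma down by sqrt(4)
  expect_equal(b$profile[[1]]$I, ts$profile[[1]]$I)
  expect_equal(b$profile[[1]]$sigma, rep(0.05 / 2, 40))
  iv <- function(s) sum(vapply(s$profile, function(p) sum(1 / p$sigma^2), 0))
  expect_equal(iv(b), iv(ts))
  # single frame per bin is the identity
  b1 <- bin_time(ts, per_bin = 1)
  expect_equal(b1$profile[[3]]$I, ts$profile[[3]]$I)
  # log-spaced bins have monotone times spanning the series
  ts2 <- simulate_disassembly(scheme_601(),
                              times = seq(0.02, 60, length.out = 300),
                              seed = 1)
  b12 <- bin_time(ts2, bins = 12)
  expect_true(all(diff(b12$time) > 0))
  expect_gte(min(b12$time), 0.02)
  expect_lte(max(b12$time), 60)
})

test_that("SVD counts spectrally distinct species", {
  q <- qgrid_default(60)
  base <- exp(-q^2 * 1600)
  # one species, scaled copies
  ts1 <- saxs_series(purrr::map(1:10, function(i) {
    saxs_profile(q, base * (1 + 0.1 * i), sigma = rep(1e-6, 60))
  }), (1:10) * 0.1)
  expect_equal(svd_analysis(ts1)$n_significant, 1)
  # two interconverting species
  other <- exp(-q * 25)
  f <- seq(0, 1, length.out = 12)
  ts2 <- saxs_series(purrr::map(f, function(fi) {
    saxs_profile(q, (1 - fi) * base + fi * other, sigma = rep(1e-6, 60))
  }), seq(0.1, 1.2, by = 0.1))
  expect_equal(svd_analysis(ts2)$n_significant, 2)
  expect_error(svd_analysis(ts1[1, ]), ">= 2 frames")
})

test_that("three-species disassembly shows at least two SVD components
           across seeds", {
  counts <- vapply(1:10, function(s) {
    ts <- simulate_disassembly(scheme_5s(),
                               times = exp(seq(log(0.005), log(10),
                                               length.out = 60)),
                               noise = noise_model(0.01), seed = s)
    svd_analysis(ts)$n_significant
  }, 0L)
  expect_true(all(counts >= 2))
})

test_that("I(0) and Rg traces reflect the kinetic scheme", {
  # stationary series -> flat traces
  q <- qgrid_default(60)
  ts0 <- saxs_series(purrr::map(1:6, function(i) {
    saxs_profile(q, exp(-q^2 * 1600), sigma = rep(1e-5, 60))
  }), (1:6) * 0.1)
  tr0 <- trace_i0_rg(ts0)
  expect_lt(diff(range(tr0$i0)) / mean(tr0$i0), 1e-9)

  # contrast-matched: protein release invisible, DNA expansion visible;
  # the extrapolated I(0) (P(r) route) stays flat while Rg rises
  times <- exp(seq(log(0.02), log(60), length.out = 80))
  ts50 <- simulate_disassembly(scheme_601(), times = times, sucrose = 0.5,
                               noise = noise_model(0.005), seed = 2)
  tr50 <- trace_i0_rg(bin_time(ts50, bins = 8), method = "pofr",
                      dmax_candidates = seq(100, 560, by = 60))
  early <- tr50$time < 0.15
  late <- tr50$time > 20
  expect_lt(abs(mean(tr50$i0[late]) / mean(tr50$i0[early]) - 1), 0.1)
  trq <- trace_i0_rg(ts50)
  expect_gt(mean(trq$rg[trq$time > 20], na.rm = TRUE),
            mean(trq$rg[trq$time < 0.15], na.rm = TRUE))

  # 0% sucrose: I(0) flat through the hold, then decays
  ts0s <- simulate_disassembly(scheme_601(), times = times, sucrose = 0,
                               noise = noise_model(0.005), seed = 3)
  tr0s <- trace_i0_rg(ts0s)
  hold <- tr0s$time < 0.19
  expect_lt(abs(mean(tr0s$i0[hold]) / tr0s$i0[1] - 1), 0.05)
  expect_lt(mean(tr0s$i0[late]), 0.8 * mean(tr0s$i0[hold]))
})

test_that("exponential fits recover constructed rates", {
  t <- seq(0.02, 12, by = 0.02)
  y1 <- 2 + 5 * exp(-0.9 * t)
  f1 <- fit_exponential(tibble::tibble(time = t, value = y1), 1)
  expect_equal(f1$rates, 0.9, tolerance = 1e-6)
  expect_equal(f1$baseline, 2, tolerance = 1e-6)

  y2 <- 1 + 4 * exp(-20 * t) + 3 * exp(-0.5 * t)
  f2 <- fit_exponential(tibble::tibble(time = t, value = y2), 2)
  expect_equal(sort(f2$rates), c(0.5, 20), tolerance = 0.01)

  # double-exponential on single-exponential data degenerates gracefully
  f12 <- fit_exponential(tibble::tibble(time = t, value = y1), 2)
  small <- min(abs(f12$amplitudes))
  expect_true(small < 0.05 * max(abs(f12$amplitudes)) ||
                length(f12$warnings) > 0)
  expect_error(fit_exponential(tibble::tibble(time = 1:3, value = 1:3), 2),
               "too few")
})

test_that("single-exponential recovery is unbiased with calibrated
           uncertainties at the default noise", {
  fits <- purrr::map(1:20, function(s) {
    ts <- simulate_disassembly(scheme_601(),
                               times = seq(0.02, 20, by = 0.04), seed = s)
    tr <- trace_i0_rg(ts)
    fit_exponential(tibble::tibble(time = tr$time, value = tr$i0), 1,
                    t_min = 0.2)
  })
  rates <- purrr::map_dbl(fits, "rates")
  ses <- purrr::map_dbl(fits, "rate_se")
  expect_lt(abs(mean(rates) / 0.74 - 1), 0.05)
  # 68% interval coverage consistent with the reported uncertainties
  coverage <- mean(abs(rates - 0.74) <= ses)
  expect_gte(coverage, 0.55)
  expect_lte(coverage, 0.95)
})

test_that("model selection separates the two constructs", {
  ts1 <- simulate_disassembly(scheme_601(), times = seq(0.02, 20, by = 0.04),
                              seed = 8)
  tr1 <- trace_i0_rg(ts1)
  expect_equal(as.integer(model_selection(
    tibble::tibble(time = tr1$time, value = tr1$i0), t_min = 0.2)), 1L)

  ts2 <- simulate_disassembly(scheme_5s(), times = seq(0.005, 10, by = 0.01),
                              seed = 9)
  tr2 <- trace_i0_rg(ts2)
  expect_equal(as.integer(model_selection(
    tibble::tibble(time = tr2$time, value = tr2$i0))), 2L)

  # flat trace: single exponential with negligible amplitude
  set.seed(1)
  flat <- tibble::tibble(time = seq(0.1, 10, by = 0.1),
                         value = 5 + rnorm(100, 0, 0.01))
  pick <- model_selection(flat)
  expect_equal(as.integer(pick), 1L)
  f1 <- attr(pick, "fit1")
  expect_lt(abs(f1$amplitudes[1]), 0.05 * 5)
})
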