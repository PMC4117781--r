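#' Final concentration after stopped-flow mixing
#'
#' Volume-weighted mean of sample and buffer concentrations, e.g. NCPs in
#' 0.2 M NaCl mixed 2:3 with 3.0 M buffer give 1.88 M final.
#'
#' @param c_sample,c_buffer Concentrations, mol/L (>= 0).
#' @param ratio Mixing ratio sample:buffer as a length-2 numeric (parts > 0).
#' @return Final concentration, mol/L.
#' @examples
#' mixing_concentration(0.2, 3.0, c(2, 3)) # 1.88
#' @export
mixing_concentration <- function(c_sample, c_buffer, ratio = c(2, 3)) {
  if (c_sample < 0 || c_buffer < 0) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (length(ratio) != 2 || any(ratio <= 0)) {
    stop("ratio must be two positive parts (zero total volume otherwise)",
         call. = FALSE)
  }
  (c_sample * ratio[1] + c_buffer * ratio[2]) / sum(ratio)
}

#' Time series of scattering profiles
#'
#' A `saxs_series` is a tibble with a `time` column (seconds, strictly
#' increasing) and a `profile` list-column of [saxs_profile()] objects on a
#' common q-grid, with attribute `frame_duration` (seconds).
#'
#' @param profiles List of [saxs_profile()] objects.
#' @param times Frame times, seconds.
#' @param frame_duration Frame duration, seconds.
#' @return A `saxs_series` tibble.
#' @export
saxs_series <- function(profiles, times, frame_duration = 0.02) {
  if (length(profiles) != length(times)) {
    stop("profiles and times must have equal length", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  if (frame_duration <= 0) stop("frame_duration must be > 0", call. = FALSE)
  out <- tibble::tibble(time = times, profile = profiles)
  attr(out, "frame_duration") <- frame_duration
  class(out) <- c("saxs_series", class(out))
  out
}

#' @export
print.saxs_series <- function(x, ...) {
  cat(sprintf("<saxs_series> %d frames, t %.3g-%.3g s, frame %.3g s\n",
              nrow(x), min(x$time), max(x$time), attr(x, "frame_duration")))
  NextMethod()
}

series_matrix <- function(ts) {
  q <- ts$profile[[1]]$q
  I <- vapply(ts$profile, function(p) {
    if (length(p$q) != length(q) || any(p$q != q)) {
      stop("frames must share a common q-grid", call. = FALSE)
    }
    p$I
  }, numeric(length(q)))
  S <- vapply(ts$profile, function(p) p$sigma, numeric(length(q)))
  list(q = q, I = I, sigma = S)
}

#' Bin a time series to improve signal-to-noise
#'
#' Frames within a bin are combined by inverse-variance weighting (plain
#' mean when uncertainties are absent); sigma propagates as
#' 1/sqrt(sum(1/sigma^2)), so a bin of n identical frames has its sigma
#' reduced by sqrt(n). Bin times are exposure-weighted mean frame times.
#'
#' @param ts A [saxs_series()].
#' @param bins Either a single number of log-spaced bins over the time
#'   span, or an explicit vector of bin edges (seconds).
#' @param per_bin Alternatively, a fixed number of consecutive frames per
#'   bin (overrides `bins`).
#' @return A binned `saxs_series`; empty bins are dropped with a warning.
#' @export
bin_time <- function(ts, bins = 12, per_bin = NULL) {
  if (!nrow(ts)) stop("empty time series", call. = FALSE)
  if (!is.null(per_bin)) {
    idx <- ceiling(seq_len(nrow(ts)) / per_bin)
  } else if (length(bins) == 1) {
    edges <- exp(seq(log(min(ts$time) * 0.999), log(max(ts$time) * 1.001),
                     length.out = bins + 1))
    idx <- findInterval(ts$time, edges, rightmost.closed = TRUE)
  } else {
    idx <- findInterval(ts$time, bins, rightmost.closed = TRUE)
    drop <- idx < 1 | idx >= length(bins)
    if (any(idx < 1 | idx > length(bins) - 1)) {
      ts <- ts[idx >= 1 & idx <= length(bins) - 1, ]
      idx <- idx[idx >= 1 & idx <= length(bins) - 1]
    }
  }
  groups <- split(seq_len(nrow(ts)), idx)
  mats <- series_matrix(ts)
  binned <- purrr::map(groups, function(rows) {
    I <- mats$I[, rows, drop = FALSE]
    S <- mats$sigma[, rows, drop = FALSE]
    if (all(S > 0)) {
      wt <- 1 / S^2
      Ib <- rowSums(I * wt) / rowSums(wt)
      Sb <- 1 / sqrt(rowSums(wt))
    } else {
      Ib <- rowMeans(I)
      Sb <- sqrt(rowSums(S^2)) / length(rows)
    }
    saxs_profile(mats$q, Ib, Sb, time = mean(ts$time[rows]),
                 salt = attr(ts$profile[[rows[1]]], "salt"),
                 sucrose = attr(ts$profile[[rows[1]]], "sucrose"),
                 label = sprintf("bin_%d", rows[1]))
  })
  tb <- purrr::map_dbl(groups, ~ mean(ts$time[.x]))
  saxs_series(unname(binned), unname(tb),
              frame_duration = attr(ts, "frame_duration"))
}

#' Kinetic singular value decomposition of a time series
#'
#' Decomposes the q-by-time intensity matrix (each q-row weighted by its
#' mean uncertainty) and counts significant components: those whose singular
#' value exceeds `ratio_threshold` times the noise floor (the median
#' singular value) and whose left (q-space) and right (time-space) vectors
#' are both smooth, with lag-1 autocorrelation above `autocorr_threshold`.
#'
#' @param ts A [saxs_series()] with >= 2 frames on a common q-grid.
#' @param ratio_threshold Singular-value to noise-floor ratio required.
#' @param autocorr_threshold Lag-1 autocorrelation required of both vectors.
#' @return An `svd_result` with `singular_values`, `u`, `v`,
#'   `n_significant` and the per-component diagnostics tibble `components`.
#' @export
svd_analysis <- function(ts, ratio_threshold = 3, autocorr_threshold = 0.6) {
  if (nrow(ts) < 2) stop("need >= 2 frames", call. = FALSE)
  mats <- series_matrix(ts)
  wq <- rowMeans(mats$sigma)
  wq[wq <= 0] <- if (any(wq > 0)) min(wq[wq > 0]) else 1
  A <- mats$I / wq
  sv <- svd(A)
  lag1 <- function(x) {
    if (length(x) < 3 || stats::sd(x) == 0) return(0)
    stats::cor(x[-1], x[-length(x)])
  }
  floor_sv <- stats::median(sv$d)
  comp <- tibble::tibble(
    component = seq_along(sv$d),
    singular_value = sv$d,
    sv_ratio = sv$d / max(floor_sv, .Machine$double.eps),
    autocorr_q = apply(sv$u, 2, lag1),
    autocorr_t = apply(sv$v, 2, lag1)
  )
  comp$significant <- comp$sv_ratio > ratio_threshold &
    comp$autocorr_q > autocorr_threshold &
    comp$autocorr_t > autocorr_threshold
  out <- list(singular_values = sv$d, u = sv$u, v = sv$v,
              q = mats$q, time = ts$time,
              n_significant = sum(comp$significant), components = comp)
  class(out) <- "svd_result"
  out
}

#' @export
print.svd_result <- function(x, ...) {
  cat(sprintf("<svd_result> %d significant of %d components\n",
              x$n_significant, length(x$singular_values)))
  print(utils::head(x$components, 5))
  invisible(x)
}

#' Extract I(0) and Rg traces from a time series
#'
#' For each (binned) frame, estimates the forward intensity and radius of
#' gyration. `method = "pofr"` runs the full Dmax scan and P(r) moments per
#' frame (as in the equilibrium analysis; slow but principled);
#' `method = "lowq"` (default) estimates I(0) as the mean intensity over the
#' lowest `n_lowq` points - a linear functional of the profile, so mixtures
#' of interconverting species keep exactly exponential I(0,t) kinetics even
#' when q_min Rg is large and the absolute extrapolation is biased - and Rg
#' from the Guinier slope over the same window. Frames whose analysis fails
#' are flagged, not fatal.
#'
#' @param ts A [saxs_series()] (bin first for noisy data).
#' @param method `"lowq"` or `"pofr"`.
#' @param dmax_candidates Dmax candidates for the `"pofr"` scan.
#' @param n_lowq Number of low-q points for the fast estimate.
#' @param ... Passed to [scan_dmax()].
#' @return A tibble with columns `time`, `i0`, `rg`, `ok`.
#' @export
trace_i0_rg <- function(ts, method = c("lowq", "pofr"),
                        dmax_candidates = seq(80, 560, by = 40),
                        n_lowq = 15, ...) {
  method <- match.arg(method)
  rows <- purrr::map2(ts$profile, ts$time, function(p, tm) {
    res <- tryCatch({
      if (method == "pofr") {
        d <- scan_dmax(p, dmax_candidates, ...)
        m <- rg_i0_from_pofr(d)
        list(i0 = m$i0, rg = m$rg)
      } else {
        n <- min(n_lowq, nrow(p))
        qq <- p$q[seq_len(n)]^2
        li <- log(pmax(p$I[seq_len(n)], .Machine$double.xmin))
        sl <- stats::coef(stats::lm(li ~ qq))[2]
        list(i0 = mean(p$I[seq_len(n)]),
             rg = if (sl < 0) sqrt(-3 * sl) else NA_real_)
      }
    }, error = function(e) NULL)
    if (is.null(res)) {
      tibble::tibble(time = tm, i0 = NA_real_, rg = NA_real_, ok = FALSE)
    } else {
      tibble::tibble(time = tm, i0 = res$i0, rg = res$rg, ok = TRUE)
    }
  })
  dplyr::bind_rows(rows)
}

#' Fit a single- or double-exponential decay to a kinetic trace
#'
#' Weighted least squares of value = baseline + sum_i A_i exp(-k_i t), with
#' decade-spaced multi-start over initial rates (initial rate pairs for the
#' double exponential are constrained to ratio > 2). Rates are bounded
#' positive; uncertainties come from the fit covariance.
#'
#' @param trace A tibble with columns `time`, `value` and optionally
#'   `sigma` (used as weights when present and positive).
#' @param n_exp 1 or 2 exponential components.
#' @param t_min Discard points earlier than this time (e.g. a hold phase).
#' @param rate_grid Multi-start initial rates, 1/s.
#' @return A `kinetic_fit` list: `n_exp`, `rates`, `rate_se`, `amplitudes`,
#'   `amplitude_se`, `baseline`, `chi2` (reduced), `rms`, `fitted`,
#'   `warnings`.
#' @export
fit_exponential <- function(trace, n_exp = 1, t_min = NULL,
                            rate_grid = 10^seq(-2, 2, by = 1)) {
  stopifnot(n_exp %in% c(1, 2))
  tr <- trace[stats::complete.cases(trace[, c("time", "value")]), ]
  if (!is.null(t_min)) tr <- tr[tr$time >= t_min, ]
  if (nrow(tr) < 2 * n_exp + 2) {
    stop("too few points for the requested model", call. = FALSE)
  }
  w <- if ("sigma" %in% names(tr) && all(tr$sigma > 0)) 1 / tr$sigma^2 else
    rep(1, nrow(tr))
  dat <- data.frame(t = tr$time, y = tr$value, w = w)
  span <- max(dat$y) - min(dat$y)

  starts <- if (n_exp == 1) {
    purrr::map(rate_grid, ~ list(b = min(dat$y), A1 = span, k1 = .x))
  } else {
    grid <- expand.grid(k1 = rate_grid, k2 = rate_grid)
    grid <- grid[grid$k1 / grid$k2 > 2, ] # distinct rates at init
    purrr::map(seq_len(nrow(grid)),
               ~ list(b = min(dat$y), A1 = span / 2, k1 = grid$k1[.x],
                      A2 = span / 2, k2 = grid$k2[.x]))
  }
  form <- if (n_exp == 1) {
    y ~ b + A1 * exp(-k1 * t)
  } else {
    y ~ b + A1 * exp(-k1 * t) + A2 * exp(-k2 * t)
  }
  lower <- if (n_exp == 1) c(-Inf, -Inf, 1e-6) else
    c(-Inf, -Inf, 1e-6, -Inf, 1e-6)

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = st, weights = dat$w,
                        lower = lower,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(dat$w * stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop("solver failure: no exponential fit converged from any start",
         call. = FALSE)
  }
  fit <- best$fit
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    rep(NA_real_, length(cf)))
  names(se) <- names(cf)
  warn <- character()
  if (n_exp == 2) {
    ks <- sort(c(cf[["k1"]], cf[["k2"]]))
    if (ks[2] / ks[1] < 2) warn <- c(warn, "rate_degeneracy")
    amp <- c(cf[["A1"]], cf[["A2"]])
    if (any(abs(amp) < 2 * se[c("A1", "A2")], na.rm = TRUE)) {
      warn <- c(warn, "weak_amplitude")
    }
  }
  dof <- nrow(dat) - length(cf)
  out <- list(
    n_exp = n_exp,
    rates = unname(cf[grep("^k", names(cf))]),
    rate_se = unname(se[grep("^k", names(cf))]),
    amplitudes = unname(cf[grep("^A", names(cf))]),
    amplitude_se = unname(se[grep("^A", names(cf))]),
    baseline = unname(cf[["b"]]),
    chi2 = best$rss / max(dof, 1),
    rms = sqrt(mean(stats::residuals(fit)^2)),
    fitted = tibble::tibble(time = dat$t, value = dat$y,
                            fit = stats::fitted(fit)),
    warnings = warn
  )
  class(out) <- "kinetic_fit"
  out
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> %d-exponential, reduced chi2 %.3g\n", x$n_exp,
              x$chi2))
  for (i in seq_along(x$rates)) {
    cat(sprintf("  k%d = %.4g +/- %.2g 1/s (amplitude %.4g)\n", i,
                x$rates[i], x$rate_se[i], x$amplitudes[i]))
  }
  cat(sprintf("  baseline %.4g\n", x$baseline))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = ", "),
                              "\n")
  invisible(x)
}

#' Choose between single- and double-exponential kinetics
#'
#' Fits both models and selects the double exponential only when it improves
#' the reduced chi-squared by more than `improvement` (fractional) and its
#' smaller amplitude is significant (> 3 standard errors).
#'
#' @inheritParams fit_exponential
#' @param improvement Required fractional reduced-chi2 improvement.
#' @return 1 or 2, with both fits attached as attributes `fit1`, `fit2`.
#' @export
model_selection <- function(trace, t_min = NULL, improvement = 0.15, ...) {
  f1 <- fit_exponential(trace, n_exp = 1, t_min = t_min, ...)
  f2 <- tryCatch(fit_exponential(trace, n_exp = 2, t_min = t_min, ...),
                 error = function(e) NULL)
  pick <- 1L
  if (!is.null(f2)) {
    small <- which.min(abs(f2$amplitudes))
    amp_ok <- is.finite(f2$amplitude_se[small]) &&
      abs(f2$amplitudes[small]) > 3 * f2$amplitude_se[small]
    if (f2$chi2 < (1 - improvement) * f1$chi2 && amp_ok &&
        !("rate_degeneracy" %in% f2$warnings)) {
      pick <- 2L
    }
  }
  attr(pick, "fit1") <- f1
  attr(pick, "fit2") <- f2
  pick
}
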