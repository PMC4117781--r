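#' Detect the diagnostic d1/d2/d3 length scales in a P(r)
#'
#' Searches a smoothed P(r) for local maxima in three windows tied to
#' nucleosomal DNA structure: d1 (10-30 Angstrom, the duplex diameter),
#' d2 (30-55 Angstrom, the separation of overlapping DNA ends) and d3
#' (55-100 Angstrom, the diameter of the wrapped superhelix). A feature is
#' called present when a local maximum in its window has prominence of at
#' least `prominence_frac` of the global maximum.
#'
#' @param pddf A `pddf`.
#' @param smooth_span Moving-average window in grid points applied before
#'   peak finding (use ~9 for noisy experimental P(r), the default 5 for
#'   model histograms).
#' @param prominence_frac Minimum peak prominence as a fraction of the
#'   global maximum of P(r).
#' @return A `feature_report`: a tibble with one row per feature (`feature`,
#'   `present`, `location`, `prominence`) carrying `dmax` and any flags as
#'   attributes.
#' @examples
#' detect_peaks(pofr_from_model(build_duplex(149)))
#' @export
detect_peaks <- function(pddf, smooth_span = 5, prominence_frac = 0.05) {
  windows <- list(d1 = c(10, 30), d2 = c(30, 55), d3 = c(55, 100))
  r <- pddf$r
  p <- as.numeric(stats::filter(pddf$p, rep(1 / smooth_span, smooth_span),
                                sides = 2))
  p[is.na(p)] <- pddf$p[is.na(p)]
  pk <- find_local_maxima(p)
  gmax <- max(p)
  flags <- character()
  if (attr(pddf, "dmax") < 100) flags <- "d3_window_truncated"
  rows <- purrr::map(names(windows), function(nm) {
    wn <- windows[[nm]]
    sel <- pk[r[pk$index] >= wn[1] & r[pk$index] <= wn[2] &
                pk$prominence >= prominence_frac * gmax, ]
    if (nrow(sel)) {
      best <- sel[which.max(sel$prominence), ]
      tibble::tibble(feature = nm, present = TRUE,
                     location = r[best$index],
                     prominence = best$prominence / gmax)
    } else {
      tibble::tibble(feature = nm, present = FALSE, location = NA_real_,
                     prominence = NA_real_)
    }
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "dmax") <- attr(pddf, "dmax")
  attr(out, "flags") <- flags
  class(out) <- c("feature_report", class(out))
  out
}

# local maxima with a simple prominence measure: height above the higher of
# the two bounding valleys (valley = minimum before the next higher point,
# or the series end)
find_local_maxima <- function(p) {
  n <- length(p)
  idx <- which(diff(sign(diff(p))) < 0) + 1
  if (!length(idx)) {
    return(tibble::tibble(index = integer(), prominence = double()))
  }
  prom <- vapply(idx, function(i) {
    h <- p[i]
    lmin <- h
    j <- i
    while (j > 1 && p[j] <= h) {
      j <- j - 1
      lmin <- min(lmin, p[j])
    }
    if (j == 1 && p[1] <= h) lmin <- min(lmin, min(p[1:i]))
    rmin <- h
    j <- i
    while (j < n && p[j] <= h) {
      j <- j + 1
      rmin <- min(rmin, p[j])
    }
    if (j == n && p[n] <= h) rmin <- min(rmin, min(p[i:n]))
    h - max(lmin, rmin)
  }, 0)
  tibble::tibble(index = idx, prominence = prom)
}

#' Call the DNA wrapping state from a feature report
#'
#' Maps the d-feature pattern and Dmax to a state:
#' * `wrapped`: d2 and d3 present with Dmax < 150 Angstrom (compact particle);
#' * `intermediate_J`: d3 present, d2 absent, Dmax > 250 Angstrom (one arm
#'   released, near-complete wrap retained, ends no longer overlapping);
#' * `unwrapped`: d1 present, d3 absent, Dmax > 400 Angstrom (free duplex);
#' * otherwise `ambiguous`.
#'
#' P(r) is mirror-symmetric, so left- versus right-end release cannot be
#' distinguished here; asymmetry quantification is the ensemble module's job.
#'
#' @param report A `feature_report` from [detect_peaks()].
#' @return One of `"wrapped"`, `"intermediate_J"`, `"unwrapped"`,
#'   `"ambiguous"`.
#' @export
call_state <- function(report) {
  has <- function(f) report$present[report$feature == f]
  dmax <- attr(report, "dmax")
  if (has("d2") && has("d3") && dmax < 150) return("wrapped")
  if (has("d3") && !has("d2") && dmax > 250) return("intermediate_J")
  if (has("d1") && !has("d3") && dmax > 400) return("unwrapped")
  "ambiguous"
}
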