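#' Detector image and reduction geometry containers
#'
#' A `detector_image` holds a non-negative counts matrix, an optional
#' logical mask (TRUE = use pixel), the exposure time and a beam-monitor
#' reading. A `reduction_geometry` holds the beam centre (pixels), pixel
#' size (mm), sample-detector distance (mm) and wavelength (Angstrom).
#'
#' @param counts Non-negative numeric matrix of pixel counts.
#' @param mask Logical matrix (TRUE = pixel used); defaults to all TRUE.
#' @param exposure Exposure time, seconds (> 0).
#' @param monitor Incident-beam monitor counts (> 0).
#' @return A `detector_image` list.
#' @export
detector_image <- function(counts, mask = NULL, exposure = 1, monitor = 1) {
  counts <- as.matrix(counts)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(counts), ncol(counts))
  if (any(counts[mask] < 0)) stop("counts must be non-negative where unmasked",
                                  call. = FALSE)
  if (exposure <= 0) stop("exposure must be > 0", call. = FALSE)
  structure(list(counts = counts, mask = mask, exposure = exposure,
                 monitor = monitor),
            class = "detector_image")
}

#' @rdname detector_image
#' @param beam_center Beam centre (row, column), pixels.
#' @param pixel_size Pixel size, mm.
#' @param distance Sample-detector distance, mm (> 0).
#' @param wavelength X-ray wavelength, Angstrom (> 0).
#' @export
reduction_geometry <- function(beam_center = c(0, 0), pixel_size = 0.172,
                               distance = 1000, wavelength = 1.17) {
  if (distance <= 0 || wavelength <= 0) {
    stop("distance and wavelength must be > 0", call. = FALSE)
  }
  structure(list(beam_center = beam_center, pixel_size = pixel_size,
                 distance = distance, wavelength = wavelength),
            class = "reduction_geometry")
}

#' Momentum transfer at a detector position
#'
#' q = (4 pi / lambda) sin( atan(r / D) / 2 ), with r the radial distance
#' from the beam centre on the detector and D the sample-detector distance.
#'
#' @param geometry A [reduction_geometry()].
#' @param r_mm Radial distance(s) from the beam centre, mm.
#' @return q in 1/Angstrom.
#' @export
q_of_pixel <- function(geometry, r_mm) {
  (4 * pi / geometry$wavelength) *
    sin(atan2(r_mm, geometry$distance) / 2)
}

pixel_q_map <- function(img, geometry) {
  nr <- nrow(img$counts)
  nc <- ncol(img$counts)
  dr <- (row(img$counts) - geometry$beam_center[1]) * geometry$pixel_size
  dc <- (col(img$counts) - geometry$beam_center[2]) * geometry$pixel_size
  q_of_pixel(geometry, sqrt(dr^2 + dc^2))
}

#' Azimuthal average of a detector image
#'
#' Averages unmasked pixel values in annuli of equal q; per-annulus
#' uncertainty is the pixel standard deviation divided by the square root
#' of the number of pixels binned. Empty annuli are omitted.
#'
#' @param img A [detector_image()].
#' @param geometry A [reduction_geometry()].
#' @param n_bins Number of q annuli (bin width ~ one-pixel resolution at
#'   the detector edge when NULL).
#' @return A [saxs_profile()] (q = mean pixel q per annulus).
#' @export
azimuthal_average <- function(img, geometry, n_bins = NULL) {
  qmap <- pixel_q_map(img, geometry)
  use <- img$mask & is.finite(img$counts)
  if (!any(use)) stop("no unmasked pixels", call. = FALSE)
  qv <- qmap[use]
  cv <- img$counts[use]
  if (is.null(n_bins)) {
    # ~one-pixel q resolution at the detector edge
    n_bins <- max(16, floor(max(dim(img$counts)) / 2))
  }
  edges <- seq(0, max(qv) * (1 + 1e-9), length.out = n_bins + 1)
  bin <- findInterval(qv, edges, rightmost.closed = TRUE)
  keep <- bin >= 1
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bin[keep], q = qv[keep],
                                   I = cv[keep]), .data$bin),
    q = mean(.data$q),
    sigma = if (dplyr::n() > 1) stats::sd(.data$I) / sqrt(dplyr::n()) else 0,
    npix = dplyr::n(),
    I = mean(.data$I),
    .groups = "drop"
  )
  agg <- agg[agg$q > 0, ]
  agg <- agg[order(agg$q), ]
  saxs_profile(agg$q, agg$I, agg$sigma, label = "azimuthal_average")
}

#' Normalize by beam monitors and subtract the buffer profile
#'
#' I = I_sample / m_sample - I_buffer / m_buffer on a common q-grid, with
#' uncertainties added in quadrature.
#'
#' @param sample,buffer [saxs_profile()] objects on identical q-grids.
#' @param monitor_sample,monitor_buffer Positive monitor counts.
#' @return A [saxs_profile()].
#' @export
normalize_and_subtract <- function(sample, buffer, monitor_sample = 1,
                                   monitor_buffer = 1) {
  if (monitor_sample <= 0 || monitor_buffer <= 0) {
    stop("monitors must be positive", call. = FALSE)
  }
  if (length(sample$q) != length(buffer$q) ||
      any(abs(sample$q - buffer$q) > 1e-9 * sample$q)) {
    stop("sample and buffer must share a q-grid", call. = FALSE)
  }
  I <- sample$I / monitor_sample - buffer$I / monitor_buffer
  sg <- sqrt((sample$sigma / monitor_sample)^2 +
               (buffer$sigma / monitor_buffer)^2)
  saxs_profile(sample$q, I, sg, salt = attr(sample, "salt"),
               sucrose = attr(sample, "sucrose"),
               time = attr(sample, "time"),
               label = paste0(attr(sample, "label"), "-buffer"))
}

#' Inverse-variance average of repeated profiles
#'
#' Combines repeat measurements on a common q-grid by inverse-variance
#' weighting with propagated sigma. Mutually inconsistent repeats (pointwise
#' reduced chi-squared above 2) trigger a warning.
#'
#' @param profiles List of [saxs_profile()] objects on identical q-grids.
#' @return A [saxs_profile()].
#' @export
average_repeats <- function(profiles) {
  if (length(profiles) == 1) return(profiles[[1]])
  q <- profiles[[1]]$q
  I <- vapply(profiles, function(p) {
    if (length(p$q) != length(q) || any(abs(p$q - q) > 1e-9 * q)) {
      stop("profiles must share a q-grid", call. = FALSE)
    }
    p$I
  }, numeric(length(q)))
  S <- vapply(profiles, function(p) p$sigma, numeric(length(q)))
  if (all(S > 0)) {
    wt <- 1 / S^2
    Ib <- rowSums(I * wt) / rowSums(wt)
    Sb <- 1 / sqrt(rowSums(wt))
    chi2 <- mean(rowSums(wt * (I - Ib)^2) / (ncol(I) - 1))
    if (chi2 > 2) {
      warning(sprintf(
        "repeats are mutually inconsistent (mean reduced chi2 %.2f)", chi2))
    }
  } else {
    Ib <- rowMeans(I)
    Sb <- sqrt(rowSums(S^2)) / ncol(S)
  }
  saxs_profile(q, Ib, Sb, salt = attr(profiles[[1]], "salt"),
               sucrose = attr(profiles[[1]], "sucrose"),
               label = "averaged")
}

#' Per-frame radiation-damage drift statistic
#'
#' Correlation of each frame's intensities with the first frame; a steady
#' decline flags exposure-dependent changes. Reported, never auto-rejected.
#'
#' @param ts A [saxs_series()].
#' @return A tibble with columns `time` and `correlation_with_first`.
#' @export
damage_drift <- function(ts) {
  mats <- series_matrix(ts)
  tibble::tibble(
    time = ts$time,
    correlation_with_first = apply(mats$I, 2, stats::cor, y = mats$I[, 1])
  )
}
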