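#' Scattering profiles
#'
#' A scattering profile is a tibble with columns `q` (momentum transfer,
#' 1/Angstrom, strictly increasing and positive), `I` (intensity, arbitrary
#' units) and `sigma` (1-sigma uncertainty), plus metadata attributes
#' `salt` (mol/L NaCl), `sucrose` (weight fraction), `time` (seconds) and
#' `label`.
#'
#' @param q,I,sigma Numeric vectors of equal length.
#' @param salt,sucrose,time,label Metadata.
#' @return A `saxs_profile` tibble.
#' @export
saxs_profile <- function(q, I, sigma = rep(0, length(q)), salt = NA_real_,
                         sucrose = NA_real_, time = NA_real_, label = "") {
  if (length(q) != length(I) || length(q) != length(sigma)) {
    stop("q, I, sigma must have equal length", call. = FALSE)
  }
  if (length(q) && (any(q <= 0) || any(diff(q) <= 0))) {
    stop("q must be positive and strictly increasing", call. = FALSE)
  }
  if (any(sigma < 0)) stop("sigma must be non-negative", call. = FALSE)
  out <- tibble::tibble(q = q, I = I, sigma = sigma)
  attr(out, "salt") <- salt
  attr(out, "sucrose") <- sucrose
  attr(out, "time") <- time
  attr(out, "label") <- label
  class(out) <- c("saxs_profile", class(out))
  out
}

#' @export
print.saxs_profile <- function(x, ...) {
  cat(sprintf("<saxs_profile '%s'> %d points, q %.4g-%.4g 1/A",
              attr(x, "label") %||% "", nrow(x),
              if (nrow(x)) min(x$q) else NA, if (nrow(x)) max(x$q) else NA))
  meta <- c(salt = attr(x, "salt"), sucrose = attr(x, "sucrose"),
            time = attr(x, "time"))
  meta <- meta[!is.na(meta)]
  if (length(meta)) {
    cat(" |", paste(names(meta), signif(unlist(meta), 4), sep = "=",
                    collapse = " "))
  }
  cat("\n")
  NextMethod()
}

profile_meta <- function(p) {
  list(salt = attr(p, "salt"), sucrose = attr(p, "sucrose"),
       time = attr(p, "time"), label = attr(p, "label"))
}

#' Default experimental q-grid
#'
#' 200 log-spaced points over 0.007-0.25 1/Angstrom, the usable range of the
#' equilibrium and stopped-flow measurements the package emulates.
#'
#' @param n Number of points.
#' @param qmin,qmax Range, 1/Angstrom.
#' @return Numeric vector of q values.
#' @export
qgrid_default <- function(n = 200, qmin = 0.007, qmax = 0.25) {
  exp(seq(log(qmin), log(qmax), length.out = n))
}

# sin(x)/x with the x -> 0 limit
sinc <- function(x) ifelse(x == 0, 1, sin(x) / x)

#' Theoretical scattering profile by the Debye formula
#'
#' Orientationally averaged intensity of a bead model:
#' I(q) = sum_ij w_i w_j sin(q r_ij) / (q r_ij), with contrast weights w from
#' the three-phase model at the given solvent composition. Optionally the
#' beads are smeared by a Gaussian of width `smear_sigma` (intensity factor
#' exp(-(q sigma)^2), leaving I(0) unchanged).
#'
#' @param conf A `conformer`.
#' @param qgrid q values, 1/Angstrom.
#' @param sucrose Sucrose weight fraction.
#' @param nacl NaCl concentration, mol/L.
#' @param model A [contrast_model()].
#' @param smear_sigma Gaussian bead smearing width, Angstrom (0 = point beads).
#' @param label Profile label.
#' @return A [saxs_profile()] (with `sigma = 0`; attach noise separately).
#' @examples
#' p <- debye_profile(build_wrapped(147), sucrose = 0.5)
#' @export
debye_profile <- function(conf, qgrid = qgrid_default(), sucrose = 0,
                          nacl = 0, model = contrast_model(),
                          smear_sigma = 0, label = attr(conf, "name")) {
  w <- bead_weights(conf, sucrose, nacl, model)
  debye_profile_w(bead_matrix(conf), w, qgrid, smear_sigma = smear_sigma,
                  salt = nacl, sucrose = sucrose, label = label)
}

# Debye sum over explicit coordinates/weights (shared with multi-particle
# assemblies in the synthetic generator)
debye_profile_w <- function(xyz, w, qgrid, smear_sigma = 0, salt = NA_real_,
                            sucrose = NA_real_, time = NA_real_, label = "") {
  if (all(abs(w) < 1e-12)) {
    stop("degenerate contrast: all bead weights are zero (all phases matched)",
         call. = FALSE)
  }
  keep <- abs(w) > 0
  xyz <- xyz[keep, , drop = FALSE]
  w <- w[keep]
  n <- nrow(xyz)
  self <- sum(w^2)
  if (n > 1) {
    d <- as.vector(stats::dist(xyz))
    ww <- tcrossprod(w)
    ww <- ww[lower.tri(ww)]
    I <- vapply(qgrid, function(q) self + 2 * sum(ww * sinc(q * d)), 0)
  } else {
    I <- rep(self, length(qgrid))
  }
  if (smear_sigma > 0) I <- I * exp(-(qgrid * smear_sigma)^2)
  saxs_profile(qgrid, I, salt = salt, sucrose = sucrose, time = time,
               label = label)
}

#' Forward-scattering intensity of a conformer
#'
#' I(0) = (sum of contrast weights)^2. Because the weights add before being
#' squared, removing the protein beads at 0% sucrose reduces I(0) by more
#' than the protein's share of the total weight; at the protein match point
#' I(0) equals the DNA-only value exactly.
#'
#' @inheritParams debye_profile
#' @return Forward intensity (electrons squared).
#' @export
i0_of <- function(conf, sucrose = 0, nacl = 0, model = contrast_model()) {
  w <- bead_weights(conf, sucrose, nacl, model)
  if (all(abs(w) < 1e-12)) {
    stop("degenerate contrast: all bead weights are zero", call. = FALSE)
  }
  sum(w)^2
}

#' Kratky transform of a profile
#'
#' Pointwise (q, I q^2, sigma q^2). Globular particles show a single
#' dominant peak; extended chains plateau at high q.
#'
#' @param profile A [saxs_profile()].
#' @return A tibble with columns `q`, `iq2`, `sigma_iq2`.
#' @export
kratky <- function(profile) {
  tibble::tibble(q = profile$q, iq2 = profile$I * profile$q^2,
                 sigma_iq2 = profile$sigma * profile$q^2)
}
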