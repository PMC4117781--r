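#' Pair-distance distribution functions
#'
#' A `pddf` is a tibble with columns `r` (Angstrom, spanning 0 to Dmax) and
#' `p` (distribution values, >= 0, pinned to zero at both ends), with
#' attributes `dmax`, `rg`, `i0`, `chi2` (reduced, against the source
#' profile where one exists), `alpha` (regularization strength),
#' `qmax_used`, `method` and `flags`. Normalization follows the
#' forward-scattering convention 4 pi * integral(P dr) = I(0); the radius of
#' gyration is the second moment, rg^2 = integral(r^2 P dr) / (2 integral(P dr)).
#'
#' @name pddf
#' @keywords internal
NULL

new_pddf <- function(r, p, dmax, chi2 = NA_real_, alpha = NA_real_,
                     qmax_used = NA_real_, method = "unknown",
                     flags = character(), rg = NULL, i0 = NULL) {
  ip <- trapz_int(r, p)
  if (ip <= 0) stop("degenerate PDDF: zero integral", call. = FALSE)
  out <- tibble::tibble(r = r, p = p)
  attr(out, "dmax") <- dmax
  attr(out, "rg") <- rg %||% sqrt(trapz_int(r, r^2 * p) / (2 * ip))
  attr(out, "i0") <- i0 %||% (4 * pi * ip)
  attr(out, "chi2") <- chi2
  attr(out, "alpha") <- alpha
  attr(out, "qmax_used") <- qmax_used
  attr(out, "method") <- method
  attr(out, "flags") <- flags
  class(out) <- c("pddf", class(out))
  out
}

#' @export
print.pddf <- function(x, ...) {
  cat(sprintf("<pddf> Dmax %.1f A, Rg %.2f A, I(0) %.4g (%s)",
              attr(x, "dmax"), attr(x, "rg"), attr(x, "i0"),
              attr(x, "method")))
  if (is.finite(attr(x, "chi2"))) cat(sprintf(", chi2 %.3g", attr(x, "chi2")))
  fl <- attr(x, "flags")
  if (length(fl)) cat(" [", paste(fl, collapse = ", "), "]", sep = "")
  cat("\n")
  NextMethod()
}

#' Pair-distance distribution directly from a bead model
#'
#' Brute-force weighted histogram of all pairwise bead distances (pair weight
#' w_i w_j from the contrast model), normalized so that
#' 4 pi * integral(P dr) equals the model's I(0). This is the real-space
#' reference against which the reciprocal-space route
#' (Debye profile + regularized inversion) is validated.
#'
#' The discrete bead positions would otherwise imprint the helical repeat on
#' the histogram as a comb of spikes; by default each pair distance is
#' therefore smeared by the Gaussian bead width (`smear_sigma`, matching the
#' smearing option of [debye_profile()]), which restores the smooth
#' distribution of the underlying continuous duplex. Smearing lets P extend
#' about one bead diameter beyond the point-bead Dmax; the recorded `dmax`
#' attribute remains the geometric maximum pairwise distance.
#'
#' @param conf A `conformer` with >= 2 beads of non-zero weight.
#' @param bin_width Histogram bin width, Angstrom (bins are centred on
#'   integer multiples of the width).
#' @param sucrose,nacl Solvent composition for the contrast weights.
#' @param model A [contrast_model()].
#' @param weights Optional explicit per-bead weights (overrides the model).
#' @param smear_sigma Gaussian bead width, Angstrom (0 = raw point-bead
#'   histogram); pair distances are smeared by sqrt(2) times this.
#' @return A `pddf`.
#' @examples
#' d <- pofr_from_model(build_duplex(149))
#' attr(d, "dmax")
#' @export
pofr_from_model <- function(conf, bin_width = 1, sucrose = 0, nacl = 0,
                            model = contrast_model(), weights = NULL,
                            smear_sigma = 3) {
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  w <- weights %||% bead_weights(conf, sucrose, nacl, model)
  keep <- abs(w) > 0
  xyz <- bead_matrix(conf)[keep, , drop = FALSE]
  w <- w[keep]
  if (nrow(xyz) < 2) stop("need at least 2 weighted beads", call. = FALSE)
  d <- as.vector(stats::dist(xyz))
  ww <- tcrossprod(w)
  ww <- 2 * ww[lower.tri(ww)]
  dmax <- max(d)
  sig_pair <- sqrt(2) * smear_sigma
  rmax <- dmax + bin_width + 4 * sig_pair
  edges <- seq(-bin_width / 2, rmax, by = bin_width)
  bin <- findInterval(d, edges, rightmost.closed = TRUE)
  ph <- vapply(seq_len(length(edges) - 1),
               function(k) sum(ww[bin == k]), 0) / bin_width
  r <- edges[-length(edges)] + bin_width / 2
  if (smear_sigma > 0) {
    # convolve with the pair-smearing kernel; columns renormalized so pair
    # weight clipped at r = 0 is not lost
    K <- outer(r, r, function(a, b) stats::dnorm(a - b, 0, sig_pair))
    K <- sweep(K, 2, colSums(K), "/")
    ph <- as.vector(K %*% ph)
  }
  r <- c(0, r[-1], edges[length(edges)])
  p <- c(0, ph[-1], 0)
  i0 <- sum(w)^2
  p <- p * i0 / (4 * pi * trapz_int(r, p))
  # recorded moments are the exact bead-model values (the curve's own second
  # moment omits the infinitesimal self-correlation mass at r = 0, which
  # matters only for models of very few beads)
  rg_exact <- sqrt(sum(tcrossprod(w) * as.matrix(stats::dist(xyz))^2) /
                     (2 * sum(w)^2))
  new_pddf(r, p, dmax = dmax, method = "histogram", rg = rg_exact, i0 = i0)
}

# second-difference regularization matrix for m interior points with
# zero boundary conditions
second_diff_matrix <- function(m) {
  L <- diag(-2, m)
  if (m > 1) {
    idx <- seq_len(m - 1)
    L[cbind(idx, idx + 1)] <- 1
    L[cbind(idx + 1, idx)] <- 1
  }
  L
}

#' Regularized indirect Fourier transform
#'
#' Inverts a measured profile I(q) to P(r) on [0, dmax] by minimizing the
#' weighted residual plus a second-difference smoothness penalty,
#' subject to P >= 0 and P(0) = P(dmax) = 0:
#' sum_k ((I(q_k) - 4 pi integral P(r) sinc(q_k r) dr) / sigma_k)^2
#'   + alpha * || second difference of P ||^2.
#' When `alpha` is NULL it is chosen by a discrepancy-principle rule: the
#' largest alpha on a log-spaced grid whose (unconstrained) solution keeps
#' the reduced chi-squared within 10% of its minimum over the grid, and at
#' least at 1 (the statistically expected misfit). This keeps the smoothest
#' P(r) compatible with the data.
#'
#' @param profile A [saxs_profile()] with positive uncertainties.
#' @param dmax Assumed maximum dimension, Angstrom.
#' @param alpha Regularization strength, or NULL for L-curve selection.
#' @param n_r Number of r-grid points on [0, dmax].
#' @param alphas Candidate grid for L-curve selection.
#' @return A `pddf` with reduced chi-squared, alpha and flags recorded.
#' @export
ift_regularized <- function(profile, dmax, alpha = NULL, n_r = 201,
                            alphas = 10^seq(-7, 3, length.out = 21)) {
  q <- profile$q
  I <- profile$I
  sg <- profile$sigma
  if (all(sg <= 0)) {
    stop("invalid uncertainties: all sigma are zero; attach a noise model",
         call. = FALSE)
  }
  sg[sg <= 0] <- min(sg[sg > 0])
  flags <- character()
  if (dmax > pi / min(q)) flags <- c(flags, "dmax_beyond_resolution")

  r <- seq(0, dmax, length.out = n_r)
  dr <- r[2] - r[1]
  ri <- r[-c(1, n_r)]
  m <- length(ri)
  A <- 4 * pi * dr * outer(q, ri, function(qk, rj) sinc(qk * rj))
  Aw <- A / sg
  bw <- I / sg
  L <- second_diff_matrix(m) / dr^1.5 # keep penalty roughly grid-invariant

  AtA <- crossprod(Aw)
  Atb <- crossprod(Aw, bw)
  LtL <- crossprod(L)
  if (is.null(alpha)) {
    rchi2 <- vapply(alphas, function(a) {
      u <- tryCatch(solve(AtA + a * LtL, Atb), error = function(e) NULL)
      if (is.null(u)) return(NA_real_)
      sum((Aw %*% u - bw)^2) / (length(q) - 1)
    }, 0)
    if (all(!is.finite(rchi2))) {
      alpha <- stats::median(alphas)
    } else {
      thr <- max(1, 1.1 * min(rchi2, na.rm = TRUE))
      ok <- which(is.finite(rchi2) & rchi2 <= thr)
      alpha <- if (length(ok)) alphas[max(ok)] else
        alphas[which.min(rchi2)]
    }
  }

  fit <- tryCatch(
    pracma::lsqnonneg(rbind(Aw, sqrt(alpha) * L), c(bw, rep(0, m))),
    error = function(e) {
      stop("solver failure in regularized IFT: ", conditionMessage(e),
           call. = FALSE)
    })
  p <- c(0, fit$x, 0)
  chi2 <- sum(((A %*% fit$x - I) / sg)^2) / (length(q) - 1)
  new_pddf(r, p, dmax = dmax, chi2 = chi2, alpha = alpha,
           qmax_used = max(q), method = "ift", flags = flags)
}

# index of maximum discrete curvature on the L-curve (log rho vs log eta)
lcurve_corner <- function(lrho, leta) {
  ok <- is.finite(lrho) & is.finite(leta)
  n <- length(lrho)
  curv <- rep(NA_real_, n)
  for (i in 2:(n - 1)) {
    if (!all(ok[(i - 1):(i + 1)])) next
    x <- lrho[(i - 1):(i + 1)]
    y <- leta[(i - 1):(i + 1)]
    a <- sqrt((x[2] - x[1])^2 + (y[2] - y[1])^2)
    b <- sqrt((x[3] - x[2])^2 + (y[3] - y[2])^2)
    cc <- sqrt((x[3] - x[1])^2 + (y[3] - y[1])^2)
    area2 <- abs((x[2] - x[1]) * (y[3] - y[1]) - (x[3] - x[1]) * (y[2] - y[1]))
    curv[i] <- if (a * b * cc > 0) 2 * area2 / (a * b * cc) else 0
  }
  if (all(is.na(curv))) return(which(ok)[1] %||% 1)
  which.max(curv)
}

#' Select Dmax by a three-criterion scan
#'
#' Runs the regularized inversion over candidate Dmax values and selects the
#' smallest candidate that simultaneously (i) fits well (reduced chi-squared
#' within `chi2_factor` of the best over the scan), (ii) gives a stabilized
#' P(r) shape (relative L2 change versus the adjacent candidate below
#' `stab_tol`) and (iii) has a smoothly decaying tail (non-increasing, within
#' `tail_tol` of the peak, over the last `tail_frac` of [0, Dmax]). If no
#' candidate passes, the best-chi2 result is returned flagged `"unstable"`.
#'
#' @inheritParams ift_regularized
#' @param candidates Candidate Dmax values (>= 3), Angstrom.
#' @param chi2_factor,stab_tol,tail_frac,tail_tol Criterion thresholds.
#' @param ... Passed to [ift_regularized()].
#' @return The winning `pddf`; the full scan record is in `attr(, "scan")`.
#' @export
scan_dmax <- function(profile, candidates, chi2_factor = 1.2,
                      stab_tol = 0.05, tail_frac = 0.10, tail_tol = 0.02,
                      ...) {
  if (length(candidates) < 3) stop("need >= 3 Dmax candidates", call. = FALSE)
  candidates <- sort(candidates)
  fits <- purrr::map(candidates, function(dm) {
    ift_regularized(profile, dmax = dm, ...)
  })
  chi2 <- purrr::map_dbl(fits, ~ attr(.x, "chi2"))

  l2_change <- function(f1, f2) {
    # compare on the support of the smaller candidate
    g <- f1$r
    p2 <- stats::approx(f2$r, f2$p, xout = g, rule = 2)$y
    sqrt(sum((f1$p - p2)^2)) / sqrt(sum(f1$p^2))
  }
  stab <- rep(NA_real_, length(fits))
  for (k in seq_along(fits)) {
    other <- if (k < length(fits)) k + 1 else k - 1
    stab[k] <- l2_change(fits[[k]], fits[[other]])
  }
  tail_ok <- purrr::map_lgl(fits, function(f) {
    i0 <- which(f$r >= (1 - tail_frac) * attr(f, "dmax"))
    pt <- f$p[i0]
    all(diff(pt) <= tail_tol * max(f$p))
  })
  pass <- chi2 <= chi2_factor * min(chi2) & stab < stab_tol & tail_ok
  scan <- tibble::tibble(dmax = candidates, chi2 = chi2, stability = stab,
                         tail_ok = tail_ok, pass = pass)
  if (any(pass)) {
    win <- which(pass)[1]
    out <- fits[[win]]
  } else {
    win <- which.min(chi2)
    out <- fits[[win]]
    attr(out, "flags") <- c(attr(out, "flags"), "unstable")
  }
  attr(out, "scan") <- scan
  out
}

#' Radius of gyration and forward intensity from a PDDF
#'
#' Moments of P(r): I(0) = 4 pi * integral(P dr) and
#' rg^2 = integral(r^2 P dr) / (2 integral(P dr)).
#'
#' @param pddf A `pddf`.
#' @return A one-row tibble with columns `rg` and `i0`.
#' @export
rg_i0_from_pofr <- function(pddf) {
  ip <- trapz_int(pddf$r, pddf$p)
  if (ip <= 0) stop("degenerate PDDF: zero integral", call. = FALSE)
  tibble::tibble(rg = sqrt(trapz_int(pddf$r, pddf$r^2 * pddf$p) / (2 * ip)),
                 i0 = 4 * pi * ip)
}
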