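#' Reduced chi-squared between a model and a measured profile
#'
#' chi2 = (1/(N-1)) sum(((s * I_model - I_data) / sigma)^2), with the model
#' interpolated onto the data grid and, when `fit_scale` is TRUE, the
#' optimal least-squares scalar s applied.
#'
#' @param model,data [saxs_profile()] objects on overlapping q ranges.
#' @param fit_scale Fit an overall intensity scale?
#' @return Reduced chi-squared (attribute `"scale"` carries the fitted s).
#' @export
chi2_profiles <- function(model, data, fit_scale = TRUE) {
  Im <- interp_profile(model, data$q)
  ok <- is.finite(Im)
  if (sum(ok) < 3) stop("model and data q-grids do not overlap", call. = FALSE)
  Id <- data$I[ok]
  sg <- data$sigma[ok]
  sg[sg <= 0] <- if (any(sg > 0)) min(sg[sg > 0]) else 1
  Im <- Im[ok]
  s <- if (fit_scale) sum(Im * Id / sg^2) / sum(Im^2 / sg^2) else 1
  out <- sum(((s * Im - Id) / sg)^2) / (sum(ok) - 1)
  attr(out, "scale") <- s
  out
}

#' Fit a profile with a non-negative ensemble of pool conformers
#'
#' EOM-style analysis: finds non-negative weights over the pool-member
#' theoretical profiles minimizing the reduced chi-squared against the data.
#' The pool is small (32 members by default) so the fit is solved exactly by
#' non-negative least squares; the result is then truncated to the
#' `max_members` largest weights (dropping members below `weight_floor`) and
#' refit. Reported weights sum to one; the overall intensity scale is
#' returned separately.
#'
#' Pool members whose profiles differ by less than the data noise are not
#' distinguishable (in particular, mirror-symmetric left/right release pairs
#' have identical P(r)); such degeneracies among the selected members are
#' reported via a `degenerate` attribute rather than suppressed.
#'
#' @param pool A pool tibble from [generate_pool()] with a `profile`
#'   list-column (see [pool_profiles()]), or a named list of
#'   [saxs_profile()] objects.
#' @param data A [saxs_profile()] with uncertainties.
#' @param max_members Maximum ensemble size reported (>= 1).
#' @param weight_floor Discard members below this weight fraction.
#' @return An `ensemble_fit`: tibble of selected members (`member`,
#'   `weight`, `symmetry` when known) with attributes `chi2`, `scale`,
#'   `asym_fraction` (when symmetry is known) and `degenerate`.
#' @export
select_ensemble <- function(pool, data, max_members = 4,
                            weight_floor = 0.01) {
  if (max_members < 1) stop("max_members must be >= 1", call. = FALSE)
  if (tibble::is_tibble(pool)) {
    if (!"profile" %in% names(pool)) {
      stop("pool tibble needs a 'profile' list-column; see pool_profiles()",
           call. = FALSE)
    }
    profiles <- stats::setNames(pool$profile, pool$name)
    symmetry <- stats::setNames(pool$symmetry, pool$name)
  } else {
    profiles <- pool
    symmetry <- NULL
  }
  if (!length(profiles)) stop("empty pool", call. = FALSE)
  sg <- data$sigma
  sg[sg <= 0] <- if (any(sg > 0)) min(sg[sg > 0]) else 1
  M <- vapply(profiles, function(p) interp_profile(p, data$q) / sg,
              numeric(length(data$q)))
  if (anyNA(M)) stop("pool profiles do not cover the data q-range",
                     call. = FALSE)
  b <- data$I / sg

  nn <- pracma::lsqnonneg(M, b)
  coef <- nn$x
  keep <- which(coef > 0)
  keep <- keep[order(coef[keep], decreasing = TRUE)]
  keep <- utils::head(keep, max_members)
  if (!length(keep)) keep <- which.max(coef)
  # refit on the truncated support
  coef2 <- rep(0, length(coef))
  coef2[keep] <- pracma::lsqnonneg(M[, keep, drop = FALSE], b)$x
  if (sum(coef2) <= 0) coef2[which.max(coef)] <- 1
  w <- coef2 / sum(coef2)
  sel <- which(w >= weight_floor)
  if (!length(sel)) sel <- which.max(w)
  w <- w[sel] / sum(w[sel])

  fitI <- as.vector(M[, sel, drop = FALSE] %*% coef2[sel])
  chi2 <- sum((fitI - b)^2) / (length(b) - 1)

  nm <- names(profiles)[sel]
  out <- tibble::tibble(member = nm, weight = w)
  if (!is.null(symmetry)) out$symmetry <- unname(symmetry[nm])
  out <- dplyr::arrange(out, dplyr::desc(.data$weight))
  attr(out, "chi2") <- chi2
  attr(out, "scale") <- sum(coef2)
  attr(out, "degenerate") <- ensemble_degeneracy(M[, sel, drop = FALSE], nm)
  if (!is.null(symmetry)) {
    attr(out, "asym_fraction") <- sum(out$weight[out$symmetry == "asymmetric"])
  }
  class(out) <- c("ensemble_fit", class(out))
  out
}

# pairs of selected members whose (sigma-weighted) profiles differ by less
# than ~1 sigma per point are reported as degenerate
ensemble_degeneracy <- function(Msel, names) {
  k <- ncol(Msel)
  if (k < 2) return(character())
  out <- character()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      # columns are already in units of sigma
      s_i <- sum(Msel[, i] * Msel[, j]) / sum(Msel[, j]^2)
      rms <- sqrt(mean((Msel[, i] - s_i * Msel[, j])^2))
      if (rms < 1) out <- c(out, paste(names[i], names[j], sep = " ~ "))
    }
  }
  out
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat(sprintf("<ensemble_fit> %d members, chi2 %.3g", nrow(x),
              attr(x, "chi2")))
  af <- attr(x, "asym_fraction")
  if (!is.null(af)) cat(sprintf(", asymmetric fraction %.2f", af))
  dg <- attr(x, "degenerate")
  if (length(dg)) cat("\n  degenerate pairs:", paste(dg, collapse = "; "))
  cat("\n")
  NextMethod()
}

#' Compute theoretical profiles for every pool member
#'
#' Adds a `profile` list-column of [debye_profile()] results to a pool
#' tibble.
#'
#' @param pool A tibble from [generate_pool()].
#' @param qgrid,sucrose,nacl,model,smear_sigma Passed to [debye_profile()].
#' @return The pool tibble with a `profile` list-column.
#' @export
pool_profiles <- function(pool, qgrid = qgrid_default(), sucrose = 0.5,
                          nacl = 0, model = contrast_model(),
                          smear_sigma = 3) {
  pool$profile <- purrr::map(pool$conformer, debye_profile, qgrid = qgrid,
                             sucrose = sucrose, nacl = nacl, model = model,
                             smear_sigma = smear_sigma)
  pool
}

#' Weight fraction on asymmetric pool members
#'
#' @param fit An `ensemble_fit` from [select_ensemble()].
#' @param pool The pool tibble the fit was made against (used to resolve
#'   member symmetry when the fit does not carry it).
#' @return Fraction of ensemble weight on members classified asymmetric.
#' @export
asymmetric_fraction <- function(fit, pool = NULL) {
  if (sum(fit$weight) <= 0) stop("degenerate fit: zero weights", call. = FALSE)
  if (!"symmetry" %in% names(fit)) {
    if (is.null(pool)) stop("pool needed to resolve member symmetry",
                            call. = FALSE)
    idx <- match(fit$member, pool$name)
    if (anyNA(idx)) {
      stop("unknown member id: ",
           paste(fit$member[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    sym <- pool$symmetry[idx]
  } else {
    sym <- fit$symmetry
  }
  sum(fit$weight[sym == "asymmetric"]) / sum(fit$weight)
}
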