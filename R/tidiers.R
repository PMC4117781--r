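#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a pair-distance distribution
#'
#' @param x A `pddf`.
#' @param ... Unused.
#' @return `tidy`: the (r, p) tibble; `glance`: a one-row tibble with
#'   `dmax`, `rg`, `i0`, `chi2`, `alpha`, `method`, `n_flags`.
#' @export
tidy.pddf <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname tidy.pddf
#' @export
glance.pddf <- function(x, ...) {
  tibble::tibble(dmax = attr(x, "dmax"), rg = attr(x, "rg"),
                 i0 = attr(x, "i0"), chi2 = attr(x, "chi2"),
                 alpha = attr(x, "alpha"), method = attr(x, "method"),
                 n_flags = length(attr(x, "flags")))
}

#' Tidy an ensemble fit
#'
#' @param x An `ensemble_fit`.
#' @param ... Unused.
#' @return `tidy`: one row per selected member; `glance`: a one-row tibble
#'   with `chi2`, `scale`, `n_members`, `asym_fraction`, `n_degenerate`.
#' @export
tidy.ensemble_fit <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname tidy.ensemble_fit
#' @export
glance.ensemble_fit <- function(x, ...) {
  tibble::tibble(chi2 = attr(x, "chi2"), scale = attr(x, "scale"),
                 n_members = nrow(x),
                 asym_fraction = attr(x, "asym_fraction") %||% NA_real_,
                 n_degenerate = length(attr(x, "degenerate")))
}

#' Tidy an exponential kinetic fit
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return `tidy`: one row per parameter (`term`, `estimate`, `std.error`);
#'   `glance`: one row with `n_exp`, `chi2`, `rms`, `n_warnings`.
#' @export
tidy.kinetic_fit <- function(x, ...) {
  k <- length(x$rates)
  tibble::tibble(
    term = c(paste0("k", seq_len(k)), paste0("A", seq_len(k)), "baseline"),
    estimate = c(x$rates, x$amplitudes, x$baseline),
    std.error = c(x$rate_se, x$amplitude_se, NA_real_)
  )
}

#' @rdname tidy.kinetic_fit
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(n_exp = x$n_exp, chi2 = x$chi2, rms = x$rms,
                 n_warnings = length(x$warnings))
}

#' Tidy a kinetic SVD result
#'
#' @param x An `svd_result`.
#' @param ... Unused.
#' @return `tidy`: the per-component diagnostics tibble; `glance`: one row
#'   with `n_significant` and the leading singular-value ratio.
#' @export
tidy.svd_result <- function(x, ...) x$components

#' @rdname tidy.svd_result
#' @export
glance.svd_result <- function(x, ...) {
  tibble::tibble(n_significant = x$n_significant,
                 leading_ratio = x$components$sv_ratio[1])
}
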