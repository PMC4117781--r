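#' Plot a scattering profile
#'
#' Log-intensity versus q with uncertainty ribbon.
#'
#' @param object A [saxs_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.saxs_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q, y = .data$I)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$I - .data$sigma,
                                      ymax = .data$I + .data$sigma),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)), y = "I(q)",
                  title = attr(object, "label"))
}

#' Kratky plot of a scattering profile
#'
#' @param profile A [saxs_profile()].
#' @return A ggplot of I q^2 versus q.
#' @export
plot_kratky <- function(profile) {
  df <- kratky(profile)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q, y = .data$iq2)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)),
                  y = expression(I(q) %.% q^2))
}

#' Plot a pair-distance distribution
#'
#' @param object A `pddf`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pddf <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "dmax"),
                        linetype = "dashed", alpha = 0.5) +
    ggplot2::labs(x = expression(r ~ (ring(A))), y = "P(r)",
                  subtitle = sprintf("Dmax %.0f A, Rg %.1f A",
                                     attr(object, "dmax"),
                                     attr(object, "rg")))
}

#' Plot ensemble weights
#'
#' @param object An `ensemble_fit`.
#' @param ... Unused.
#' @return A ggplot bar chart of member weights.
#' @export
autoplot.ensemble_fit <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$member,
                                                           -.data$weight),
                                        y = .data$weight))
  if ("symmetry" %in% names(df)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$symmetry))
  } else {
    p <- p + ggplot2::geom_col()
  }
  p + ggplot2::labs(x = NULL, y = "weight",
                    subtitle = sprintf("chi2 = %.3g", attr(object, "chi2"))) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a kinetic trace and its exponential fit
#'
#' @param object A `kinetic_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  ggplot2::ggplot(object$fitted, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value), alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time (s)", y = "value",
                  subtitle = paste0(
                    object$n_exp, "-exponential, k = ",
                    paste(signif(object$rates, 3), collapse = ", "), " 1/s"))
}

#' Scree plot of a kinetic SVD
#'
#' @param object An `svd_result`.
#' @param ... Unused.
#' @return A ggplot of singular values, significant components highlighted.
#' @export
autoplot.svd_result <- function(object, ...) {
  df <- object$components
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component,
                                   y = .data$singular_value,
                                   colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "component", y = "singular value")
}
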