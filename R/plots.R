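#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Dot plot of a base-pair probability matrix
#'
#' @param object A `bppm` from [rna_partition()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bppm <- function(object, ...) {
  n <- nrow(object)
  df <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n)) |>
    dplyr::filter(.data$j > .data$i) |>
    dplyr::mutate(p = object[cbind(.data$i, .data$j)]) |>
    dplyr::filter(.data$p > 1e-4)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "position j", y = "position i",
                  fill = "P(i, j)",
                  title = "Base-pair probabilities") +
    ggplot2::theme_minimal()
}

#' Plot a per-position ensemble profile
#'
#' @param profile Tibble from [ensemble_profile()].
#' @param site Optional positions to highlight.
#' @return A ggplot of the per-position measures, faceted by measure.
#' @export
plot_ensemble_profile <- function(profile, site = NULL) {
  long <- tidyr::pivot_longer(profile, -"position",
                              names_to = "measure", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$position,
                                          y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "position", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(site)) {
    p <- p + ggplot2::geom_vline(xintercept = site, alpha = 0.15)
  }
  p
}

#' Density-of-states histogram plot
#'
#' @param object A `dos_histogram`.
#' @param ... Unused.
#' @return A ggplot of `p(k)` against `k`.
#' @export
autoplot.dos_histogram <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$k, y = .data$p)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::labs(
      x = "base-pair distance k to reference",
      y = "p(k)",
      title = paste0("Density of states (", attr(object, "method"), ")")
    ) +
    ggplot2::theme_minimal()
}

#' Cleavage-kinetics fit plot
#'
#' Observed points, the fitted first-order curve and its delta-method 95%
#' confidence band.
#'
#' @param object A [fit_cleavage()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cleavage_fit <- function(object, ...) {
  tt <- seq(min(object$data$time_min), max(object$data$time_min),
            length.out = 200)
  curve <- tibble::tibble(
    time_min = tt,
    fit = object$f_max - (object$f_max - object$f0) *
      exp(-object$k_obs * tt)
  )
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$time_min,
                               y = .data$fraction_cleaved)) +
    ggplot2::geom_ribbon(data = object$band,
                         ggplot2::aes(x = .data$time_min, ymin = .data$lower,
                                      ymax = .data$upper),
                         inherit.aes = FALSE, alpha = 0.2) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$time_min, y = .data$fit),
                       inherit.aes = FALSE) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (min)", y = "fraction cleaved",
                  title = sprintf("K_obs = %.4g /min, F_max = %.3g",
                                  object$k_obs, object$f_max)) +
    ggplot2::theme_minimal()
}
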