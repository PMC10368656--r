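#' Plot helpers
#'
#' ggplot2 views of the main result types: contrast densities, marginal
#' power spectra, joint binned spectra (optionally with behavioral-limit
#' overlays), and nonlinearities. Each returns a ggplot object that can be
#' themed further.
#'
#' @name plots
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a contrast density table
#'
#' @param density A [contrast_density()] tibble (optionally row-bound
#'   across samples with an extra grouping column passed via `colour`).
#' @param colour Optional name of a grouping column.
#' @return A ggplot object.
#' @export
plot_contrast_density <- function(density, colour = NULL) {
  p <- ggplot2::ggplot(density,
                       ggplot2::aes(x = .data$bin_mid, y = .data$density))
  p <- if (is.null(colour)) {
    p + ggplot2::geom_line()
  } else {
    p + ggplot2::geom_line(ggplot2::aes(colour = .data[[colour]]))
  }
  p + ggplot2::labs(x = "Contrast", y = "Probability density")
}

#' Autoplot a binned spectrum
#'
#' Joint mean power on log-log axes, colour-coded as log10 power.
#'
#' @param object A `binned_spectrum`.
#' @param limits Optional [behavioral_limits()] tibble to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot binned_spectrum
#' @export
autoplot.binned_spectrum <- function(object, limits = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$temporal_freq,
                                        y = .data$spatial_freq,
                                        fill = log10(.data$power))) +
    ggplot2::geom_raster() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Temporal frequency (cps)",
                  y = "Spatial frequency (cpd)",
                  fill = "log10 power")
  if (!is.null(limits)) {
    ov <- limits_overlay(limits, object)
    sp <- ov[ov$axis == "spatial", ]
    tp <- ov[ov$axis == "temporal", ]
    p <- p +
      ggplot2::geom_hline(data = sp, ggplot2::aes(yintercept = .data$coordinate),
                          linetype = "dashed", colour = "white") +
      ggplot2::geom_vline(data = tp, ggplot2::aes(xintercept = .data$coordinate),
                          linetype = "dashed", colour = "white")
  }
  p
}

#' Autoplot marginal spectra with slope fits
#'
#' @param object A [marginal_spectra()] tibble.
#' @param ... Unused.
#' @return A ggplot object faceted by domain on log-log axes.
#' @export
plot_marginal_spectra <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$freq, y = .data$power)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~domain, scales = "free") +
    ggplot2::labs(x = "Frequency", y = "Mean power")
}

#' Autoplot a nonlinearity
#'
#' @param object A `nonlinearity`.
#' @param ... Further nonlinearities to overlay.
#' @return A ggplot object.
#' @method autoplot nonlinearity
#' @export
autoplot.nonlinearity <- function(object, ...) {
  extra <- Filter(function(o) inherits(o, "nonlinearity"), list(...))
  df <- dplyr::bind_rows(lapply(c(list(object), extra), tidy))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$contrast, y = .data$response,
                                   colour = .data$environment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Contrast", y = "Response (cumulative probability)")
}

#' Plot a median contrast map
#'
#' @param map A matrix from [median_contrast_map()].
#' @return A ggplot object with the top of the visual field at the top.
#' @export
plot_contrast_map <- function(map) {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(map)), times = ncol(map)),
    col = rep(seq_len(ncol(map)), each = nrow(map)),
    contrast = as.vector(map)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$contrast)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "Azimuth (px)", y = "Elevation (px)",
                  fill = "Median contrast")
}
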