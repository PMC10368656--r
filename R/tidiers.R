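#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a log-log slope fit
#'
#' @param x A `slope_fit` from [fit_loglog_slope()].
#' @param ... Unused.
#' @return A tibble with one row per model term (`term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`).
#' @method tidy slope_fit
#' @export
tidy.slope_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$model))$coefficients
  tibble::tibble(
    term = c("intercept", "log10(freq)"),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' Glance at a log-log slope fit
#'
#' @param x A `slope_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `slope`, `intercept`, `r.squared`,
#'   `sigma`, `nobs`, `domain`.
#' @method glance slope_fit
#' @export
glance.slope_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept,
    r.squared = x$r_squared, sigma = x$residual_sd,
    nobs = x$n_bins, domain = x$domain
  )
}

#' Tidy a 2x2 ANOVA
#'
#' @param x An `anova_2x2` from [anova_2x2()].
#' @param ... Unused.
#' @return The effects tibble (term, df, sums of squares, F, p, partial
#'   eta-squared).
#' @method tidy anova_2x2
#' @export
tidy.anova_2x2 <- function(x, ...) x$effects

#' Glance at a 2x2 ANOVA
#'
#' @param x An `anova_2x2`.
#' @param ... Unused.
#' @return A one-row tibble with the model R-squared, residual df, and SS
#'   type.
#' @method glance anova_2x2
#' @export
glance.anova_2x2 <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(
    r.squared = s$r.squared,
    df.residual = x$model$df.residual,
    ss_type = x$ss_type
  )
}

#' Tidy a nonlinearity
#'
#' @param x A `nonlinearity` from [build_nonlinearity()].
#' @param ... Unused.
#' @return A tibble with `contrast` and `response` columns.
#' @method tidy nonlinearity
#' @export
tidy.nonlinearity <- function(x, ...) {
  tibble::tibble(contrast = x$contrast, response = x$response,
                 environment = x$environment)
}

#' Tidy a binned spectrum into long format
#'
#' @param x A `binned_spectrum` from [bin_spectrum()].
#' @param ... Unused.
#' @return A tibble with `spatial_freq`, `temporal_freq`, `power`.
#' @method tidy binned_spectrum
#' @export
tidy.binned_spectrum <- function(x, ...) {
  n_s <- length(x$spatial_centers)
  n_t <- length(x$temporal_centers)
  tibble::tibble(
    spatial_freq = rep(x$spatial_centers, times = n_t),
    temporal_freq = rep(x$temporal_centers, each = n_s),
    power = as.vector(x$joint)
  )
}
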