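#' Through-water stimulus geometry
#'
#' Visual stimuli shown on a screen below a water-filled dish reach the
#' fish through an air gap, the container material, and the water column.
#' Refraction at the air-water boundary (Snell's law) compresses the
#' angles at which on-screen patterns appear, so a grating designed to
#' subtend a given spatial period subtends a smaller one at the fish. The
#' functions here solve that planar single-interface geometry and convert
#' periods to acuities for comparison against behavioral limits.
#'
#' @name stimulus-geometry
NULL

#' Refraction geometry of a stimulus rig
#'
#' @param d_water_cm Fish height above the container bottom. Default 0.25.
#' @param d_interface_cm Container plus transparent-stage thickness.
#'   Default 0.5.
#' @param d_air_cm Container-to-screen air gap. Default 5.65.
#' @param n_water,n_air Refractive indices. Defaults 1.33 and 1.
#' @param interface_medium `"water-equivalent"` (container and stage
#'   counted in the refracting path at `n_water`; the default) or
#'   `"air-equivalent"` (counted in the air path).
#' @return An object of class `refraction_setup`.
#' @export
refraction_setup <- function(d_water_cm = 0.25, d_interface_cm = 0.5,
                             d_air_cm = 5.65, n_water = 1.33, n_air = 1,
                             interface_medium = c("water-equivalent",
                                                  "air-equivalent")) {
  interface_medium <- match.arg(interface_medium)
  if (any(c(d_water_cm, d_interface_cm, d_air_cm) < 0)) {
    stop("distances must be >= 0", call. = FALSE)
  }
  if (n_water < 1 || n_air < 1) stop("indices must be >= 1", call. = FALSE)
  structure(
    list(d_water_cm = d_water_cm, d_interface_cm = d_interface_cm,
         d_air_cm = d_air_cm, n_water = n_water, n_air = n_air,
         interface_medium = interface_medium),
    class = "refraction_setup"
  )
}

#' Apparent spatial period at the fish
#'
#' A pattern extending `nominal_period_deg` from the nadir is drawn on the
#' screen at the extent `x` that would subtend that angle at the fish over
#' the straight-line path (no refraction). The in-water ray angle
#' `theta_w` that actually reaches that screen extent satisfies
#' `x = d_air * tan(theta_a) + d_refr * tan(theta_w)` with
#' `n_air * sin(theta_a) = n_water * sin(theta_w)`, where `d_refr` is the
#' water column plus (by default) the container/stage thickness. The
#' returned `theta_w` is the period the fish actually sees; it is always
#' at most the nominal period when `n_water > n_air`. The root is found by
#' bisection to a screen-extent residual below 1e-9 cm.
#'
#' @param setup A [refraction_setup()].
#' @param nominal_period_deg Designed spatial period, degrees in (0, 90).
#' @return Apparent period at the fish, degrees.
#' @export
apparent_period <- function(setup = refraction_setup(),
                            nominal_period_deg) {
  stopifnot(inherits(setup, "refraction_setup"))
  if (any(nominal_period_deg <= 0 | nominal_period_deg >= 90)) {
    stop("nominal_period_deg must lie in (0, 90)", call. = FALSE)
  }
  if (length(nominal_period_deg) > 1) {
    return(vapply(nominal_period_deg, function(p) apparent_period(setup, p),
                  numeric(1)))
  }
  if (setup$interface_medium == "water-equivalent") {
    d_refr <- setup$d_water_cm + setup$d_interface_cm
    d_air <- setup$d_air_cm
  } else {
    d_refr <- setup$d_water_cm
    d_air <- setup$d_air_cm + setup$d_interface_cm
  }
  total <- d_refr + d_air
  x <- total * tan(deg2rad(nominal_period_deg))
  if (setup$n_water == setup$n_air || d_air == 0) {
    return(nominal_period_deg)
  }
  ratio <- setup$n_water / setup$n_air
  # screen extent reached by an in-water ray at angle tw (radians)
  extent <- function(tw) {
    s <- ratio * sin(tw)
    if (s >= 1) return(Inf)    # beyond total internal reflection
    d_air * tan(asin(s)) + d_refr * tan(tw)
  }
  lo <- 1e-12
  hi <- min(asin(1 / ratio) - 1e-12, deg2rad(89))
  if (extent(hi) < x) stop("no in-water ray reaches the screen extent",
                           call. = FALSE)
  while (hi - lo > 1e-15) {
    mid <- (lo + hi) / 2
    if (abs(extent(mid) - x) < 1e-9) { lo <- mid; hi <- mid; break }
    if (extent(mid) < x) lo <- mid else hi <- mid
  }
  (lo + hi) / 2 / deg2rad(1)
}

#' Spatial acuity from period
#'
#' @param period_deg Spatial period in degrees (> 0).
#' @return Acuity in cycles/degree, `1 / period_deg`.
#' @export
acuity_cpd <- function(period_deg) {
  if (any(period_deg <= 0)) stop("period must be positive", call. = FALSE)
  1 / period_deg
}

#' Behavioral and physiological limits of larval zebrafish vision
#'
#' The published limits overlaid on the aquatic joint spectrum: optokinetic
#' response (OKR) acuity 0.16 cpd and temporal limit ~2 cps; optomotor
#' response (OMR) temporal limit ~14 cps and acuity derived from the
#' refraction-corrected 12-degree grating (about 0.11 cpd with the default
#' rig geometry); prey-capture bounds 0.09-0.33 cpd and 2-60 cps; flicker
#' fusion rate 20 Hz; theoretical cone-spacing limit 0.24 cpd.
#'
#' @param setup A [refraction_setup()] used to derive the OMR acuity from
#'   the 12-degree nominal grating period.
#' @return A tibble with columns `limit`, `axis` (`"spatial"` or
#'   `"temporal"`), `value`, `units`.
#' @export
behavioral_limits <- function(setup = refraction_setup()) {
  omr_acuity <- acuity_cpd(apparent_period(setup, 12))
  tibble::tibble(
    limit = c("OKR acuity", "OMR acuity", "cone spacing",
              "prey capture lower", "prey capture upper",
              "OKR temporal", "OMR temporal", "flicker fusion",
              "prey capture temporal lower", "prey capture temporal upper"),
    axis = c(rep("spatial", 5), rep("temporal", 5)),
    value = c(0.16, omr_acuity, 0.24, 0.09, 0.33, 2, 14, 20, 2, 60),
    units = c(rep("cpd", 5), rep("cps", 5))
  )
}

#' Map behavioral limits onto a binned-spectrum axis
#'
#' Converts each limit to the coordinate system of a [bin_spectrum()]
#' grid for overlay plotting; limits outside the axis range are clipped to
#' the range and flagged.
#'
#' @param limits A [behavioral_limits()] tibble.
#' @param spectrum A `binned_spectrum`.
#' @return The limits tibble with `coordinate` (clipped value on the bin
#'   axis) and `in_range` columns added.
#' @export
limits_overlay <- function(limits, spectrum) {
  stopifnot(inherits(spectrum, "binned_spectrum"))
  s_rng <- range(spectrum$spatial_edges)
  t_rng <- range(spectrum$temporal_edges)
  lo <- ifelse(limits$axis == "spatial", s_rng[1], t_rng[1])
  hi <- ifelse(limits$axis == "spatial", s_rng[2], t_rng[2])
  dplyr::mutate(
    limits,
    in_range = .data$value >= lo & .data$value <= hi,
    coordinate = pmin(pmax(.data$value, lo), hi)
  )
}
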