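#' End-to-end analysis pipeline
#'
#' [run_pipeline()] orchestrates ingest/generation, clipping exclusion,
#' contrast statistics, hemifield summaries, spectral slopes, and the
#' Laughlin nonlinearity analysis over a manifest of samples;
#' [make_report()] reduces the per-sample tables to environment-level
#' comparisons (t/d-prime, 2x2 ANOVA, response entropy).
#'
#' @name pipeline
NULL

#' Run configuration
#'
#' @param manifest A tibble describing the samples: columns `sample_id`,
#'   `environment` (`"aquatic"`/`"terrestrial"`), and exactly one of
#'   `spec` (list-column of [scene_spec()]s; the pipeline calls
#'   [generate_skewed_field()] unless the spec's `gradient_amplitude` is
#'   positive, in which case [generate_gradient_scene()]) or `path`
#'   (frame directories readable by [read_sample_frames()]).
#' @param out_dir Optional directory; when given, all result tables are
#'   written there as CSV and the configuration as JSON.
#' @param density_bins Bins for the contrast density table. Default 100.
#' @param f_s_range,f_t_range,n_bins Spectral binning parameters passed to
#'   [bin_spectrum()]. Defaults are chosen at run time from the manifest's
#'   sample geometry when `NULL`.
#' @param local_contrast_stats Also compute DoG local-contrast summaries
#'   (slower). Default `TRUE`.
#' @param seed Seed for any stochastic stage. Generators carry their own
#'   seeds in their specs; this seed only feeds stages without one.
#' @return An object of class `run_config`.
#' @export
run_config <- function(manifest, out_dir = NULL, density_bins = 100,
                       f_s_range = NULL, f_t_range = NULL, n_bins = 19,
                       local_contrast_stats = TRUE, seed = 1L) {
  stopifnot(is.data.frame(manifest), nrow(manifest) >= 1)
  if (!all(c("sample_id", "environment") %in% names(manifest))) {
    stop("manifest needs sample_id and environment columns", call. = FALSE)
  }
  if (!("spec" %in% names(manifest) || "path" %in% names(manifest))) {
    stop("manifest needs a spec or path column", call. = FALSE)
  }
  structure(
    list(manifest = manifest, out_dir = out_dir,
         density_bins = density_bins,
         f_s_range = f_s_range, f_t_range = f_t_range, n_bins = n_bins,
         local_contrast_stats = local_contrast_stats,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

# spectral bin ranges resolvable by a sample's geometry: frequency
# resolution at the low end, Nyquist at the high end, padded inward
default_bin_ranges <- function(sample) {
  d <- dim(sample$intensities)
  f_s_lo <- max(0.05, 1.5 / (min(d[1], d[2]) * sample$deg_per_px))
  f_s_hi <- min(0.75, 0.5 / sample$deg_per_px * 0.9)
  f_t_lo <- max(0.5, 1.5 * sample$frame_rate / d[3])
  f_t_hi <- min(50, sample$frame_rate / 2 * 0.9)
  list(f_s = c(f_s_lo, f_s_hi), f_t = c(f_t_lo, f_t_hi))
}

acquire_sample <- function(row) {
  if (!is.null(row$spec)) {
    spec <- row$spec
    s <- if (spec$gradient_amplitude > 0) {
      generate_gradient_scene(spec)
    } else {
      generate_skewed_field(spec)
    }
    s <- digitize_sample(s)
    s$environment <- row$environment
    s
  } else {
    s <- read_sample_frames(row$path)
    s$environment <- row$environment
    s
  }
}

#' Simulate camera digitization of a continuous-intensity sample
#'
#' Quantizes linear intensities to stored camera codes (`0 .. max_code`)
#' with the saturation level set to `exposure_headroom` times the mean
#' intensity, emulating a camera exposed for the scene's mean light
#' level. This gives synthetic samples the stored-code layer that real
#' footage carries, so the clipping-exclusion rules and the 256-level
#' entropy measure apply with identical semantics: a low-contrast scene
#' occupies few code levels (low entropy) while bright tails clip at the
#' top of the code range instead of stretching it.
#'
#' @param sample A [video_sample()].
#' @param max_code Maximum stored code. Default 255 (8-bit).
#' @param exposure_headroom Saturation intensity as a multiple of the
#'   mean. Default 4.
#' @return The sample with a `codes` array attached.
#' @export
digitize_sample <- function(sample, max_code = 255, exposure_headroom = 4) {
  stopifnot(inherits(sample, "video_sample"))
  i_sat <- exposure_headroom * mean(sample$intensities)
  if (i_sat <= 0) stop("saturation level must be positive", call. = FALSE)
  sample$codes <- array(
    pmin(round(sample$intensities / i_sat * max_code), max_code),
    dim = dim(sample$intensities)
  )
  sample
}

#' Run the full pipeline over a manifest
#'
#' For every manifest row: acquire the sample, assess clipping (excluded
#' samples are reported but not analyzed; surviving clipped pixels are
#' masked out of contrast analyses), compute global (and optionally local)
#' contrast summaries, entropy, hemifield summaries, the contrast density,
#' the binned spectrum with marginal slope fits, and collect per-sample
#' results. Per-environment Laughlin nonlinearities are then built from
#' the global-contrast fields, each applied to every sample of every
#' environment, and the response entropies recorded. A failing sample is
#' flagged in the manifest report and the pipeline continues.
#'
#' @param config A [run_config()].
#' @return A `pipeline_result`: list of tibbles `samples` (per-sample
#'   status and clipping), `contrast` (per sample x field kind),
#'   `hemifields`, `densities`, `slopes`, `nonlinearities` (grid
#'   long-format), `response_entropy`, plus `spectra` (list of
#'   `binned_spectrum` keyed by sample_id).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  mf <- config$manifest
  rows <- seq_len(nrow(mf))

  samples <- list(); contrast_tbl <- list(); hemi_tbl <- list()
  dens_tbl <- list(); slope_tbl <- list(); spectra <- list()
  fields <- list(); status <- character(nrow(mf)); note <- character(nrow(mf))

  for (i in rows) {
    row <- lapply(mf, function(col) if (is.list(col)) col[[i]] else col[i])
    res <- tryCatch({
      s <- acquire_sample(row)
      rep <- clipping_check(s)
      if (rep$excluded_sample) {
        status[i] <- "excluded"
        note[i] <- sprintf("clipping fraction %.3f >= 0.10",
                           rep$low_fraction + rep$high_fraction)
        samples[[i]] <- tibble::tibble(
          sample_id = row$sample_id, environment = row$environment,
          status = "excluded",
          low_fraction = rep$low_fraction, high_fraction = rep$high_fraction)
        NULL
      } else {
        s <- mask_clipped(s, rep)
        gc_field <- global_contrast(s)
        fields[[row$sample_id]] <- gc_field
        mom <- contrast_moments(gc_field)
        mom$entropy_bits <- contrast_entropy(gc_field)
        mom$kind <- "global"
        ctr <- mom
        if (config$local_contrast_stats) {
          lc <- local_contrast(s)
          lmom <- contrast_moments(lc)
          lmom$entropy_bits <- NA_real_
          lmom$kind <- "local"
          ctr <- dplyr::bind_rows(ctr, lmom)
        }
        ctr$sample_id <- row$sample_id
        ctr$environment <- row$environment
        contrast_tbl[[i]] <- ctr

        hs <- hemifield_summaries(gc_field)
        hs$sample_id <- row$sample_id
        hs$environment <- row$environment
        hemi_tbl[[i]] <- hs

        dn <- contrast_density(gc_field, n_bins = config$density_bins)
        dn$sample_id <- row$sample_id
        dn$environment <- row$environment
        dens_tbl[[i]] <- dn

        rng <- default_bin_ranges(s)
        f_s <- config$f_s_range %||% rng$f_s
        f_t <- config$f_t_range %||% rng$f_t
        grid <- power_spectrum_3d(s)
        bs <- suppressWarnings(
          bin_spectrum(grid, f_s_range = f_s, f_t_range = f_t,
                       n_bins = config$n_bins))
        spectra[[row$sample_id]] <- bs
        sl <- dplyr::bind_rows(
          glance(suppressWarnings(
            fit_loglog_slope(bs$marginals, domain = "spatial"))),
          glance(suppressWarnings(
            fit_loglog_slope(bs$marginals, domain = "temporal")))
        )
        sl$sample_id <- row$sample_id
        sl$environment <- row$environment
        slope_tbl[[i]] <- sl

        status[i] <- "analyzed"
        samples[[i]] <- tibble::tibble(
          sample_id = row$sample_id, environment = row$environment,
          status = "analyzed",
          low_fraction = rep$low_fraction, high_fraction = rep$high_fraction)
        TRUE
      }
    }, error = function(e) {
      status[i] <<- "error"
      note[i] <<- conditionMessage(e)
      samples[[i]] <<- tibble::tibble(
        sample_id = row$sample_id, environment = row$environment,
        status = "error", low_fraction = NA_real_, high_fraction = NA_real_)
      NULL
    })
  }

  sample_tbl <- dplyr::bind_rows(samples)
  sample_tbl$note <- note[seq_len(nrow(sample_tbl))]

  # environment-averaged nonlinearities over analyzed global-contrast fields
  env_of <- vapply(fields, function(f) f$environment, character(1))
  nls <- list()
  for (env in unique(env_of)) {
    nls[[env]] <- build_nonlinearity(unname(fields[env_of == env]),
                                     environment = env)
  }
  nl_tbl <- dplyr::bind_rows(lapply(nls, tidy))

  re_tbl <- list()
  k <- 1
  for (sid in names(fields)) {
    for (env in names(nls)) {
      re_tbl[[k]] <- tibble::tibble(
        sample_id = sid,
        sample_environment = fields[[sid]]$environment,
        nonlinearity_environment = env,
        entropy_bits = response_entropy(
          apply_nonlinearity(fields[[sid]], nls[[env]]))
      )
      k <- k + 1
    }
  }

  out <- structure(
    list(samples = sample_tbl,
         contrast = dplyr::bind_rows(contrast_tbl),
         hemifields = dplyr::bind_rows(hemi_tbl),
         densities = dplyr::bind_rows(dens_tbl),
         slopes = dplyr::bind_rows(slope_tbl),
         nonlinearities = nl_tbl,
         response_entropy = dplyr::bind_rows(re_tbl),
         spectra = spectra,
         config = config),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) write_result_bundle(out, config$out_dir)
  out
}

write_result_bundle <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("samples", "contrast", "hemifields", "densities", "slopes",
               "nonlinearities", "response_entropy")) {
    readr::write_csv(result[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  cfg <- result$config
  jsonlite::write_json(
    list(density_bins = cfg$density_bins, f_s_range = cfg$f_s_range,
         f_t_range = cfg$f_t_range, n_bins = cfg$n_bins,
         local_contrast_stats = cfg$local_contrast_stats, seed = cfg$seed,
         n_samples = nrow(cfg$manifest)),
    file.path(dir, "run_config.json"), auto_unbox = TRUE, digits = NA,
    null = "null"
  )
  invisible(dir)
}

#' Environment-level summary report
#'
#' Reduces a pipeline result to the comparison tables: per-environment
#' means and SDs of every contrast statistic and spectral slope, pooled
#' t-tests with d-prime for each statistic across environments, the 2x2
#' environment-by-hemifield ANOVA for each hemifield statistic, and the
#' matched-versus-mismatched nonlinearity response-entropy comparison.
#' With fewer than 2 analyzed samples per environment the comparison
#' tables are skipped with a message.
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @return A list of tibbles: `environment_means`, `comparisons`,
#'   `anova` (long tibble over statistics), `entropy_comparison`.
#' @export
make_report <- function(result) {
  stopifnot(inherits(result, "pipeline_result"))
  ctr <- result$contrast[result$contrast$kind == "global", ]
  sl <- result$slopes
  stats_long <- dplyr::bind_rows(
    tidyr::pivot_longer(
      ctr[, c("sample_id", "environment", "variance", "skewness",
              "kurtosis", "entropy_bits", "prop_negative")],
      cols = c("variance", "skewness", "kurtosis", "entropy_bits",
               "prop_negative"),
      names_to = "statistic", values_to = "value"),
    tibble::tibble(sample_id = sl$sample_id, environment = sl$environment,
                   statistic = paste0("slope_", sl$domain),
                   value = sl$slope)
  )
  env_means <- dplyr::summarise(
    dplyr::group_by(stats_long, .data$environment, .data$statistic),
    mean = mean(.data$value, na.rm = TRUE),
    sd = stats::sd(.data$value, na.rm = TRUE),
    n = sum(is.finite(.data$value)),
    .groups = "drop"
  )

  envs <- unique(stats_long$environment)
  comparisons <- NULL
  anova_tbl <- NULL
  entropy_cmp <- NULL
  n_per_env <- table(result$samples$environment[
    result$samples$status == "analyzed"])
  if (length(envs) == 2 && all(n_per_env >= 2)) {
    comparisons <- purrr::map_dfr(unique(stats_long$statistic), function(st) {
      d <- stats_long[stats_long$statistic == st & is.finite(stats_long$value), ]
      a <- d$value[d$environment == envs[1]]
      b <- d$value[d$environment == envs[2]]
      if (length(a) < 2 || length(b) < 2) return(NULL)
      out <- ttest_dprime(a, b)
      out$statistic <- st
      out$environment_a <- envs[1]
      out$environment_b <- envs[2]
      out
    })

    hemi_long <- tidyr::pivot_longer(
      result$hemifields[, c("sample_id", "environment", "hemifield",
                            "mean_contrast", "variance", "kurtosis",
                            "skewness", "prop_negative")],
      cols = c("mean_contrast", "variance", "kurtosis", "skewness",
               "prop_negative"),
      names_to = "statistic", values_to = "value")
    anova_tbl <- purrr::map_dfr(unique(hemi_long$statistic), function(st) {
      d <- hemi_long[hemi_long$statistic == st & is.finite(hemi_long$value), ]
      fit <- tryCatch(anova_2x2(d), error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      eff <- tidy(fit)
      eff$statistic <- st
      eff
    })

    re <- result$response_entropy
    matched <- re$entropy_bits[re$sample_environment ==
                                 re$nonlinearity_environment]
    mismatched <- re$entropy_bits[re$sample_environment !=
                                    re$nonlinearity_environment]
    if (length(matched) >= 2 && length(mismatched) >= 2) {
      entropy_cmp <- ttest_dprime(matched, mismatched)
      entropy_cmp$comparison <- "matched vs mismatched nonlinearity"
    }
  } else {
    message("fewer than 2 environments with >= 2 analyzed samples; ",
            "comparison tables skipped")
  }

  list(environment_means = env_means, comparisons = comparisons,
       anova = anova_tbl, entropy_comparison = entropy_cmp)
}
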