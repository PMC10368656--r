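#' Laughlin contrast-response nonlinearities
#'
#' Under the efficient-coding argument of Laughlin, a neuron with one
#' continuous response dimension maximizes its information about contrast
#' when its response function equals the cumulative probability
#' distribution of contrast in the animal's environment: every response
#' level is then used equally often (histogram equalization), which
#' maximizes response entropy under uniform quantization.
#'
#' @name neural-coding
NULL

#' Build an environment-averaged contrast-response nonlinearity
#'
#' Evaluates each sample's empirical cumulative distribution of contrast
#' on a fixed linear grid, averages pointwise across samples, and enforces
#' monotonicity with a running maximum. The result is an
#' environment-level estimate of the optimal (CDF-shaped) contrast
#' response function.
#'
#' @param fields A `contrast_field` or list of them (one per sample).
#' @param grid Contrast grid; must span at least `[-1, 4]`. Default: 256
#'   linearly spaced points on `[-1, 4]`.
#' @param environment Label recorded for provenance; defaults to the first
#'   field's environment.
#' @return A `nonlinearity`: list with `contrast`, `response` (monotone,
#'   in `[0, 1]`), `environment`, `n_samples`.
#' @export
build_nonlinearity <- function(fields, grid = seq(-1, 4, length.out = 256),
                               environment = NULL) {
  if (inherits(fields, "contrast_field")) fields <- list(fields)
  if (length(fields) == 0) stop("need at least one contrast field",
                                call. = FALSE)
  if (min(grid) > -1 || max(grid) < 4) {
    stop("grid must span at least [-1, 4]", call. = FALSE)
  }
  cdfs <- vapply(fields, function(f) {
    v <- f$values[f$valid_mask]
    stats::ecdf(v)(grid)
  }, numeric(length(grid)))
  resp <- if (is.matrix(cdfs)) rowMeans(cdfs) else cdfs
  resp <- cummax(pmin(pmax(resp, 0), 1))
  structure(
    list(contrast = grid, response = resp,
         environment = environment %||% fields[[1]]$environment,
         n_samples = length(fields)),
    class = "nonlinearity"
  )
}

#' @export
print.nonlinearity <- function(x, ...) {
  cat(sprintf("<nonlinearity> %s, averaged over %d sample(s), %d grid points\n",
              x$environment, x$n_samples, length(x$contrast)))
  invisible(x)
}

#' Apply a nonlinearity to a contrast field
#'
#' Maps every contrast value through the nonlinearity by linear
#' interpolation on its grid; contrasts beyond the grid clamp to the end
#' responses (a CDF saturates at 0 and 1). Because the nonlinearity is
#' monotone, response ordering preserves contrast ordering.
#'
#' @param field A `contrast_field`.
#' @param nl A [build_nonlinearity()] result.
#' @return A `contrast_field` of kind `"response"` with values in
#'   `[0, 1]`.
#' @export
apply_nonlinearity <- function(field, nl) {
  stopifnot(inherits(field, "contrast_field"), inherits(nl, "nonlinearity"))
  resp <- stats::approx(nl$contrast, nl$response,
                        xout = as.vector(field$values), rule = 2)$y
  new_contrast_field(array(resp, dim = dim(field$values)), "response",
                     field$valid_mask, field$deg_per_px, field$environment)
}

#' Entropy of a neural response distribution
#'
#' Quantizes responses (which live in `[0, 1]` by construction) into
#' `n_levels` equal-width bins and returns the Shannon entropy in bits.
#' A field passed through its own environment's CDF approaches the
#' `log2(n_levels)` maximum (histogram equalization); a mismatched CDF
#' wastes response levels and yields lower entropy.
#'
#' @param responses A `contrast_field` of kind `"response"`, or a numeric
#'   vector/array of responses in `[0, 1]`.
#' @param n_levels Number of quantization levels. Default 256.
#' @return Entropy in bits.
#' @export
response_entropy <- function(responses, n_levels = 256) {
  v <- if (inherits(responses, "contrast_field")) {
    responses$values[responses$valid_mask]
  } else {
    as.vector(responses)
  }
  if (any(v < 0 | v > 1)) stop("responses must lie in [0, 1]", call. = FALSE)
  idx <- pmin(pmax(ceiling(v * n_levels), 1L), n_levels)
  shannon_bits(tabulate(idx, nbins = n_levels) / length(v))
}
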