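#' Inferential comparison layer
#'
#' The statistics used to compare environments and hemifields: unpaired
#' two-tailed pooled-variance t-tests with d-prime effect sizes,
#' one-sample tests of per-sample statistics against distributional
#' reference values (3 for kurtosis, 0 for skewness, 0.5 for proportion
#' negative), and 2x2 fixed-effects ANOVA (environment x hemifield) with
#' partial eta-squared and Tukey-Kramer pairwise follow-ups.
#'
#' @name inferential-stats
NULL

#' Unpaired two-tailed t-test with d-prime
#'
#' Pooled-variance unpaired t-test (Welch's correction available by flag)
#' plus d-prime: the absolute mean difference in pooled-standard-deviation
#' units. d-prime is invariant to a common affine rescaling of both groups
#' and to exchanging group labels. Zero pooled variance leaves d-prime
#' undefined (`NA`).
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param welch Use Welch's unequal-variance correction. Default `FALSE`.
#' @return A one-row tibble: `mean_a`, `mean_b`, `n_a`, `n_b`,
#'   `t_statistic`, `df`, `p_value`, `d_prime`.
#' @export
ttest_dprime <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  n1 <- length(group_a); n2 <- length(group_b)
  pooled_var <- ((n1 - 1) * stats::var(group_a) +
                 (n2 - 1) * stats::var(group_b)) / (n1 + n2 - 2)
  d_prime <- if (pooled_var > 0) {
    abs(mean(group_a) - mean(group_b)) / sqrt(pooled_var)
  } else {
    NA_real_
  }
  if (is.na(d_prime)) {
    # both groups constant: degenerate exact comparison
    same <- mean(group_a) == mean(group_b)
    return(tibble::tibble(
      mean_a = mean(group_a), mean_b = mean(group_b),
      n_a = n1, n_b = n2,
      t_statistic = if (same) 0 else Inf * sign(mean(group_a) - mean(group_b)),
      df = n1 + n2 - 2,
      p_value = if (same) 1 else 0,
      d_prime = NA_real_
    ))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = !welch)
  tibble::tibble(
    mean_a = mean(group_a), mean_b = mean(group_b),
    n_a = n1, n_b = n2,
    t_statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    d_prime = d_prime
  )
}

#' One-sample test against a distributional reference
#'
#' One-sample two-tailed t-test of per-sample statistics against a
#' reference constant: 3 for kurtosis (Gaussian), 0 for skewness
#' (symmetry), 0.5 for proportion negative. With zero variance the test
#' degenerates to an exact comparison of the mean against the reference
#' (`p = 1` if equal, `p = 0` otherwise).
#'
#' @param values Numeric vector of per-sample statistics, length >= 2.
#' @param reference Reference constant.
#' @return A one-row tibble: `mean`, `reference`, `n`, `t_statistic`,
#'   `df`, `p_value`.
#' @export
one_sample_reference <- function(values, reference) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (stats::var(values) == 0) {
    return(tibble::tibble(
      mean = mean(values), reference = reference, n = length(values),
      t_statistic = if (mean(values) == reference) 0 else Inf,
      df = length(values) - 1,
      p_value = if (mean(values) == reference) 1 else 0
    ))
  }
  tt <- stats::t.test(values, mu = reference)
  tibble::tibble(
    mean = mean(values), reference = reference, n = length(values),
    t_statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value
  )
}

#' 2x2 ANOVA with partial eta-squared and Tukey-Kramer follow-ups
#'
#' Two-way fixed-effects ANOVA with interaction over environment x
#' hemifield cells. Type II sums of squares accommodate unbalanced cells
#' (Type I and II coincide under balance). Effect sizes are partial
#' eta-squared, `SS_effect / (SS_effect + SS_error)`. Pairwise follow-ups
#' compare all six cell pairs with the Tukey-Kramer studentized-range
#' method (exact for unequal cell sizes).
#'
#' @param data A data frame with columns `value`, `environment`,
#'   `hemifield` (each factor-like with 2 levels); every cell needs >= 2
#'   observations.
#' @return An `anova_2x2` object: list with `effects` (tibble: `term`,
#'   `df`, `sum_sq`, `f_statistic`, `p_value`, `partial_eta_sq`),
#'   `pairwise` (tibble of 6 Tukey-Kramer comparisons), `ss_type = "II"`.
#' @export
anova_2x2 <- function(data) {
  need <- c("value", "environment", "hemifield")
  if (!all(need %in% names(data))) {
    stop("data must have columns value, environment, hemifield",
         call. = FALSE)
  }
  data <- data.frame(
    value = data$value,
    environment = factor(data$environment),
    hemifield = factor(data$hemifield)
  )
  counts <- table(data$environment, data$hemifield)
  if (any(counts < 2)) {
    stop("every environment x hemifield cell needs >= 2 observations",
         call. = FALSE)
  }
  fit <- stats::lm(value ~ environment * hemifield, data = data)
  a2 <- car::Anova(fit, type = 2)
  ss <- a2[["Sum Sq"]]
  terms <- rownames(a2)
  err <- which(terms == "Residuals")
  effects <- tibble::tibble(
    term = terms[-err],
    df = a2$Df[-err],
    sum_sq = ss[-err],
    f_statistic = a2$`F value`[-err],
    p_value = a2$`Pr(>F)`[-err],
    partial_eta_sq = ss[-err] / (ss[-err] + ss[err])
  )

  cell <- interaction(data$environment, data$hemifield, sep = ":")
  tk <- stats::TukeyHSD(stats::aov(value ~ cell,
                                   data = data.frame(value = data$value,
                                                     cell = cell)))$cell
  pairwise <- tibble::tibble(
    comparison = rownames(tk),
    diff = tk[, "diff"],
    conf_low = tk[, "lwr"],
    conf_high = tk[, "upr"],
    p_adjusted = tk[, "p adj"]
  )
  structure(
    list(effects = effects, pairwise = pairwise, ss_type = "II",
         model = fit),
    class = "anova_2x2"
  )
}

#' @export
print.anova_2x2 <- function(x, ...) {
  cat("<anova_2x2> Type", x$ss_type, "sums of squares\n")
  print(x$effects)
  invisible(x)
}
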