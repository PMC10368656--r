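# aquascene

Quantitative visual statistics of natural habitat video, built for
comparing aquatic scenes (such as shallow-water fish habitats) with
terrestrial ones. The package turns calibrated video into the summary
statistics that matter for visual neuroscience — contrast distributions,
their information content, spatiotemporal frequency structure, and the
contrast-response nonlinearities they imply — and ships synthetic video
generators with known ground truth so the entire pipeline is testable
without field recordings.

## What it computes

**Global contrast.** For linear intensities `I(x, y, t)` and the sample
mean `Ī` over the full window and duration,

    C(x, y) = (I(x, y) − Ī) / Ī

so the mean contrast is zero by definition and `C ≥ −1`. Per sample the
package reports the variance, skewness, non-excess kurtosis (Gaussian
= 3), the proportion of strictly negative contrast (dark dominance), and
the probability density over linearly spaced bins on [−1, 4].

**Entropy.** Shannon entropy `H = −Σ p(Cᵢ) log₂ p(Cᵢ)` over 256 discrete
levels (8 bits): the stored-code quantization classes of the camera.
Because contrast is a monotone relabeling of codes within a sample, `H`
is invariant to the camera nonlinearity.

**Local contrast.** A zero-sum isotropic difference of Gaussians
(σ_center = 1°, σ_surround = 2°) normalized by the local mean luminance,

    C_L = [I ∗ (g_c − g_s)] / [I ∗ g_s],

with kernel-width borders removed before any summary.

**Hemifields.** All contrast statistics split at the elevation-zero
midline (upper vs. lower visual field), with the whole-field
normalization retained so illumination-from-above shows up as a signed
mean-contrast asymmetry.

**Spatiotemporal power spectra.** Mean subtraction, separable 3-D Hann
window, 3-D FFT, then mean power in 19 × 19 logarithmically spaced bins:
radial spatial frequency rings over 0.05–0.75 cycles/degree and |f_t|
over 0.5–50 cycles/second (361 cells). Marginal spectra are fit by OLS
in log-log coordinates to give the familiar `1/f^n` slopes; joint-spectrum
differences carry iso-speed contours (`f_t / f_s`, degrees/second).

**Efficient coding.** Laughlin's principle: the optimal contrast-response
nonlinearity of a neuron is the cumulative probability distribution of
environmental contrast. The package builds environment-averaged empirical
CDFs, applies them to samples, and measures the response entropy under
256-level quantization — matched nonlinearities approach the 8-bit
maximum, mismatched ones waste response levels.

**Stimulus geometry.** A Snell's-law correction for visual stimuli viewed
through a water column: with the fish 0.25 cm above the container bottom,
a 0.5 cm water-equivalent container/stage, and a 5.65 cm air gap to the
screen, a grating designed with a 12° spatial period subtends only 9.3°
at the fish (≈ 0.11 cycles/degree acuity instead of 0.08).

**Inference.** Pooled-variance two-tailed t-tests with d′ effect sizes,
one-sample tests against distributional references (kurtosis 3, skewness
0, proportion negative 0.5), and 2 × 2 environment × hemifield ANOVAs
(Type II sums of squares) with partial η² and Tukey–Kramer pairwise
follow-ups.

## Worked example

Two synthetic environment classes — a narrow, low-contrast "aquatic-like"
lognormal scene and a wider "terrestrial-like" one, both with an
illumination gradient — run through the full pipeline:

```r
library(aquascene)

round(apparent_period(refraction_setup(), 12), 1)
#> [1] 9.3

mk <- function(sig, grad, seed) scene_spec(
  width_px = 64, height_px = 64, n_frames = 24,
  intensity_model = "lognormal",
  intensity_params = list(mean = 100, sigma_log = sig),
  gradient_amplitude = grad, seed = seed)

manifest <- tibble::tibble(
  sample_id   = sprintf("s%d", 1:6),
  environment = rep(c("aquatic", "terrestrial"), each = 3),
  spec        = c(lapply(1:3, function(i) mk(0.25, 0.3, i)),
                  lapply(1:3, function(i) mk(0.60, 0.5, 100 + i))))

result <- run_pipeline(run_config(manifest, local_contrast_stats = FALSE))
report <- make_report(result)

tidyr::pivot_wider(report$environment_means[, c("environment", "statistic", "mean")],
                   names_from = "environment", values_from = "mean")
#> # A tibble: 7 × 3
#>   statistic       aquatic terrestrial
#>   <chr>             <dbl>       <dbl>
#> 1 entropy_bits    6.28        7.07
#> 2 kurtosis        4.10        5.44
#> 3 prop_negative   0.556       0.615
#> 4 skewness        0.849       1.47
#> 5 slope_spatial  -0.474      -0.209
#> 6 slope_temporal  0.00361    -0.00245
#> 7 variance        0.0980      0.446
```

The narrow class shows the expected signature: lower contrast variance,
kurtosis and entropy, with dark dominance (proportion negative > 0.5) in
both. Applying each environment's averaged CDF nonlinearity to the
aquatic-like samples shows the efficient-coding effect — the matched
nonlinearity nearly saturates the 8-bit response channel:

```r
report$entropy_comparison[, c("mean_a", "mean_b", "t_statistic", "df", "p_value", "d_prime")]
#> # A tibble: 1 × 6
#>   mean_a mean_b t_statistic    df   p_value d_prime
#>    <dbl>  <dbl>       <dbl> <dbl>     <dbl>   <dbl>
#> 1   8.00   7.13        6.76    10 0.0000497    3.90
```

(`mean_a` is the matched-nonlinearity response entropy in bits, `mean_b`
mismatched.)

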