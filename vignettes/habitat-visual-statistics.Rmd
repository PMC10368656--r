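---
title: "Methods: spatiotemporal visual statistics of habitat video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatiotemporal visual statistics of habitat video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquascene)
```

This vignette documents the models, conventions and numerical choices
behind `aquascene`, in the spirit of a methods section: what each stage
computes, which knobs matter, what the synthetic generators do and do not
emulate, and where genuinely open design choices were settled.

## The measurement model

A sample is a rectified block of linear light intensities
$I(x, y, t)$ — by convention 225 × 225 pixels covering 75° × 75° of the
visual field at 1/3 °/pixel, over 10 s at 100 frames/s (1001 frames,
both endpoint frames included). Row 1 is the top of the visual field.
Smaller blocks are used freely in tests and examples; every operation
takes its calibration (`deg_per_px`, `frame_rate`) from the sample, not
from global state.

The ingest path is fixed in this order: read frames → keep the green
channel → Gaussian prefilter (σ = 2 source pixels, suppressing
compression blocking) → linearize stored codes through the camera's
monotone lookup → rectify → clipping check. The prefilter acts on raw
frames because its width is specified in source pixels; linearization
interpolates the lookup linearly between integer codes so prefiltered
(non-integer) codes remain valid.

**Rectification.** Each output pixel's view ray is built by gnomonic
(perspective) projection: a tangent plane orthogonal to the window's
central ray, sampled on a uniform angular grid mapped through the
tangent, then projected through the camera model (pinhole or equidistant
fisheye) and interpolated bilinearly from the source frame. Bilinear
interpolation is smooth, standard, and operates below the prefilter
scale; the round-trip error of the grid (ray → pixel → ray) is bounded
by half a source pixel in tests. For synthetic, already-rectified input
an identity camera maps angles directly to pixels so the downstream
pipeline is unchanged.

**Clipping.** Pixel-frames whose stored codes fall in the bottom or top
2% of the camera's code range are flagged; a sample with 10% or more
flagged pixel-frames is excluded outright (the boundary counts as
excluded). Surviving flagged pixels are masked out of all contrast
analyses but retain their linear values for spectral analysis, where
masking would punch holes in the Fourier support. The clip bands are
assessed on stored codes before linearization, because the thresholds
are defined relative to the camera's maximum code.

## Contrast, entropy and hemifields

Global contrast is $C = (I - \bar I)/\bar I$ with $\bar I$ the
spatiotemporal mean over unmasked pixels of the whole sample. Moments
use population (biased) estimators — at the default geometry a sample
contributes ~5 × 10⁷ pixel-frames, so estimator bias is negligible —
with kurtosis reported non-excess (Gaussian = 3). The proportion
negative counts strictly negative values; exact zeros count as neither
dark nor bright.

Entropy is computed over 256 discrete levels. The levels are the
sample's stored-code quantization classes: this makes $H$ exactly
invariant under any strictly monotone intensity transform (including
linearization and the contrast normalization itself), bounded by 8 bits,
and directly comparable across cameras. For continuous synthetic values
with no code layer, values are treated as discrete symbols when they
take at most 256 distinct values and are otherwise quantized into 256
equal-width bins over their observed range.

Local contrast divides a zero-sum difference of unit-sum Gaussians
(σ_center = 1°, σ_surround = 2°; 3 and 6 pixels at 1/3 °/px) by the
surround-Gaussian local mean. Kernels are truncated at 4 σ_surround and
renormalized; a border of the same width is cropped so padded-boundary
artifacts never reach summary statistics. Constant input yields exactly
zero response, and both contrast kinds are invariant to a global
intensity rescaling.

Hemifield summaries split rows at the elevation-zero midline; the middle
row of an odd-height grid belongs to neither half, keeping the split
unbiased. Hemifield means stay normalized by the *whole-field* mean, so
a bright-above illumination gradient appears as positive upper-field and
negative lower-field mean contrast.

## Spectral analysis

The spectrum pipeline subtracts the sample mean, applies a separable 3-D
Hann window, takes the 3-D FFT and squares amplitudes. Mean subtraction
precedes windowing — the reverse order lets the window modulate a
nonzero pedestal back into low frequencies. The Parseval identity
(`sum(power)/N = windowed signal energy`) is enforced in tests at 10⁻⁶
relative error.

Binning uses 19 bins per axis delimited by 20 logarithmically spaced
edges, 0.05–0.75 cycles/degree for the radial spatial frequency
$r = \sqrt{f_x^2 + f_y^2}$ (rings, so all orientations contribute
equally) and 0.5–50 Hz for $|f_t|$ (the two Hermitian-symmetric halves
fold together). Coefficients land in $[e_i, e_{i+1})$ cells; bin centres
are geometric means of their edges; the DC coefficient and out-of-range
coefficients are excluded. Cells that contain no Fourier coefficient —
unavoidable for small grids at the low-frequency end, where ring annuli
are thinner than the frequency resolution — propagate as missing with a
warning rather than as zeros.

Marginal spectra are computed from the raw grid (mean power per spatial
ring over *all* temporal frequencies and vice versa, with no band
restriction on the other axis), not from the 19 × 19 table. Slopes are
ordinary least squares of log₁₀ power on log₁₀ frequency over all bins
with positive power — no low- or high-frequency trimming. Joint spectra
compared across environments are cellwise *medians* across samples, and
their difference is reported in log₁₀ units with each cell's iso-speed
value $f_t / f_s$ (deg/s) attached: patterns drifting at speed $v$
concentrate power where the ratio brackets $v$.

For small synthetic samples the pipeline derives bin ranges from the
sample geometry (low edge at 1.5 frequency-resolution steps, high edge
at 90% of Nyquist, clipped to the defaults) so that slope fits are not
dominated by empty cells; the default ranges apply unchanged at the full
sample geometry.

## The synthetic generators

The generators define the study conditions for every test; they emulate
the statistical structure the analyses assume, not underwater optics.

* **Power-law videos** filter white Gaussian noise in the Fourier domain
  with the separable amplitude $r^{s_s/2} |f_t|^{s_t/2}$ (zero at the
  zero-frequency planes), inverse-transform, and affine-map into
  `mean × [0.1, 1.9]` so luminance stays positive and contrast is
  well-defined. Filtering real noise by a real, even amplitude is the
  Hermitian-symmetric random-phase construction in one step, and the
  target slopes are analytically known for recovery tests: at
  128 × 128 × 256 both slopes are recovered within ±0.2 averaged over
  five seeds.
* **Skewed fields** draw i.i.d. intensities from Gaussian, lognormal, or
  two-level models. The lognormal with log-scale σ has closed-form
  contrast skewness $(e^{\sigma^2}+2)\sqrt{e^{\sigma^2}-1}$ and
  dark-pixel proportion $\Phi(\sigma/2) > 1/2$, giving exact targets for
  the moment machinery; the two-level model pins the dark proportion at
  `p_low` exactly.
* **Gradient scenes** multiply a base field by a linear ramp from
  $1+a$ (top row) to $1-a$ (bottom), mean 1 — the simplest
  illumination-from-above model, with closed-form hemifield means on a
  constant base.
* **Dot fields** render hard, un-anti-aliased discs drifting with
  per-dot speeds (fixed or gamma-distributed) and toroidal wrap, so dot
  count is conserved and single-speed fields put binned power on the
  corresponding iso-speed locus. Hard discs are deliberate: the simplest
  speed-controlled stimulus whose spectrum still concentrates correctly
  after binning.

All generators are bit-reproducible given their spec (the seed is part
of the spec), and they restore the caller's RNG state.

What passing tests on this synthetic family shows — and does not show:
the pipeline correctly measures distribution shape, spectral slopes,
gradients and speed structure when those properties are present by
construction. Real footage adds compression artifacts, luminance
nonstationarity, camera motion and scene-specific structure that no
i.i.d. or separable-spectrum model reproduces; conclusions about real
habitats rest on the field recordings, not on the generators.

**Simulated digitization.** When the pipeline ingests synthetic
continuous intensities it first quantizes them to 8-bit stored codes
with saturation at four times the mean intensity
(`digitize_sample()`) — a camera auto-exposed to the scene. This gives
synthetic samples the same code layer as real footage, so the
clipping-exclusion rules and the 256-level entropy measure apply with
identical semantics: a low-contrast scene occupies few code levels and
scores low entropy, and bright lognormal tails clip at the top of the
range instead of stretching it. The headroom factor of 4 keeps clipped
fractions at realistic sub-percent levels for moderate contrast while
still allowing heavy-tailed scenes to saturate.

## Neural coding analysis

The environment-level nonlinearity is the pointwise mean of per-sample
empirical CDFs evaluated on a fixed 256-point linear grid over [−1, 4],
forced monotone by a running maximum (sampling noise can produce tiny
inversions after averaging). Responses interpolate linearly on that
grid and clamp beyond it, as a CDF saturates at 0 and 1. Response
entropy quantizes the [0, 1] response range into 256 fixed equal-width
bins — not data-adaptive bins, since the range is bounded by
construction. Two properties anchor the analysis: a sample passed
through its own CDF is within 0.1 bits of the 8-bit maximum at 10⁶
pixels (probability integral transform), and a matched-environment
nonlinearity never yields lower mean response entropy than the other
environment's on two-class synthetic data.

## Stimulus geometry

For a grating extending $\theta$ degrees from the nadir, the on-screen
extent is $x = d_\text{total}\tan\theta$ (straight-ray design). The
in-water angle actually reaching that extent solves
$x = d_\text{air}\tan\theta_a + d_\text{refr}\tan\theta_w$ with
$\sin\theta_a = (n_w/n_a)\sin\theta_w$, found by bisection on
$\theta_w$ (monotone objective, unconditionally convergent, terminated
at 10⁻⁹ cm extent residual). The container and transparent stage are
counted in the refracting path at the water index by default — their
material index is not known, and the water-equivalent treatment
reproduces the 9.3° worked example, while the air-equivalent alternative
(≈ 9.1°) remains available via `interface_medium`. The derived acuity
for the optomotor response is therefore reported as ≈ 0.11
cycles/degree (1/9.3°); a figure of 10.8 cycles/degree sometimes quoted
for this quantity is unit-inconsistent with a 9.3° period, so the
package derives the value rather than hard-coding it.

## Inference layer

d′ is the absolute mean difference in pooled-standard-deviation units
(Cohen's d with pooled SD) attached to a pooled-variance two-tailed
t-test; Welch's correction is available by flag but pooled is the
default. One-sample references test per-sample statistics against 3
(kurtosis), 0 (skewness) or 0.5 (proportion negative). The 2 × 2 ANOVA
uses Type II sums of squares — the samples per environment are
unbalanced in real datasets, and Type II coincides with Type I under
balance — with partial η² = SS_effect/(SS_effect + SS_error) and
Tukey–Kramer studentized-range follow-ups over all six cell pairs
(exact for unequal cell sizes). Hemifield enters as a crossed fixed
factor without a repeated-measures correction, mirroring how such
designs are conventionally reported; this is a fidelity caveat, not a
recommendation.

Type-I error of the t-test and ANOVA is verified by Monte Carlo under
the null at 0.05 ± 0.02, and Tukey–Kramer adjusted p-values are checked
to dominate unadjusted pairwise tests computed from the same pooled
error term.

## Problem sizes and degenerate inputs

Tests and examples run at reduced geometry chosen to keep every
statistical check well-powered: moment calibration at ≥ 10⁶
pixel-frames (kurtosis 3 ± 0.1, skewness 0 ± 0.05, proportion negative
0.5 ± 0.005 for Gaussian input), slope recovery at 128 × 128 × 256 over
five seeds, probability-integral-transform checks at ≥ 10⁶ values, and
Monte-Carlo calibration at 1500–2000 replicates. Degenerate inputs have
defined behaviour throughout: zero-variance fields report missing
skewness/kurtosis; non-positive mean intensity, fully-masked samples,
empty bins, constant groups and out-of-domain codes raise typed errors
or propagate missing values rather than silently producing numbers.

## Known limitations

* MP4 is not read directly (no codec binding); frames must be extracted
  to PNG first. Frame export quantizes to 8-bit PNG.
* The pipeline is green-channel, achromatic by design; no chromatic
  statistics.
* No physically-based underwater light transport: generators emulate
  statistics, not caustics or scattering.
* The hemifield ANOVA treats hemifield as an independent factor though
  both hemifields come from the same sample (see above).
* Ring binning assumes square pixels and isotropic sampling; orientation-
  resolved spectra are out of scope.
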