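---
title: "Models and methods behind hrmesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hrmesim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrmesim)
```

This vignette documents the models, parameter choices and numerical
conventions of `hrmesim`, in the spirit of a methods section: what is
simulated and why, which constants are physical, which are design choices,
and what the synthetic experiments do and do not establish about real
microendoscopy data.

## The imaging model

A fiber-bundle microendoscope images proflavine-stained epithelium in
contact mode: nuclei fluoresce brightly against dim cytoplasm, and the
coherent bundle superimposes a hexagonal core lattice ("honeycomb") on the
image. `hrmesim` models a scene as a **phantom**: a homogeneous Poisson
point process of nuclei (centers uniform over the extent, count Poisson
with mean density × area), each a disk with uniformly drawn radius and
intensity, on a constant cytoplasm background. Overlaps are permitted — at
the densities of interest (200–700 nuclei/mm²) a hard-core exclusion would
change little and would complicate exact density bookkeeping, which the
tests rely on.

Rendering a frame at time $t$:

1. **Exposure integration.** The probe center moves along a straight
   trajectory at constant speed $v$ (mm/s ≡ µm/ms). The frame is the mean
   of sub-exposure renders across the exposure window, so the
   within-exposure blur extent is $v \cdot t_{exp}$ (5 mm/s × 1.4 ms = 7 µm)
   and consecutive frames shift by $v / f$ (15 mm/s at 70 fps ≈ 214 µm).
   The number of sub-samples adapts to the blur extent (2 per pixel of
   blur, capped at 15); the blur integral conserves flux to well under 1%,
   which is tested.
2. **Resolution.** Convolution with an isotropic Gaussian whose FWHM equals
   the device's lateral resolution (4 µm). No further optics are modeled.
3. **Honeycomb.** A multiplicative hexagonal transmission map built from
   three 60°-spaced cosines, rescaled to [0.6, 1], with 3 µm pitch by
   default — below the 4 µm resolution, as in the real bundle, so the
   lattice is visible but does not dominate.
4. **Field of view.** Pixels outside the inscribed circle are zeroed.
5. **Noise.** Additive zero-mean Gaussian noise in linear intensity,
   clipped to [0, 1]; frame $i$ of a burst uses the deterministic substream
   `seed + i`.
6. **Gamma.** If the camera's `gamma_exponent` differs from 1, encoding is
   applied last and the frame is flagged `gamma_encoded`.

All arithmetic is floating point on normalized [0, 1] intensities;
quantization happens only when writing TIFF/PNG.

Neither camera's gamma curve is published, so `gamma_exponent` defaults to 1
(linear) and the degradation pipeline takes `source_gamma`/`target_gamma` as
configuration. Camera metadata (dynamic range 74.35 vs 57.85 dB, temporal
dark noise 3.8 vs 7.65 e⁻) is carried as reference attributes only.

## Severity and the synthetic cohort

Histopathology maps to three tiers: benign; AIN 1 (condyloma acuminatum is
grouped into this non-precancer tier, and retains its own histopathology
label in the records); and AIN 2+ (AIN 2, AIN 3, cancer), the positive
class. Neoplastic epithelium shows crowded, enlarged nuclei, so the
generator ties severity to nuclear morphology:

| tier   | density (mm⁻²) | radius (µm) |
|--------|----------------|-------------|
| benign | 200            | 3.0–4.5     |
| AIN 1  | 350            | 3.5–5.5     |
| AIN 2+ | 700            | 4.5–7.0     |

These are plausible for squamous epithelium at this resolution and were
fixed once as the package's study conditions. The tabular cohort generator
takes exact per-tier counts (the 11/71/22 analysis-set margins by default),
per-tier device-score distributions (Beta, means ordered
benign < AIN 1 < AIN 2+; the clinical per-tier distributions are not
published, so these are illustrative, not calibrated), per-tier
probabilities that the clinical comparator calls HSIL (taken from the
printed per-tier margins: 4/11, 35/71, 20/22), and a QC failure probability
(4.6% by default). Degenerate and two-point score distributions are
supported so tests can program an exact expected sensitivity/specificity
and verify the evaluation layer recovers it.

Probe speed during the scored burst defaults to 0.5 mm/s: clinicians
trigger frame capture while holding the probe in steady contact, so the
clinically selected frames are acquired well below the 15 mm/s sweep limit.

## The degradation pipeline

To emulate the slower camera, the pipeline executes, in order: optional
gamma inversion of the contributing frames; averaging of the selected frame
with its four *preceding* frames (a trailing window, matching how a slower
camera would have integrated the same interval — 70 fps/5 = 14 fps
equivalent, 5 × 1.4 ms = 7 ms composite exposure); optional Gaussian
fiber-core smoothing (σ = 1 px — "small" relative to nuclei, enough to
soften the lattice that averaging reinforces); optional noise injection;
optional saturation preservation (averaging dampens saturation, so pixels
at or above the saturation level in the selected frame are restored to full
scale); optional gamma re-encoding; and optional contrast reduction.

**Noise calibration.** Averaging $n$ frames divides the source noise
variance by $n$; injected noise of sigma $s$ gives a composite blank-frame
noise floor $\sqrt{s^2 + \sigma_{in}^2/n}$. The default
$s = \sigma_{in}\sqrt{r^2 - 1/n}$ targets a composite/source noise-floor
ratio of $r = 4$, the blank-target ratio measured between the two real
cameras. This is an analytic calibration, verified by Monte-Carlo in the
tests.

**Contrast reduction.** The luminance-statistics transfer is the grayscale
special case of mean/variance color transfer:
$I' = (I - \mu_I)/\sigma_I \cdot \sigma_T + \mu_T$, clipped to [0, 1]. On a
single-channel image the CIELAB L channel is a monotone function of
intensity, so the transfer is applied directly on normalized intensity —
this keeps the pre-clip mean/std contract exact (and testable) rather than
approximate through the L* nonlinearity. The target is a pooled statistic
of the emulated dataset, supplied as configuration; the default
(µ = 0.16, σ = 0.055) represents a dimmer, lower-contrast pooled pilot
distribution relative to the renderer's output. Under it the degradation
compresses class differences from both sides — dim low-severity frames are
amplified toward the target, bright high-severity frames are compressed —
which is the direction the package's end-to-end property tests assert
(low-severity mean scores rise, high-severity fall).

The six-method ablation harness toggles exactly one component off per
method (2: gamma, 3: smoothing, 4: noise, 5: saturation preservation,
6: contrast reduction); Method 1 enables all five, and frame averaging
always runs. With every toggle off and `n_average = 1` the pipeline is the
bit-exact identity, the anchor case for the determinism tests.

## Scoring

Frames are resampled to the reference pitch by the deployed convention —
the factor is the pitch ratio rounded to one decimal (1.24/0.78 → 1.6×;
an exact-ratio mode exists) — then the probe disk is located by Otsu
thresholding of a heavily smoothed copy (σ = side/12 homogenizes cellular
texture so the threshold separates lit from unlit rather than nuclei from
cytoplasm), keeping the largest connected component. Its centroid and
equivalent radius define a bounding square (clamped to the raster; the
radius is capped at the inscribed circle for full-frame illumination),
which is split at its midpoint into four quadrants; for odd sides the
first row/column block takes the extra pixel, so the quadrants always tile
the crop exactly.

The per-quadrant classifier is pluggable. The included baseline segments
nuclear pixels at a **fixed** intensity threshold (0.3 normalized),
computes count density, mean equivalent radius, area fraction and
foreground/background ratio, and maps a fixed weighted sum through a
logistic. Two deliberate choices:

- The threshold is fixed, not adaptive: an adaptive (Otsu) threshold would
  re-normalize away exactly the contrast changes the degradation pipeline
  introduces, making the scorer blind to the mechanism under study.
- The weights are design constants, not trained parameters. The scorer is
  a stand-in for a learned network and claims no clinical accuracy; what
  the tests establish is ordinal behavior (monotone in density and size,
  rank correlation above 0.8 with severity across a 104-site synthetic
  cohort at 256 px rasters) — not calibrated probabilities.

Site score = arithmetic mean of the four quadrant probabilities; the
positivity call is **inclusive** (score ≥ cutoff, default 0.4). Tie
handling is unstated in the deployed system; the reference example scores
(0.08, 0.67, 0.71) are unaffected either way.

Automated QC replaces the original three-expert majority review with a
stated proxy: contact fraction (in-region pixels above an absolute
intensity threshold, default 0.1 — out-of-contact areas are dark) and
sharpness fraction (8 px tiles whose mean squared gradient exceeds 10⁻⁴),
failing iff more than half the field is degraded (strictly greater, so an
exactly half-degraded field passes). The thresholds are configuration
defaults, not a validated replication of expert review.

## Feature shift

The feature extractor emits 64-element vectors (intensity moments, a 16-bin
histogram, deciles, gradient and texture summaries, the morphometry block,
zero-padded), matching the embedding width of the deployed network's
classification branch. The divergence between two labeled collections is
the **average per-dimension Gaussian Kullback–Leibler divergence**: fit a
univariate Gaussian per dimension per set and average the closed form
$\log(\sigma_b/\sigma_a) + (\sigma_a^2 + (\mu_a - \mu_b)^2)/(2\sigma_b^2) - 1/2$
over dimensions. No estimator for the original studies is documented; this
choice matches the phrase "average K–L divergence", is exactly testable
against the closed form, and is reported as KL(a‖b) with `a` the degraded
or query set and `b` the reference (the direction is asymmetric and
documented rather than symmetrized). A Kozachenko–Leonenko-style 1-NN
estimator on the full vectors is available behind a flag; it can go
slightly negative at small samples (tolerance −0.05 in the tests).
Zero-variance dimensions are floored at 10⁻⁸ rather than raised as errors,
and an optional switch standardizes both sets by the reference set's
per-dimension location/scale before estimation (off by default).

The 2-D embedding is an exact (dense) t-SNE implemented in the package —
perplexity-calibrated Gaussian affinities by bisection, Student-t
low-dimensional kernel, momentum gradient descent with early exaggeration.
It is visualization-only: deterministic for a fixed seed, but no package
statistic depends on its geometry, and the tests only check cluster
separation (silhouette) and reproducibility.

## Diagnostic evaluation

All agreement statistics are computed from the stratified
2 × 2 × 3 table. Conventions:

- **Wilson score intervals** for binomial proportions. The original report
  prints intervals without naming a method; among the standard candidates
  (Wald, Clopper–Pearson, Agresti–Coull, Wilson with and without continuity
  correction), only the Wilson score interval reproduces all four printed
  bounds for 20/22 (0.72–0.97) and 71/82 (0.77–0.92) at the printed
  two-decimal precision — under truncation; the 71/82 lower bound is
  0.7755, which truncates to the printed 0.77 but rounds half-up to 0.78.
  The package computes exact bounds and leaves presentation rounding to the
  caller; the replay check uses the truncation convention.
- **Exact McNemar**: $p = \min(1,\, 2\,P(X \le \min(b,c)))$,
  $X \sim \mathrm{Bin}(b+c, 1/2)$, $p = 1$ for no discordance. The exact
  form (not the χ² approximation) is required to return exactly 1 for the
  balanced 2-vs-2 sensitivity discordance.
- **Cohen's κ** with marginal-product expected agreement, returning 1
  directly in the degenerate all-one-category, all-agree case.
- **ROC** thresholds are the unique scores with inclusive (≥) positivity,
  matching the site-call rule; trapezoid integration makes the AUC equal
  the Mann–Whitney statistic with half credit for ties (verified against
  exhaustive pair counting). PR-AUC uses step integration (the
  average-precision convention). The matched operating point takes, among
  thresholds attaining the target sensitivity, the one with maximal
  specificity, ties toward the higher threshold.
- **Two-proportion χ²** defaults to no continuity correction (the original
  report gives no detail); the Yates-corrected variant is a flag.
- Proportions are stored as exact fractions; `print()` rounds to two
  decimals to match the field's reporting style.

## Problem sizes and what the tests show

The test and acceptance workloads are sized for a single CPU: rendered
rasters of 24–128 px for unit tests, 96 px bursts (8 sites/class) for the
degradation-direction property, 256 px single frames for the 104-site
rank-correlation property, and 10⁵-sample Gaussian collections for the
divergence calibration checks. The printed-table statistics are exact
integer/closed-form computations and run in milliseconds.

Passing these tests establishes internal consistency — exact statistics,
conservation laws, calibrations, monotonicities and directions on data the
generator produces. It does not establish clinical performance: the
phantoms lack real tissue texture, debris, uneven staining, and probe
deformation; the baseline scorer is not the deployed network; and the
clinical headline values that depend on unavailable data (AUC 0.96,
PR-AUC 0.83, the printed K–L divergences 0.433/0.211/…, the hardware Weber
fractions 7.3/1.7) are intentionally not reproduced — only their defining
computations are provided and verified on synthetic targets.

## Known limitations

- The per-dimension Gaussian KL ignores feature correlations; a full
  covariance estimator would need far more samples per set than a typical
  ablation run provides.
- Probe detection assumes a single bright disk; multi-component
  illumination defeats the largest-component rule.
- The QC proxy approximates a consensus of human experts with two global
  thresholds; its agreement with expert review is untested by construction.
- The exact t-SNE is O(n²) and intended for hundreds, not tens of
  thousands, of vectors.
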