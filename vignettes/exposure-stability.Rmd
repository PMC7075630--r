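---
title: "Exposure-invariant domains of PET texture features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exposure-invariant domains of PET texture features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(texstab)
```

## The problem

Haralick texture features are second-order statistics of a grey-level
co-occurrence matrix (GLCM) and are increasingly used as quantitative image
biomarkers in PET/CT. But PET voxel values are contaminated by count-driven
noise whose character depends on the reconstruction algorithm, so a "texture"
measured in a perfectly homogeneous object is, at short acquisitions, mostly
an image of the noise. Before texture values can be compared across scanners
or protocols, one must know at which *exposure* — the product of activity
concentration and acquisition duration, `E = AC * t` in kBq/ml·s — each
feature stops depending on the noise level. This package provides the full
pipeline for that question: simulate (or load) homogeneous-phantom VOIs over
a wide exposure range, compute first-order and Haralick features under
several grey-level quantizations, smooth the feature-versus-exposure clouds,
and detect the exposure domains where features are stable.

Exposure rather than duration makes the analysis transferable: a scanner
with tenfold lower sensitivity needs tenfold longer acquisitions for the
same exposure, and a decaying tracer is handled by the integral form
`AC0 * (1 - exp(-lambda*t)) / lambda` of `compute_exposure()`.

## The noise model

Real reconstructions imprint characteristic voxel-noise marginals on a
homogeneous object: filtered back-projection (FBP) is linear and yields
approximately Gaussian voxel noise at all exposures, including negative
voxel values at low exposure; iterative OSEM and PSF (resolution-modelling)
reconstructions yield non-negative, right-skewed noise resembling gamma or
log-normal distributions, which converge to a Gaussian as counts grow. The
synthetic generator replaces the reconstruction chain with exactly these
parametric marginals:

* `gaussian_fbp` — `Normal(ac, ac * CV)`;
* `gamma_iterative` — `Gamma(shape k = E / alpha^2, scale ac / k)`, so
  skewness `2/sqrt(k)` and excess kurtosis `6/k` vanish as exposure grows;
* `lognormal_iterative` — a log-normal matched to the same mean and CV.

In every archetype the mean equals the true activity concentration at every
exposure, and the coefficient of variation follows the count-statistics
power law `CV(E) = alpha * E^(-1/2)` — the square-root law that photon shot
noise imposes on SNR. The default `alpha = 5` puts `CV = 0.5` at
`E = 100 kBq/ml*s`, which spans the realistic range from nearly
noise-dominated (CV ≈ 0.93 at the shortest default frame) to sub-percent
noise at the longest.

Voxels are drawn i.i.d.; optional Gaussian smoothing (`smoothing_fwhm`, mm)
adds neighbour correlation the way post-reconstruction filters do, with the
noise field rescaled afterwards so the *marginal* CV stays on the analytic
power law (this keeps all first-order expectations closed-form). The default
is no smoothing. What the generator deliberately does **not** emulate:
object-dependent covariance of iterative reconstructions, the point-spread
function, scatter/attenuation residuals, or tomographic artefacts. Passing
tests therefore demonstrate correctness of the *pipeline* and of the
noise-convergence mechanism, not equivalence with any particular scanner.

The default acquisition schedule places 25 frame durations geometrically
from 3 s to 10861 s (step ratio ≈ 1.407) with 20 replicates each, at
9.54 kBq/ml and no decay (a Ge-68 phantom is effectively constant over a
session); exposures then span 28.6 to 1.04e5 kBq/ml·s. Per-item seeds are
derived deterministically from the master seed, so any single VOI is
reproducible in isolation.

## The VOI rule

All statistics are computed in a cuboid VOI of about 50 mm edge length at
the phantom centre. Per axis the voxel count is the even integer nearest to
`50 / spacing`, ties rounded upward — the only reading consistent with the
published 12×12×12 (4 mm), 24×24×26 (2 mm) and 32×32×34 (1.5 mm) grids.
For real volumes, `extract_voi()` centres the cuboid either on the image
centre or on the detected phantom (50% of the 99th-percentile intensity,
centre of mass) — both are exposed because an automatic detector and the
geometric centre can disagree on clipped or off-centre scans.

## First-order statistics

`first_order_stats()` returns eleven descriptors: mean, SD, CV, excess
kurtosis, skewness, Lilliefors D and p, Gaussian-histogram-fit NRMSD, crest
factor (dB), normalized histogram entropy ("efficiency") and mode/mean.
Conventions that required a decision:

* **Moments** use the population (1/N) normalisation, exactly as the
  defining equations are written; the Lilliefors test alone uses the (n−1)
  SD because it is a named test with a fixed convention.
* **Lilliefors p** comes from a seeded Monte-Carlo null (default 10^3–10^4
  Gaussian samples of the same N) rather than table approximations, which
  are unreliable over the twelve orders of magnitude this analysis spans;
  p is floored at `1/(reps+1)` and never reported as 0. The null depends
  only on N, so `run_study()` computes it once and reuses it for all VOIs.
* **Efficiency** is the histogram entropy over a 256-level min–max
  discretization, normalised by `log(N)` with N the voxel count, as the
  defining expression is printed; the discretization and the log base are
  configurable because the original text fixes neither.
* **NRMSD** fits a 3-parameter Gaussian to Freedman–Diaconis histogram
  counts by nonlinear least squares and normalises the RMS residual by the
  count range; the normalising constant is a documented choice.
* **Crest factor** uses `max(|c|)`, relevant when FBP noise drives voxels
  negative.
* Degenerate inputs (zero variance) yield `NA` for standardized moments
  with an explicit flag — never a silent zero.

## GLCMs and Haralick features

`quantize()` implements three grey-level mappings: per-VOI min–max
("mapped", the Tixier resampling: VOI minimum to level 1, maximum to level
G), fixed global bounds ("full_range", out-of-range values clamped to the
end levels and counted), and fixed bin width from zero ("fixed_bin_zero").
`build_glcm()` counts orthogonally adjacent voxel pairs at displacement
d = 1 along the two in-plane axes (0° and 90°), by default across all
slices; an option adds the axial offset, since the original in-plane/3-D
choice is not documented. Counting is symmetric (each pair in both orders),
R is the ordered-pair total, and `P = counts / R` sums to one.

`haralick_features()` evaluates the eleven features (ASM, contrast, IDM,
entropy, correlation, variance, sum average, sum entropy, difference
entropy, cluster shade, cluster prominence) with `0·log 0 = 0` and natural
logarithms by default (the defining equations write a bare "log"; the base
is configurable and recorded). Two printed-equation quirks are handled
explicitly:

* the marginal SDs are the probability-weighted
  `sqrt(sum_i (i - mu_x)^2 Px(i))`; the printed expression omits the
  weights and squares a difference of mismatched quantities, which cannot
  be what was computed;
* the variance feature's internal mean is written as
  `mu = (1/G^2) * sum P(i,j)`, which reduces to the constant `1/G^2`. It is
  implemented as printed (default) with the conventional grey-level mean
  behind `variance_mu = "marginal_mean"`, because the published curves do
  not disambiguate the two.

## Smoothing and stability detection

Feature values from all replicates are plotted against exposure and
smoothed with a degree-1 locally weighted regression (tricube weights) on
log-log axes, so each decade of the geometric schedule contributes equally.
The window covers the 13 nearest *distinct exposure stations*; all
replicate points at those stations enter the fit. (A window of 13 raw
points would sit entirely inside one 20-replicate station and leave the
local line unidentifiable — the station reading is the one that makes a
fixed-width window well-posed with replicated designs.) Each local fit
yields the smoothed value, the analytic slope of the local line — which on
log-log axes is `d ln F / d ln E` — and t-based standard errors from the
weighted residuals.

Features that can take non-positive values (cluster shade, correlation) are
smoothed on semi-log axes (log10 E vs raw F), and their relative slope is
computed as `(dF/dlogE) / (ln 10 * |F|)`; the choice is recorded per curve.

A **plateau onset** is the smallest measured exposure at which
`|d ln F / d ln E| <= 0.05` and the criterion continues to hold at every
larger measured exposure — the one-sided printed form `ΔF/(ΔE·F) ≤ 0.05/E`
is exactly this log-log slope bound, taken with an absolute value so that
decreasing features plateau symmetrically, and read strictly so that a
curve dipping back out of tolerance has its onset reset. A feature whose
onset is the first station is flagged stable over the entire range.
**Islands of stability** — for quantizations that never reach a global
plateau — are maximal runs of stations whose derivative confidence interval
(default 99%) contains zero. **Variability** of a feature is
`log10(max|F|) - log10(min|F|)` in Bel over values above 1e-12 in
magnitude; near-zero values are excluded and counted, since sign-changing
features otherwise produce unbounded log ranges.

## The study driver

`run_study(study_config(...))` executes the whole pipeline deterministically
from one seed and returns a classed object with the long feature table, the
per-curve fits, and a report row per (archetype, scheme, G, feature) with
onset exposure, onset time at the stated AC, island intervals and Bel range.
The default configuration (two archetypes, 25 × 20 VOIs of 24×24×26 voxels,
mapped 256-level GLCMs) runs in well under a minute; these problem sizes are
the package's defaults and were chosen to match the phantom study design
while remaining desk-scale. `write_report()` emits a schema-stamped JSON
(absent plateaus are explicit nulls) plus a tidy CSV of the curves, and
`read_report()` round-trips it.

## Known limitations

* The i.i.d. marginals ignore the spatial covariance of real iterative
  reconstructions; onset exposures from the synthetic study characterise
  the pipeline, not a specific scanner. Real phantom series can be fed in
  via `read_volume()` + `extract_voi()` or the `series` argument of
  `run_study()`.
* A Monte-Carlo-calibrated Lilliefors p in a 15k-voxel VOI is extremely
  sensitive: the gamma archetype's residual skew `2/sqrt(k)` remains
  statistically detectable across the entire default schedule, so the
  median p approaches but does not exceed 0.5 within it. Published analyses
  showing p saturating at unity reflect correlated voxels (smaller
  effective N) and saturating table approximations; with this package's
  exact p the coincidence of feature plateaus with "p reaching unity"
  should be read qualitatively, not as a crossing of p = 0.5.
* DICOM series are not read directly; convert to NIfTI-1 first.
* Displacements d > 1 and diagonal directions are out of scope by design.
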