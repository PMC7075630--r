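# texstab

Exposure stability of Haralick texture features in PET phantom images.

## What it is for

PET radiomics relies on texture features being comparable across scanners,
protocols and acquisition times. In a perfectly homogeneous phantom, any
apparent texture is image noise, and its character depends on the
reconstruction: filtered back-projection (FBP) leaves approximately Gaussian
voxel noise at every count level, while iterative OSEM/PSF reconstructions
leave right-skewed (gamma / log-normal-like) noise that only becomes
Gaussian as counts grow. Texture feature values therefore drift with
**exposure** `E = AC * t` (activity concentration × acquisition duration,
kBq/ml·s) until the noise distribution stops changing, after which they sit
on a stable plateau. `texstab` implements the full analysis that locates
those exposure-invariant domains:

* a synthetic homogeneous-phantom generator with three reconstruction noise
  archetypes, mean fixed at the true activity concentration and
  `CV(E) = alpha * E^(-1/2)`;
* the cuboid VOI rule (~50 mm edge, nearest even voxel count per axis) and
  exposure arithmetic, including the decaying-source integral;
* eleven first-order statistics (CV, skewness, excess kurtosis, Lilliefors
  D and Monte-Carlo p, Gaussian-fit NRMSD, crest factor, normalized
  histogram entropy, mode/mean);
* grey-level co-occurrence matrices at displacement 1 (0° ∪ 90°) under
  min–max ("mapped"), full-range and fixed-bin-from-zero quantization, with
  3 to 9 bit grey scales;
* the eleven Haralick features (ASM, contrast, IDM, entropy, correlation,
  variance, sum average, sum/difference entropy, cluster shade/prominence);
* fixed-window (13 exposure stations) tricube local regression on log-log
  axes with analytic slopes and confidence intervals, plateau-onset
  detection via the relative-slope criterion
  `|d ln F / d ln E| <= 0.05`, islands of stability (derivative CI
  containing zero) and variability ranges in Bel.

## Worked example

A reduced study — two noise archetypes, 13 durations × 5 replicates on a
12×12×12 VOI (4 mm voxels), 64 grey levels, mapped quantization:

```r
library(texstab)
cfg <- study_config(archetypes = c("gaussian_fbp", "gamma_iterative"),
                    voxel_size = c(4.07, 4.07, 4.0),
                    durations = default_durations(13),
                    replicates = 5L, levels = 64L, seed = 42L)
st <- run_study(cfg)
summary(st)
#> Stability summary (exposures in kBq/ml*s, times in s):
#>         archetype scheme  G n_features n_stable_over_range median_onset
#> 1 gamma_iterative mapped 64         11                   3      1295.98
#> 2    gaussian_fbp mapped 64         11                   9        28.62
#>   median_onset_time max_bel lilliefors_cross
#> 1             135.8   2.759            13358
#> 2               3.0   2.716              222
```

Reading: with Gaussian (FBP-like) noise, 9 of the 11 Haralick features are
already stable at the lowest measured exposure (28.62 kBq/ml·s, the 3 s
frame) — the noise shape never changes, so mapped-GLCM features do not
drift. With gamma (OSEM/PSF-like) noise the median feature only reaches its
plateau at ~1.3e3 kBq/ml·s (≈136 s at 9.54 kBq/ml), and feature values span
up to ~2.8 Bel (a ~600-fold range) below their plateaus — measuring texture
at too low an exposure changes the numbers by orders of magnitude.
`plot(st, features = "asm")` shows the underlying curve; single steps are
available as `simulate_voi()`, `first_order_stats()`, `quantize()`,
`build_glcm()`, `haralick_features()`, `loess_loglog()`, `plateau_onset()`.

Real volumes enter through `read_volume()` (NIfTI-1) and `extract_voi()`,
or as a precomputed `series` to `run_study()`; `write_report()` /
`read_report()` round-trip the results as JSON + CSV.

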