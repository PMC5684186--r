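---
title: "Methods: NIR hyperspectral nitrate mapping in leaves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NIR hyperspectral nitrate mapping in leaves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitramap)
```

## The problem

Nitrate taken up by a leafy vegetable under nitrogen fertilisation is
not distributed uniformly: petioles and veins accumulate several-fold
more than the blade, and the content changes during post-harvest
storage as nitrate reductase keeps working at a temperature-dependent
rate. Wet chemistry (extraction plus reflectometry) gives one number
per destructively sampled disc. NIR hyperspectral imaging instead
records a full reflectance spectrum per ~156 µm pixel, and a
calibration model turns each spectrum into a concentration — giving a
spatial map from a single non-destructive scan. `nitramap` implements
that pipeline end to end and, because no real spectra of this kind are
publicly available, validates every stage against synthetic leaf
phantoms with known ground truth.

## Measurement model

A push-broom scanner images one spatial line per exposure while the
stage translates, producing a cube of raw counts `S` over rows (scan
direction) × columns (detector positions) × bands. Counts are
normalised between a dark image `B` (capped lens) and a white-plate
scan `W`:

$$R_{\lambda n} = \frac{S_{\lambda n} - B_{\lambda n}}
                       {W_{\lambda n} - B_{\lambda n}}$$

Both references are single line scans, stored as columns × bands
matrices and broadcast along the scan direction. Detector elements with
`W = B` have undefined reflectance; they are marked `NA` and excluded
from every downstream statistic rather than propagating as ±Inf.

### Stripe noise and its removal

Per-column detector-gain drift produces stripes running along the scan
direction: a pattern that varies across columns and is nearly constant
along rows. In the 2-D discrete Fourier domain this pattern lives on
the near-zero row-frequency line. `destripe_fft()` attenuates a notch
of half-width 2 bins around that line (cosine-tapered edge, attenuation
0 inside), band by band.

The one genuinely open design choice is the **DC guard** — how many
low column-frequency bins to protect. Protecting only the DC bin keeps
mean brightness but forces every column of the output to the same mean,
because the whole kr = 0 line is removed: on our phantoms this biased
the narrow petiole's mapped mean by ~30% and even inverted the
petiole/vein ordering, and it changed a clean smooth test image by 15%
RMS. The scene's own column profile is smooth and therefore
concentrated in the first few column-frequency bins, while the stripes
of interest are high-frequency (default period 4 px → bin `n_cols/4`).
The default guard is therefore 8 bins: stripes of period shorter than
`n_cols/8` are fully attenuated, the scene profile is untouched, and
the filter is near-identity (< 0.1% RMS change) on smooth stripe-free
images. All four parameters (axis, half-width, guard, attenuation) are
configurable in `stripe_filter_config()`.

A second, map-level smoothing (`smooth_map()`) is available for the
finished concentration image: a masked moving average across the stripe
axis that never mixes background into leaf values.

## Spectral preprocessing

The default calibration recipe (`default_recipe()`) is

1. `crop(932.1, 2217.8)` — the informative window; band selection uses
   a closed interval on the wavelength axis;
2. `snv` — per-spectrum centring and scaling to unit *sample* standard
   deviation (n − 1 denominator), removing multiplicative scatter and
   additive offsets;
3. `derivative(gap = 1, segment = 2)` — gap-segment first derivative.

The gap-segment derivative deserves precision, since published
descriptions vary. Ours uses two segments of `segment` points separated
by `gap` skipped points; the derivative is (upper segment mean − lower
segment mean) divided by the centre-to-centre separation
`segment + gap` in index units, so a line of unit slope per band index
differentiates to exactly 1 — many chemometrics codes skip this
normalisation; ours states and tests it. The output axis keeps only
positions where both segments fit (`n − 2·segment − gap + 1` bands),
with no edge padding, so every output value is a pure function of
observed data.

The order SNV-then-derivative is not canonical in the literature; both
orders are expressible, the default applies SNV to reflectance first
(scatter is multiplicative in reflectance, so SNV removes it before
differencing), and the order actually used is frozen inside the fitted
model, which stores its entire recipe and re-applies it at prediction
time.

## PLS calibration

`fit_pls()` is classical NIPALS PLS1: X and y are mean-centred (never
variance-scaled — standard for spectral data where all bands share
units), then factors are extracted sequentially (weights from the X/y
covariance, scores, loadings) with deflation after each factor. The
inner iteration starts from the maximal-variance X column and stops
when the relative score change falls below 1e−10 (cap 500 iterations);
with a single response the direction is stationary, so convergence
occurs on the second pass, but it is checked, not assumed. The fit is
deterministic and seed-free.

Model selection uses leave-one-out cross-validation (`loocv()`): refit
on n − 1 samples, predict the held-out spectrum at every factor count,
report RMSECV per factor count and choose the smallest count attaining
the minimum (`select_factors()`; ties break toward fewer factors,
default search cap 20 factors). The cross-validated r² is the squared
Pearson correlation between references and held-out predictions; the
`1 − SSE/SST` variant is computed alongside
(`r2_1msst_by_factor`) because the two definitions differ under bias
and the field's usage is ambiguous.

Key invariants, all tested: score orthogonality (< 1e−8 cosine),
training RMSE non-increasing in factor count, exact equivalence with
ordinary least squares at full rank, exact scale equivariance in y, and
exact agreement of LOOCV with a brute-force refit oracle implemented
independently through the Krylov-subspace characterisation of PLS1.

## Mapping

`map_concentration()` extracts each in-mask pixel spectrum, applies the
model's stored recipe, and predicts. Processing happens in spatial
blocks (default 4,096 spectra) so cubes larger than memory stream
through; since every preprocessing step is row-independent, the result
is bit-identical for any block size (tested). Predictions are clipped —
by default the caller passes `[0, 1.5 × calibration max]` — because PLS
extrapolates at vein/petiole pixels whose true content exceeds the
calibration ceiling; the clipped-pixel count is recorded in the map.
Extrapolated predictions are attenuated toward the calibration range
(SNV normalises spectral amplitude, so the transformed spectrum
saturates as concentration grows); region *ordering* is preserved and
tested, absolute vein/petiole values are reported as indicative.

Leaf segmentation thresholds the band nearest 1,450 nm (the water
absorption feature: a hydrated leaf is dark, the dry background
bright), keeps the largest connected component and fills holes
(via EBImage). This is a stand-in for whatever the original
instrument's operators did — any mask of the same shape can be supplied.

## The synthetic generator

`phantom_config()` fixes the study conditions. Choices and their
reasons:

* **Axis**: 256 bands from 913 nm in 6.2 nm steps (the instrument
  geometry this pipeline targets).
* **Forward model**: absorbance
  `A = baseline + (c / 5000 mg/kg) · analyte + s · interferents`,
  reflectance `R = m · 10^(−A) + o + ε`. Each distortion exercises
  exactly one pipeline stage: multiplicative scatter `m` (U[0.85,
  1.15]) and offset `o` (sd 0.01) are removed by SNV, the smooth
  polynomial baseline by the derivative, column-gain stripes (10%
  amplitude, period 4 px) by the notch filter, and band noise `ε`
  (sd 0.004) by the multivariate regression itself.
* **Analyte signature**: Gaussian peaks near 1,500 and 2,050 nm with
  absorbance 0.15 at the 5,000 mg/kg reference — a modelling stand-in;
  the true in-matrix NIR signature of nitrate is not available, only
  its qualitative basis (C–H/O–H/N–H overtone region). Water-like
  interferent peaks sit at 1,450/1,940 nm with per-sample strength
  variation (sd 15%), which is what makes the problem genuinely
  multivariate.
* **Concentrations**: calibration samples drawn uniformly from
  2,178–8,767 mg/kg (the blade calibration range); phantom defaults put
  veins at 11,000–13,000 and petioles at 13,000–15,000 mg/kg, above the
  calibration ceiling as in real leaves. The blade carries a ±15%
  centre-to-edge gradient (centres are enriched relative to edges), so
  "uniform" phantoms are uniform per tissue, not per pixel.
* **Noise level**: the defaults give a leave-one-out r² around 0.97 on
  210 samples. A study on real leaves reports much lower r² because
  biological matrix variation, instrument drift and reference-method
  error cannot be captured by a band-noise model; the synthetic figure
  is a ceiling that validates the machinery, not a claim about real
  tissue.
* **Geometry**: the leaf silhouette is procedural (superellipse blade,
  tapered petiole, midrib plus branching secondary veins) so the
  repository carries no image assets.

What passing the synthetic tests does **not** show: robustness to
instrument wavelength drift, temperature-dependent spectral shifts,
surface specularities, curvature/illumination geometry, or a real
nitrate signature overlapping water bands more severely than the
configured Gaussians. Those require real data.

## Storage physiology

`nitrate_content()` resolves `NC_s = NC_l · V_l / W_s` with explicit
units (mg/L × mL / g = mg/kg); the printed form of this relation is
unit-ambiguous, so the resolution is fixed and tested. RWC and RNC are
deliberately **not** clamped to [0, 1]: observation noise can push them
above baseline and clamping would hide it. `storage_series()` reports
mean ± se per (day, temperature) cell — multiple-comparison lettering
is out of scope. The storage generator decays RNC exponentially with
per-temperature rates (defaults 0.05/0.15/0.30/0.50 per day at
10/20/30/40 °C, mirroring faster enzymatic nitrate loss when warm) and
RWC slowly (0.01 per day) independent of temperature, emulating
saturated-humidity storage; day-0 expectations are 1 by construction.

## Numerical choices and degenerate inputs

* SNV refuses constant spectra by row number; cropping refuses empty
  band selections; the derivative refuses windows that do not fit.
* Reflectance with `W = B` gives `NA`, never Inf; all-`NA` images make
  destriping a warning no-op; empty segmentation masks warn.
* A constant response makes LOOCV r² `NA` (not 0, not 1) while RMSECV
  is honestly 0 when predictions equal the constant.
* ENVI I/O supports BSQ/BIL interleaves and float32/uint16 payloads
  with mandatory wavelength metadata; payload/header size mismatches
  are integrity errors, and float32 round-trips are exact only for
  values representable in single precision.
* Problem sizes in the shipped tests (64-band phantoms, 60–210-sample
  calibrations, 128 × 160 maps) were chosen so the whole suite runs in
  a few minutes on one CPU while still exercising every claim at
  realistic dimension ratios.

## Known limitations

* PLS extrapolation above the calibration ceiling is biased low; the
  package reports clipped counts and preserves ordering but cannot make
  extrapolated absolute values trustworthy.
* The notch destriper assumes stripes are near-constant along the scan
  axis; slowly drifting gain (non-stationary stripes) leaks outside the
  notch.
* The leaf mask is a single-band threshold; leaves lying over bright
  wet patches, or backgrounds spectrally similar to tissue at 1,450 nm,
  need a user-supplied mask.
* The synthetic generator is a mixture/scatter model, not radiative
  transfer; it cannot stand in for leaf-optics effects such as
  multiple scattering between cell layers.
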