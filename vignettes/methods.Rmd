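---
title: "Methods: hyperspectral prediction of apple aroma chemical groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral prediction of apple aroma chemical groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Apple aroma is carried by volatile compounds — mostly esters, alcohols,
aldehydes and ketones — that are conventionally measured by headspace
GC-MS, a destructive and slow assay. In breeding programmes with many
hybrid offspring, a non-destructive proxy is attractive: visible/NIR
hyperspectral images (here 462 bands, 400–1000 nm) of intact fruit,
calibrated against GC-MS group totals on a training set, then used to
predict aroma content of new fruit and to draw its spatial distribution on
the fruit surface.

`aromahsi` implements that pipeline end to end: reflectance calibration,
region-of-interest (ROI) spectra, spectral pre-treatments, outlier
screening, characteristic-wavelength selection, random-forest regression,
the standard chemometric report (Rc², RMSEC, Rv², RMSEP, RPD), and
pixel-/object-wise concentration maps. Because no public hyperspectral +
GC-MS apple dataset is available, a synthetic-data module generates the
whole study with known ground truth; all tests and the reproduction script
run on it.

## Reflectance calibration and the ROI

Raw counts are converted to relative reflectance with the two-point
correction

$$R = 10000 \cdot \frac{R_0 - D}{W - D},$$

where $D$ is a dark frame and $W$ a white reference, rounded
half-to-even to integers and clipped to $[0, 10000]$ (so 10000 is 100%
reflectance). The fruit is segmented from the black tray by Otsu's
threshold on per-pixel mean reflectance, keeping the largest connected
component.

Sample spectra come from a *moderate-reflection* ROI: fruit pixels are
ranked by brightness (mean reflectance over bands) and the central 15%
percentile band around the median is retained — this excludes both the
specular centre and the under-illuminated rim. The 15% is interpreted as a
fraction of *fruit* pixels (not of the whole image); ties at the percentile
cut are broken by pixel index (column-major, as R stores matrices) so the
retained count is exactly `round(0.15 * n)` and reproducible.

## Spectral pre-treatments

Three pre-treatments are compared against raw spectra:

* **SNV** (standard normal variate): each spectrum is centred and scaled to
  unit *population* standard deviation. SNV removes per-sample affine
  distortions exactly: `snv(a*x + b) == snv(x)` for `a > 0`. The
  population-sd convention is a config choice (`population = FALSE` gives
  the $n-1$ convention, differing by $\sqrt{n/(n-1)}$).
* **D1** (first derivative): a Savitzky–Golay-type derivative — at each
  wavelength a degree-2 polynomial is least-squares fitted over a 7-point
  window and its slope taken, in per-nm units. The local fit is computed
  from the actual wavelength grid, so non-uniform grids are handled and the
  edge columns use the truncated window rather than padding. The estimator
  is exact for polynomials up to the fit order (constants → 0, ramps →
  slope, quadratics → $2\lambda$), which the tests exploit; interior
  columns agree with `signal::sgolayfilt` on uniform grids.
* **SS** (column standardization): per-wavelength z-scoring with mean and
  population sd learned on the calibration set only, so no validation
  information leaks into the transform.

One consequence worth knowing: random forests are invariant to strictly
monotone per-feature transforms, so SS produces *identical* forests to raw
spectra. SS can matter for other regressors, but for this pipeline the
informative comparison is raw vs SNV vs D1 — consistent with scatter-prone
spectra benefiting from per-spectrum (not per-wavelength) correction.

## Outlier screening by Monte-Carlo cross-validation

Before calibration, anomalous samples (e.g. a GC-MS vial mismatched to its
image) are screened out: over many cycles (study setting 1000; tests use
200) a small forest is fitted on a random 80% subsample and absolute
residuals recorded on the held-out 20%. Each sample's mean held-out
residual is turned into a robust outlyingness score — its excess over the
median in MAD units — and samples above a cutoff are flagged.

Two design points:

* **Multi-target screening.** A sample carries one label per chemical
  group. Screening accepts a target matrix and flags a sample when its
  *worst* per-target score exceeds the cutoff: an apple whose spectrum
  contradicts any of its labels is suspect. Single-target screening is
  information-limited — a corrupted label can land near the value the
  spectrum implies for that one group while being wildly off in another.
* **Cutoff 6.** Absolute held-out residuals are strongly right-skewed
  (forest predictions compress towards the mean, so clean samples near the
  concentration range edges carry large residuals), and the max over four
  targets pushes the clean tail further out. Six MAD units above the median
  sits beyond the 99th percentile of clean samples in simulation, while
  genuine label anomalies score 8–15. A textbook 2.5–3 cutoff flags 5–25%
  of clean samples here and is not usable.

## Wavelength selection and the forest model

Samples are split 3:2 into calibration and validation sets. On the
calibration set, a grid search with 10-fold cross-validation chooses both
the forest hyperparameters (trees, depth; optionally mtry) and the number
of retained characteristic wavelengths `k`: per fold, a full-spectrum
forest is fitted and its impurity importances (normalised to sum 1) rank
the wavelengths; a forest restricted to the fold's top-`k` predicts the
held-out fold; the pooled CV RMSE scores the grid point, with ties broken
towards fewer wavelengths, then fewer trees, then shallower forests.

Retention is *peak-style*: wavelengths are accepted in decreasing
importance subject to a minimum separation (default 5 nm,
config-exposed). Neighbouring bands of a 1.3 nm grid are nearly collinear,
and a plain top-k spends its whole budget inside the single strongest
absorption region; with the separation constraint the selection spreads
over distinct importance peaks, which is what "characteristic wavelengths"
mean in practice. In simulation this raises the recovery of planted ester
band centres from 3/10 to 8/10 without hurting validation R².

The final model is a forest on the selected wavelengths; bundles serialize
to a JSON manifest plus the stored ensemble and reload with bit-identical
predictions.

## Evaluation metrics

`evaluate_model()` reports Rc²/RMSEC on calibration and Rv²/RMSEP/RPD on
validation. RPD is the *population* standard deviation of the validation
reference values over RMSEP; with these conventions the identity
$R_v^2 = 1 - 1/\mathrm{RPD}^2$ is exact, and the conventional reading
(<1.4 unreliable, 1.4–2 fairly reliable, >2 quantification-grade) is
attached to each report. Published chemometric tables do not always follow
a consistent RPD convention — RPD values near 1 alongside R² near 0.9 are
arithmetically impossible under any standard definition — so this package
states its convention and tests the identity rather than attempting to
match any particular printed table.

## The synthetic study

The generator emulates the study conditions rather than any instrument
physics:

* 160 apples, 462 bands over 400–1000 nm; group contents drawn uniformly
  within the study's reported per-group ranges (ester 1286.91–15432.56,
  aldehyde 173.85–12635.05, ketone 13.02–655.99, alcohol 33.77–1504.67,
  treated as ug/kg throughout).
* Reflectance is a smooth apple-like baseline (low in the chlorophyll-
  absorbing visible, bright NIR plateau) minus one Gaussian absorption band
  per characteristic wavelength per group, with depth linear in the group
  content (a Beer–Lambert-like link — the simplest invertible choice, so
  that recovery is well-posed). Ester and alcohol centres are the study's
  reported characteristic wavelengths; aldehyde/ketone lists were not
  printed in full, so representative sets keep their stated anchors
  (aldehyde's most informative band at 1000 nm, ketone partly beyond the
  visible). Band width is 8 nm and maximal per-band depth ~1200 reflectance
  units — narrow enough that the reported centres 8 nm apart stay distinct,
  deep enough that the signal dominates noise.
* Corruption is exactly the family SNV removes: per-sample lognormal
  multiplicative scatter (sdlog 0.10), a normal baseline offset (sd 150
  units) and white noise (sd 20 units). These magnitudes are chosen to make
  the spectra plausibly noisy (median between-sample relative spread ~12%
  raw) while keeping the planted signal recoverable — ordinary least
  squares at the exact band centres reaches R² ≥ 0.95, the oracle ceiling
  the pipeline is measured against.
* Cubes place a disk-shaped fruit on a near-black tray; each fruit pixel is
  the sample spectrum times a radial brightness profile (specular boost at
  the centre, falloff at the rim, normalised to unit disk mean so the
  fruit-average spectrum equals the sample spectrum), inverted through the
  calibration map to raw counts next to matching dark/white frames. An
  optional radial concentration gradient supports testing the orientation
  of pixel-wise maps.
* Label outliers are planted by re-drawing all four group labels of a
  random subset independently of the spectra — the corruption MCCV
  screening is expected to find.

What passing tests on this generator do *not* show: performance on real
fruit. Real peel optics, water/sugar absorption overlaps, instrument
stray light and GC-MS quantification error are all absent, and the
linear concentration→spectrum link is an idealisation. The tests
demonstrate that the pipeline recovers what was planted under the stated
noise model, not that the biological signal in real apples is this strong.

## Problem sizes and numerical choices

The test suite runs the study-scale configuration (n = 160, 462 bands)
where a property depends on it, with a reduced grid
({100, 300} trees × {unlimited, 10} depth × k ∈ {8, 10, 15}) and MCCV
scaled to 200 cycles; stochastic claims aggregate over 10 seeds and assert
a majority, so single unlucky draws do not flip them. Unit tests use a
40-sample, 80-band configuration. Degenerate inputs error early and
specifically: constant spectra in SNV (named sample), zero-variance columns
in SS (named wavelength), white ≤ dark at calibration (named pixel),
already-calibrated cubes, empty ROIs, unknown chemical classes and targets.
Reflectance is kept on the integer 0–10000 scale end to end; a synthetic
spectrum losing more than half its bands to the clip bounds is treated as a
configuration error ("absorption strength too large") rather than silently
saturating.
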