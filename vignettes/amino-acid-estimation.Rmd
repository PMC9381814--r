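---
title: "Estimating leaf amino acid contents from hyperspectral images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating leaf amino acid contents from hyperspectral images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Free amino acids in maize leaves respond strongly to nitrogen supply and
correlate with yield formation, but quantifying them requires destructive
LC-MS workflows. Hyperspectral imaging offers a non-destructive alternative:
pigment and biochemical composition modulate visible/near-infrared leaf
reflectance, so a calibration model can map a leaf's mean reflectance
spectrum (here 300 channels, 400-1000 nm, ~2 nm resolution) to the
concentrations of 24 amino acids (umol/L).

`aminospec` implements that calibration workflow end to end:

1. **Segmentation** — leaf pixels are separated from the background by
   NDVI = (r~NIR~ − r~red~)/(r~NIR~ + r~red~) > 0, using the channels
   nearest 780 and 660 nm, and the mean spectrum over leaf pixels becomes
   the sample's predictor vector.
2. **Preprocessing** — Savitzky-Golay smoothing of the spectra;
   z-score standardization of each analyte (concentrations span two orders
   of magnitude across the panel).
3. **Regression** — univariate NIPALS partial least squares regression
   (PLSR), with the component count chosen per training set by
   leave-one-out PRESS.
4. **Band screening** — a two-stage reduction: first the wavelength axis is
   partitioned at 717.08 nm by the per-band coefficient of variation
   (CV = SD/mean × 100) of reflectance across samples; then, within the
   variable (visible) range, bands are eliminated backward in order of
   increasing |regression coefficient|, the PRESS-minimal subset of each
   resampled repetition is recorded, and bands surviving more than 80 of
   100 repetitions are declared *sensitive* for that analyte.
5. **Evaluation** — repeated 70/30 holdout (203/87 of 290 samples, 100
   repetitions), reporting the test-set averages of R², RMSE (umol/L),
   relative error RE = RMSE/ȳ × 100 and RPD = SD/RMSE, for four band-set
   variants (all bands, low range, high range, sensitive bands), and the
   per-analyte optimum.

## Model and estimator choices

**NIPALS, not SIMPLS.** Components are extracted by the classic
weight/score/loading recursion with deflation; for a univariate response the
two algorithms give the same predictions, which keeps an independent
cross-check simple. Predictors are mean-centered but *not* variance-scaled:
all bands share reflectance units, and scaling would inflate the noise-only
NIR plateau. Only the response is z-scored (sample SD, n−1 convention —
the same convention as the panel's published descriptive statistics).

**Honest cross-validation.** The leave-one-out PRESS refits the model on
every fold rather than using shortcut formulas; the compiled kernel merely
accelerates the same arithmetic, and the test suite pins it against a
brute-force loop of independent fit/predict calls. Within every holdout
repetition the component count is re-selected on that repetition's training
set (capped at A ≤ min(15, n~train~ − 2, bands); 15 covers common
chemometric practice), and the response standardizer is refit on the
training portion only, so no information leaks from the test set.

**Metrics in concentration units.** Test predictions are mapped back to
umol/L with the training standardizer before computing metrics, because
RMSE, RE and RPD are only interpretable in concentration units. The mean
and SD entering RE and RPD are those of the evaluated (test) samples: the
published RPD values are inconsistent with a whole-dataset SD, which rules
out that alternative. PRESS ties during component selection break toward
the smaller count (parsimony); PRESS ties along an elimination trace break
toward the larger band subset.

**Elimination order.** The backward elimination sorts bands once, by the
absolute coefficients of the full-subset model, and removes them in that
fixed order, re-selecting the component count and recording the LOO PRESS
after every removal down to a floor of 2 bands (a coefficient ordering
needs at least two competitors). A `mode = "dynamic"` variant that re-ranks
after every removal is available but not the default. Each of the voting
repetitions draws a fresh 70/30 resample from a seed-derived child stream.
"Sensitive" is a strict majority: `count > threshold`, so a threshold equal
to the repetition count can never be met.

## The synthetic study generator

No leaf-level spectral archive accompanies the emulated study, so the
package ships a generator that reproduces its statistical structure with a
known ground truth; every downstream stage is tested against that truth.

**Concentrations.** Each analyte is drawn log-normal, moment-matched to the
published per-analyte mean and SD of the 290-sample panel
(`sdlog² = log(1 + CV²)`), and truncated below at a configurable floor.
Log-normality is structural: the published panels are strictly positive and
strongly right-skewed (max ≫ mean, CV up to 159%). Draws use stratified
uniforms pushed through the quantile function (one draw per
equal-probability stratum, in random order): the marginals are exactly the
intended log-normals, but sample moments converge far more quickly, which
keeps the generator calibrated even for the heavy-tailed high-CV analytes
at study-sized n.

**Spectra.** A parametric green-leaf baseline (visible floor with a green
peak at 550 nm, logistic red edge at 718 nm, NIR plateau at 0.48
reflectance) minus Gaussian absorption features whose depths follow the
standardized concentrations through a coupling matrix:
`depth = depth_scale · tanh(Z·C / squash)`. The tanh bounds depths at
`depth_scale` (0.04), so spectra never clip, while remaining strictly
monotone in every coupled concentration. Standardizing the concentrations
first lets one coupling matrix serve analytes whose scales differ by two
orders of magnitude. Additive band noise (SD 0.002) and a per-sample
multiplicative gain (SD 0.005) model sensor noise and residual illumination
error; the gain is kept sub-percent, as expected after white-reference
calibration with a stabilized lamp — a larger gain would make baseline-only
bands informative as illumination references, which is not the
signal-recovery behavior the screening stage is meant to exhibit.

**Where the signal lives.** The 14 feature centers sit inside the two
windows where the emulated study located its sensitive bands
(505.39-604.95 and 651.21-714.10 nm), with widths (sigma 5 nm) on the order
of the instrument resolution so each feature maps to an identifiable
channel even on the reduced test grid. The five analytes whose published
models are most accurate (BABA, Orn, Cit, Met, His) each own an *exclusive*
pair of features, one per window, with strong loadings; the other nineteen
analytes share a pool of four features with strictly decreasing loadings,
assigned greedily so per-feature interference stays balanced. This design
follows from a variance-budget argument: with F shared latent features the
summed linear R² across analytes cannot exceed F, so strongly recoverable
analytes must not share their features with the rest of the panel. It gives
the generator two properties the tests rely on: a strongly coupled
analyte is recoverable with R² > 0.9 at low noise, and estimation accuracy
is a monotone function of an analyte's own coupling strength (row norm),
which the evaluation harness checks as a rank correlation.

**Images.** Per-sample cubes place the leaf spectrum on an elliptical
region over a background whose reflectance decreases strictly with
wavelength, so background NDVI is negative *deterministically* and the
NDVI > 0 threshold recovers the true mask exactly in the noise-free case —
no flakiness at the threshold boundary. Dark pixels (zero denominator) are
defined as background.

**What the generator does not emulate.** No radiative-transfer realism
(no PROSPECT-style leaf optics), no genotype or nitrogen-treatment effects
(the two experiments differ only by a metadata label, as the emulated study
pools them for modeling), no temporal dynamics, and absolute reflectance
levels are unconstrained by data. Passing tests therefore demonstrate that
the *algorithms* recover planted structure under realistic noise — not that
real maize leaves meet these models.

## Numerical conventions and degenerate inputs

* Savitzky-Golay defaults to window 11 / order 2 (a common chemometric
  choice at ~2 nm resolution; neither value is prescribed by the emulated
  study) with polynomial edge handling, so the band axis is never
  shortened and band indices stay aligned with wavelengths. On the reduced
  60-band desk grid the analysis scripts narrow the window to 5 channels —
  an 11-channel window there would span ~110 nm and smear real features —
  and the recovery checks run unsmoothed, since the planted features are
  only a few channels wide at that resolution.
* NDVI uses nearest-channel lookup (the 2.1 nm grid has no exact 780/660 nm
  channel) and warns if a requested wavelength falls outside the grid.
  Segmentation is strict (`NDVI > 0`); ties are background.
* Zero-variance responses, empty masks, headers without wavelengths,
  component counts beyond `min(n − 1, b)`, and fully clipped optics raise
  labeled errors rather than propagating NaNs.
* NIPALS stops extracting when the deflated score norm collapses
  (relative tolerance 1e-12); leave-one-out folds cap the component count
  at `min(n − 2, b)` so every fold stays estimable.
* All randomness flows from one master seed through fixed-stage child
  seeds, so changing, say, the number of evaluation repetitions never
  perturbs the generator draws; identical configurations give bit-identical
  outputs, including byte-identical CSV reports.

## Problem sizes used by tests and scripts

The shipped checks run the full 290-sample study on a 60-band grid
(10.2 nm spacing), vote over R = 20 repetitions with a proportional > 16
threshold, and evaluate with R = 10 holdout repetitions; the full-scale
protocol (300 bands, R = 100, > 80) is identical code with different
configuration values, and the backward elimination cost scales linearly in
the band count (one LOO profile per removed band). These sizes were chosen
so the complete workflow — including the combinatorial voting stage —
remains a minutes-scale desk computation while leaving every algorithmic
path exercised at full sample size.

## Known limitations

* The two-stage screening inherits the instability of coefficient-based
  rankings under collinearity; the frequency vote mitigates but does not
  remove it (that is its purpose in the original design).
* PRESS-based component selection with a noiseless response keeps
  improving with more components; the selector is only meaningful when the
  response carries noise, which all realistic configurations do.
* The emulated study's headline accuracies for real leaves are not
  reproducible without its raw data; the package's claims are limited to
  internal consistency (printed statistics, split arithmetic, metric
  identities) and parameter recovery on the synthetic ground truth.
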