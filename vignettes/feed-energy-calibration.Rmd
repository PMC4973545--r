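---
title: "Calibrating feed energy from NIR spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating feed energy from NIR spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Formulating swine diets requires the digestible energy (DE) and metabolizable
energy (ME) content of each ingredient, but direct determination needs a
digestion-metabolism trial: pigs housed in metabolism cages, total collection
of feces and urine, bomb calorimetry of feed and excreta. Near-infrared
reflectance spectroscopy (NIRS) offers a rapid alternative: ground corn is
scanned in diffuse reflectance from 400 to 2498 nm at 2 nm steps, absorbance
recorded as log(1/R), and a multivariate calibration maps the spectrum to the
energy value. `feednirs` implements that calibration workflow end to end —
spectral pre-treatment, modified partial least squares (MPLS) regression,
cross-validated factor selection, outlier elimination, grid search over
pre-treatments, and the evaluation statistics used to judge the result — plus
the Noblet–Perez composition equations that provide calculated reference
energies, and a synthetic corn generator so the whole pipeline is testable
without proprietary spectra.

## Spectral pre-treatments

Raw feed spectra carry broad peaks, baseline shifts, and parallel offsets
caused by light scattering from particles. Two families of corrections are
composed:

* **Scatter corrections.** `SNV` z-scores each spectrum (row mean 0, sample
  SD 1); `Detrend` removes each spectrum's least-squares quadratic in
  wavelength; `SNVD` chains the two. The multiplicative family regresses each
  spectrum against a reference mean spectrum learned from the calibration
  set: `SMSC` returns `(x − a)/b` from `x = a + b·m`; `WMSC` uses
  per-wavelength weights proportional to the inverse calibration variance in
  that regression; `IMSC` regresses the reference on the spectrum and returns
  the fitted values. `None` is the identity.
* **Gap–segment derivatives**, coded `"d,g,s1,s2"`: a centred moving average
  of `s1` points, a difference across a gap of `g` points (first derivative
  `x(i+g) − x(i−g)`; second `x(i−g) − 2x(i) + x(i+g)`), then a second
  smoothing of `s2` points. Differences are left unnormalised by the gap
  width — after mean-centring, only relative scale reaches the regression.

The search grid couples the 7 scatter methods with 11 derivative codes
(`0,0,1,1` through `2,16,16,1`), 77 pre-treatments in all.

Design choices made where practice varies:

* **Order of composition**: scatter correction before the derivative, the
  common SNV-then-derivative convention; a flag on `pretreatment()` reverses
  it.
* **Units of the code numbers**: all four are data points (2 nm per point on
  the default grid).
* **Edges**: windows that do not fit are truncated, never padded, and the
  retained wavelength grid travels with the data.
* **Second smoothing** is applied after the gap difference; every code in
  the default grid has `s2 = 1`, so the default results are insensitive to
  this.
* The exact weighted/inverse MSC formulas used by commercial packages are
  proprietary; the regressions above are this package's documented contract.

## MPLS regression

The regression core is PLS1 by sequential NIPALS factor extraction on
centred data. The *modified* PLS variant follows the published
Shenk–Westerhaus description: after each factor is extracted and deflated,
the X-residual columns and the y-residuals are divided by their current
standard deviations (denominator n − 1; columns with SD below 1e−12 are left
unscaled) before the next factor is sought. Every scaling vector is stored,
so prediction replays exactly the centring–projection–deflation–scaling
chain of the fit; the chain is affine in the input spectrum and
`mpls_coef()` collapses it to an intercept plus coefficient vector. With
`standardize_residuals = FALSE` the fit reduces to plain NIPALS PLS1 — kept
as a cross-check mode, and verified in the tests against an independent
Krylov-subspace (Helland) closed form to 1e−8. The commercial MPLS
implementation is closed source; the residual-standardisation rule here is
declared as this package's contract and labelled as such.

The factor search is capped at `min(15, n/6)` by default, which brackets the
10–13 factors typical of feed-energy calibrations at n ≈ 88.

## Factor selection, outliers, and the grid search

`cross_validate()` partitions the calibration set into 6 seeded random
groups of near-equal size (the grouping method is otherwise free), pools
held-out residuals over groups, and reports
`SECV(p) = sqrt(sum(e²)/n)` for every factor count; the optimum is the SECV
minimum, ties resolved toward fewer factors. Data-dependent pre-treatment
parts — MSC reference spectra and WMSC weights — are refitted inside every
training fold, so no information about held-out samples leaks through the
scatter correction.

Outlier elimination runs at most two passes. In each pass the fitted model
flags **H outliers** — global H, the squared Mahalanobis distance of a
sample in the p-dimensional score space divided by p (so the calibration
mean is ≈ 1), at GH ≥ 10 — and **T outliers**, reference-versus-predicted
residuals exceeding 2.5 SEC in absolute value (strict inequality). Flagged
samples are removed jointly, and cross-validation is re-run from scratch on
the survivors. A run that would discard more than half the calibration set
aborts with a diagnostic instead.

`grid_search()` calibrates every pre-treatment in the grid with the same
seed (hence the same cross-validation partition), and ranks by SECV
ascending, ties broken by higher cross-validation R² and then fewer factors.
`validate()` applies the winner's stored pre-treatment and model — no
refitting — to held-out samples.

## Evaluation statistics

All statistics follow the conventions of the feed-NIRS literature:

* `SEC = sqrt(sum(e²)/(n − p − 1))` on training residuals;
* `SECV` and `SEP` are uncorrected root-mean-squares of held-out residuals
  (no bias correction — this is the convention under which published
  SD/SEP ratios reproduce the printed RPDs);
* `RSQ_cal = 1 − SSE/SST`; cross-validation and validation R² are squared
  Pearson correlations;
* `RPD = SD/SECV` (cross-validation) or `SD/SEP` (validation), with 2.5 the
  customary threshold for routine quantitative use;
* `SEL = sqrt(sum((a−b)²)/2m)` over m laboratory duplicate pairs, and
  `RSEL = SEL/mean × 100`.

Ratios are conventionally reported to 2 decimals and standard errors to 3.

## The energy equations

The Noblet–Perez equations predict pig DE and ME of a feed from proximate
composition in g/kg DM:

```
DE (MJ/kg) = (4168 − 9.1·Ash + 1.9·CP + 3.9·EE − 3.6·NDF) × 4.18/1000
ME (MJ/kg) = DE × (1.003 − 0.00021·CP)
```

The kcal-to-MJ factor is 4.18/1000 exactly as published (not 4.184).
Composition tables are usually printed in % DM; the conversion is ×10 and
`add_calculated_energy()` performs it. Note the ME multiplier exceeds 1 when
CP < 14.29 g/kg — the formula's own behaviour, allowed with a warning.
`direct_method()` implements the balance-trial accounting: DE of the diet is
(GE intake − fecal GE)/intake, ME further subtracts urinary GE, and
ingredient values divide by the inclusion rate (default 0.968, a corn-only
test diet).

## The synthetic corn generator

No public corn NIRS dataset with pig DE/ME references exists, so
`sim_config()`/`make_dataset()` generate one with known structure. What it
emulates, and the choices behind the defaults:

* **Composition** (% DM) is drawn from a truncated multivariate normal over
  the ranges of a real 117-sample Chinese corn collection (CP 7.80–11.00,
  NDF 6.40–19.37, ...). Because those ranges sit at only 1.5–2.5 SD, clipping
  shrinks the spread, so pre-truncation SDs carry fixed inflation factors
  calibrated once (by fixed-point iteration at large n) to make the
  *post*-truncation sample SDs land on the published ones. The correlation
  structure links the fibre fractions positively with ash and negatively
  with oil and protein — bran-rich versus starchy kernels — which also
  reproduces the published spread of calculated energy (the printed
  calculated-DE SD sits essentially at the perfectly-correlated limit of the
  component contributions, so the default correlations approach the feasible
  ceiling).
* **Energies**: calculated DE/ME are the exact equation outputs, so the
  generator and the energy module agree by construction. Determined DE/ME
  add independent Gaussian lab noise, SD 0.22 MJ/kg, chosen so the
  signal-SD-to-noise ratio sits in the 2.5–2.9 band that the published
  SD/SECV ratios imply for digestion-trial references. Determined ME is
  clamped to at most determined DE to respect the energy balance.
* **Spectra**: each sample's noiseless spectrum is a fixed smooth corn
  background plus 2–4 Gaussian absorption bands per constituent in the
  1100–2400 nm overtone/combination region, scaled by concentration. The
  band library is an invented fixture, not a claim about real corn band
  assignments; amplitudes are set so constituent-driven band-depth variation
  is of order 0.01 absorbance, comparable to real feed spectra. Each scan
  (two per sample) is then degraded by a wavelength-dependent multiplicative
  scatter factor (log-space offset, tilt and curvature), an additive offset
  and tilt, and white noise of SD 5e−5 — the level of a scanning
  monochromator averaging 32 scans.

What the generator does *not* emulate: real corn band assignments and their
overlaps, instrument line-shape and wavelength error, moisture–starch
interaction effects, and reference errors correlated across samples (trial
effects). Passing the end-to-end tests therefore demonstrates that the
pipeline recovers known structure under realistic noise — not that it would
achieve any particular accuracy on real corn.

### Test-bed for outlier recovery

The implant-and-recover experiment (two gross outliers planted in an
88-sample set, both recovered leaving n = 86) uses a reference built from
the calculated energy plus *bounded* uniform error (±0.5 MJ/kg) rather than
Gaussian noise. The T rule is scale-free: with unbounded Gaussian reference
error, about one honest sample per 88 exceeds T = 2.5 at any noise level, so
"exactly the implants are removed" would be unattainable by construction —
published calibrations likewise drop one to three real samples. The bounded
error keeps natural |T| below ≈ 1.9 and isolates the recovery machinery,
which is what that experiment is meant to test. The default generator keeps
Gaussian lab noise.

## Problem sizes and numerical choices

The test suite runs the full pipeline at the study geometry (117 samples,
88/29 split, duplicate scans, 1050 wavelengths) and uses a reduced 20-cell
grid (4 scatter methods × 5 codes spanning the raw, first- and
second-derivative families) for repeated end-to-end runs; unit tests use toy
grids of 25–90 points. Degenerate inputs fail loudly: constant rows under
SNV, near-zero MSC slopes (|b| < 1e−12), zero-variance responses, factor
counts at or above n − 1, and wavelength-grid mismatches between a model and
new spectra. A near-singular score covariance in the global-H computation is
ridge-stabilised with a warning. All randomness — splits, cross-validation
partitions, the generator — flows through explicit seeds, and seeded runs
are byte-reproducible.

## Known limitations

* The MPLS residual-scaling rule is a published description of a closed
  implementation; other implementations may scale different moments.
* SEP is reported without bias decomposition; the bias itself is reported
  alongside.
* The grid search re-uses one cross-validation partition across
  pre-treatments. That makes the comparison paired (good) but means the
  winner's SECV is an optimistic estimate of its own performance; the
  validation set exists to price that in.
* Wavelength selection, repeatability-file corrections, and calibration
  transfer between instruments are out of scope.
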