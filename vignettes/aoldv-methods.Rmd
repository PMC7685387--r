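---
title: "aoldv: methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{aoldv: methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aoldv)
```

# Overview

`aoldv` implements the computational pipeline of an adaptive-optics
bidirectional laser Doppler velocimeter (LDV) for absolute retinal blood
flow, together with a physics-grounded simulator so that every stage can be
validated against ground truth without the instrument. The measurement chain
is:

1. **Doppler spectra** — 30 ms two-channel detector records at 120 kHz are
   turned into one-sided power spectra (`computePowerSpectrum()`).
2. **Cutoff frequency** — the maximum Doppler shift of each channel is
   estimated from the normalized cumulative spectrum by a two-line
   intersection (`detectCutoff()`).
3. **Absolute velocity** — the cutoff difference of the two channels gives
   the centerline red-blood-cell velocity,
   `vmax = lambda * |fA - fB| / (n * alpha * cos(beta))` with
   `alpha = arctan(x / L)` (`computeVmax()`).
4. **Vessel diameter** — 16-bit adaptive-optics fundus frames are analyzed
   around the probing-beam spot: ROI extraction, background flattening,
   template-based orientation, perpendicular profiles, per-profile edge
   widths, outlier rejection, and a pixel-to-micrometer calibration
   (`measureDiameter()`).
5. **Flow** — Poiseuille flow `F = pi (d/2)^2 vmax / 2`, aggregated over an
   acquisition, and checked for conservation at venous bifurcations
   (`computeFlow()`, `measureBifurcation()`).

# The velocity model

For laminar Poiseuille flow with uniformly distributed scatterers, the
Doppler power spectrum is a flat step up to the shift produced by the fastest
cells on the vessel axis. The two detection channels see cutoffs separated by
`deltaF`, and only this difference enters the velocity, which removes the
unknown incidence geometry:

```{r velocity}
cfg <- OpticalConfig()
v <- computeVmax(3000, cfg)
1e3 * vmax(v)  # mm/s
```

Two analytic sensitivities are exposed because they quantify the dominant
systematic errors:

* `betaErrorFactor(betaDeg)` — ignoring a tilt `beta` between the velocity
  vector and the scattering plane inflates velocity by `1/cos(beta) - 1`
  (1.5% at 10 degrees).
* `axialLengthSensitivity(config, deltaL)` — using an assumed axial eye
  length `L` in `alpha = arctan(x/L)` changes the computed flow by about 4%
  per millimeter of error at `L = 23.95` mm.

```{r sensitivities}
round(100 * betaErrorFactor(10), 1)
round(100 * axialLengthSensitivity(cfg, 1), 2)
```

# Cutoff detection

`cumulativeRc()` is the normalized cumulative spectrum: linear in the
step band, flat above it. `detectCutoff()` fits the plateau line over the
last third of the bins, finds the largest bin at least 10% below that line
(`kx`), fits the rise line over bins `1..kx`, and intersects the two lines.
On noise-free steps the estimate is exact:

```{r cutoff}
sp <- simulateStepSpectrum(100 * 100 / 3, nBins = 300L, snr = Inf)
detectCutoff(sp)
```

The printed normalization of the cumulative statistic in the source material
is garbled; `rc` is normalized to end at 1, which cannot affect the
intersection abscissa (it is invariant to any positive rescaling of the
spectrum).

## Speckle statistics and acquisition averaging

A single 30 ms periodogram of the tone-sum signal has exponentially
distributed bins (unaveraged periodogram statistics), so per-frame cutoff
estimates scatter by several bins *regardless of detector signal-to-noise
ratio*. The instrument's remedy is acquisition averaging: 40 spectrum pairs
are recorded per measurement. `simulateStepSpectrum()` exposes both regimes
through `noiseModel = "speckle"` (raw single window) and `"gaussian"`
(averaged/smoothed regime), and the recovery guarantees in the test suite
are stated for acquisition-averaged spectra, where the cutoff lands within
3 bins of truth in well over 95% of replicates at SNR 20. The in-silico
linearity experiment (`runLinearityExperiment()`) likewise averages the
per-frame cutoff differences over `framesPerLevel` spectrum pairs per pump
setting.

## Estimator bias under centre-weighted illumination

With a narrow Gaussian beam (`beamWidthRatio` well below 1) the spectrum is
enhanced near the cutoff, the cumulative statistic becomes convex, and the
two-line intersection overshoots the true cutoff by 15–18% per channel;
the measured-vs-imposed flow slope then sits near 1.2 (the instrument's own
in-vitro validation shows the same over-read direction, slope 1.09). The
bias is nearly proportional, so the linearity figure of merit r² is
insensitive to it. In the uniform/weak-weighting limit the estimator is
unbiased to about 2%, which is where the noise-free closure property
(slope within 1 ± 0.02) is tested.

# Vessel diameter

The image pipeline composes:

1. `detectSpot()` — threshold at 80% of the frame maximum, keep the largest
   **8-connected** component (implemented in-package; the available
   `EBImage::bwlabel` is 4-connected), intensity-weighted centroid.
2. `extractRoi()` — 360 x 360 window on the centroid, shifted inward at
   borders.
3. `flattenBackground()` — least-squares second-order polynomial surface,
   subtracted.
4. `estimateOrientation()` — normalized cross-correlation against dark-bar
   templates on a 15 degree grid with a perpendicular offset search, then a
   centerline refinement: the fixed-width template only localizes *a bar
   position* (for vessels wider than the template the correlation is
   plateau-flat), so the centerline is re-centered on the trough midpoint of
   the mean perpendicular profile, with pixels within 40 px of the spot
   centroid excluded (the beam spot is a known instrument landmark of about
   31 px FWHM).
5. `extractProfiles()` — bilinear profiles perpendicular to the centerline,
   one every 2 px.
6. `measureEdgeDistance()` — per-profile width; see below.
7. `rejectAberrant()` — single-pass mean ± 3 sd rejection.
8. `pixelsToUm()` — `d = n * 19.269 * (L - 1.82) / 373.87` micrometers with
   the examined eye's axial length `L` in mm.

```{r diameter}
img <- simulateFundusImage(ImageScenario(diameterPx = 73, orientationDeg = 30,
                                         noiseSigma = 400,
                                         nrow = 440L, ncol = 440L, seed = 1L))
measureDiameter(img)
```

## Edge criterion: half-depth vs maximum gradient

`measureEdgeDistance()` supports two criteria. *Half-depth* measures the
distance between the two crossings of `baseline - depth/2` nearest the
trough minimum; the baseline is the 80th percentile of the profile rather
than the median, because troughs wider than 90 px occupy more than half of a
180 px profile and would swallow the median. *Maximum gradient* measures the
distance between the steepest descent and the steepest ascent of the lightly
smoothed profile (sub-pixel by parabolic interpolation).

The pipeline default is `edgeMethod = "max_gradient"`: the second-order
background fit is computed over *all* ROI pixels, including the vessel, so
part of a wide trough leaks into the fitted surface (a 120 px vessel's
residual trough loses more than half its depth and acquires compensating
side lobes). Half-depth widths inherit a pixel-scale bias from that
distortion, while the gradient extrema — the wall inflection points — are
invariant to smooth additive background and to depth rescaling. Both
criteria are exported and tested; per-profile half-depth examples follow the
half-depth definition.

## Profile usability rules

Two per-profile conditions return `NA` (the non-fatal exclusion path):
a trough depth below 6 times the first-difference noise scale, and a bright
peak exceeding the baseline by more than half the trough depth. The latter
marks profiles crossing the probing-beam spot, which violate the
single-dominant-trough assumption and would otherwise bias the width; the
mean ± 3 sd pass cannot flag them because they sit within 3 sd.

A property of the 3 sd rule worth recording: for a single outlier among `n`
values the maximum attainable z-score is `(n - 1)/sqrt(n)`, which is below 3
for all `n <= 10` — no single aberrant width among ten or fewer profiles can
ever be flagged. The rejection pass earns its keep at realistic profile
counts (a 360 px ROI yields up to 180 profiles).

# Synthetic generators

All generators draw from one integer seed through deterministic substream
derivation and restore the global RNG state afterwards; outputs are
bit-reproducible.

* `simulateDetectorRecord()` — sums `nTones` random-phase tones with
  frequencies uniform on `[0, fCut]` (the frequency law of Poiseuille flow
  with uniform scatterers), plus white noise at the prescribed SNR. Channel
  cutoffs are `fBase` and `fBase + deltaF` with `deltaF` derived from the
  true velocity. The hot loop is a small C++ phase-rotation recurrence.
* `simulateCapillarySpectrum()` — tone powers weighted by a Gaussian beam
  across the capillary (scatterers near the axis enhanced); amplitudes are
  renormalized so expected total power is independent of the true velocity.
  The spectrum-area constancy is exact in expectation; single frames scatter
  by ~17% (speckle over few effective bins), so the constancy property is
  tested on multi-frame means.
* `simulateFundusImage()` — 16-bit phantom: background, second-order
  illumination, Gaussian beam spot, and a vessel band rendered as a
  flat-bottomed trough with Gaussian-smoothed walls whose FWHM equals the
  nominal diameter. (A pure Gaussian cross-section of FWHM above ~60 px
  would leave no baseline anywhere on a 180 px profile, defeating any
  baseline-referenced edge criterion; real lumen absorption is
  flat-bottomed.)
* `conservedBifurcationScenario()` / `simulateBifurcation()` — a parent and
  two daughter vessels with daughter velocities solved so the flows close
  exactly; full paired image + record acquisitions per vessel.

```{r scenario}
sc <- conservedBifurcationScenario()
computeFlow(sc@parentDiameterUm, sc@parentVmaxMmS) -
  sum(computeFlow(sc@daughterDiametersUm, sc@daughterVmaxMmS))
```

# Flow conventions and the bifurcation check

`computeFlow()` defaults to the Poiseuille convention
`F = pi (d/2)^2 vmax / 2` (mean velocity is half the centerline velocity).
The `"cross_section"` convention drops the 1/2; it is the relation the
in-vitro capillary validation follows (plug-like tracer seeding) and is used
by `runLinearityExperiment()`. Flows are reported in uL/min
(1 m^3/s = 6e10 uL/min).

At a bifurcation, `bifurcationConservation()` evaluates
`deltaF = F_PV - (F_DV1 + F_DV2)` and its percentage of the parent flow. The
shipped reference table (`retinalBifurcationTable()`) retains the printed
per-subject relative errors, which follow the opposite sign convention from
the formula above; both are kept, clearly labelled.

```{r conservation}
conservationSummary(retinalBifurcationTable()$deltaFRelPrintedPct)
```

# Problem sizes in the validation suite

The test suite states its guarantees at sizes chosen to fit a desk-scale
time budget; these are package choices, the generator physics is unchanged:

* diameter recovery: 50 phantom seeds, widths cycled over 40–120 px, all 24
  template angles, 440 x 440 frames, vessel contrast-to-noise 20 (defined as
  trough depth over noise sd, since image SNR is otherwise unspecified);
* end-to-end conservation: 50 bifurcation seeds at 8 frames per acquisition
  on 440 x 440 frames;
* linearity: 10 pump levels over 1.75–25.9 uL/min; the acceptance runs
  average two full 40-pair acquisitions per level, sized so the r²
  criterion holds with margin for an arbitrary seed (per-level variance
  scales as 1/K);
* spectrum-area constancy: means over 300 frames; the uniform-vs-centered
  cutoff comparison is stated at `beamWidthRatio = 2`, where the documented
  estimator bias stays within 2 bins.
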