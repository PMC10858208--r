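---
title: "Models and methods behind doct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind doct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`doct` turns repeated-frame OCT time series of tumor spheroids into two
per-voxel dynamics contrasts — the logarithmic intensity variance (LIV) and
the late OCT correlation decay speed (OCDS_l) — and into study-level
quantities: spheroid volume, mean dynamics, dead-cell ratios and Welch
day-pair comparisons. This vignette explains the underlying models, the
estimator properties that drove the design, the tunable parameters, and
what the synthetic phantom does and does not establish about real data.

## Acquisition model

A volume is acquired as a block-repeat raster (`scan_protocol()`): the
lateral field of view is split into `n_blocks` blocks of
`locations_per_block` B-scan locations; each block's raster is repeated
`n_repeats` times, so each location carries `n_repeats` frames spaced
`frame_interval` ms apart. Defaults are 8 × 16 × 32 at 204.8 ms over
1 × 1 mm — 128 B-scan locations, 4096 frames, a 6348.8 ms per-location
span. All frames of one raster pass share the pass's nominal timestamp:
the dynamics contrasts only use the per-location uniform spacing, which
this convention preserves exactly. Inter-block flyback is not modelled, so
schedule timestamps are arithmetic, not wall-clock.

Axis order is `[location (slow), depth, lateral]` with 0-based file names
and 1-based R indices; depth grows away from the lens, and the well-plate
reflection is a bright static plane below the spheroid.

## Speckle model and its oracles

Each voxel's complex field is a static-plus-dynamic circular Gaussian
mixture

    E(t) = sqrt(1 - m) E_s + sqrt(m) E_d(t),

where `m` in [0, 1] is the motility fraction (fraction of field power that
fluctuates) and `E_d` is a stationary Ornstein–Uhlenbeck process with
field correlation `exp(-|dt|/tau_c)`. The discrete recursion
`E_d(t+D) = a E_d(t) + sqrt(1-a^2) w`, `a = exp(-D/tau_c)`, is exact at
any sampling interval. Fields are low-pass filtered with the Gaussian PSF
(FWHM 18.1 µm lateral, 14 µm axial; `sigma = FWHM / (2 sqrt(2 ln 2))`;
kernel L2-normalised so white-noise variance is preserved), intensity is
`|E|^2` scaled by the region reflectivity, and an independent
exponential-intensity background (`noise_floor`) is added. Speckle is
generated per voxel post-PSF rather than by ray-tracing scatterers: the
analysis depends only on the field's spatio-temporal correlation, and this
construction yields closed-form oracles.

For circular Gaussian fields the Siegert relation gives the intensity
Pearson correlation

    rho(tau) = ((1 - m) + m exp(-tau / tau_c))^2,

implemented in `analytic_intensity_correlation()`. For fully developed
speckle (`m = 1`) the correlation of the *log*-scaled intensity also has a
closed form, `corr(ln I_1, ln I_2) = Li2(rho) / (pi^2/6)` with `Li2` the
dilogarithm — the exact size of the dB-versus-linear domain bias, exposed
via `domain = "log_intensity"`. Likewise the temporal variance of
`10 log10 I` for exponential `I` is `(10/ln 10)^2 pi^2/6 ≈ 31.02 dB²`,
which fixes the expected LIV of fast i.i.d. speckle (times `(N-1)/N` for
the divisor-`N` variance).

## The estimators, and two biases that matter

`compute_liv()` is the temporal variance of the dB-scaled signal (divisor
`N` by default, configurable to `N-1`). `compute_autocorrelation()` is the
per-voxel sample Pearson autocorrelation: full-series mean subtraction,
full-series variance normalisation (so `rho(0) = 1` by construction), and
lag-`k` products averaged over the `N-k` available pairs.
`compute_ocds()` fits an OLS slope to `rho(tau)` over the lags inside the
late window `[204.8, 1228.8]` ms — exactly lags 1..6 at 204.8 ms sampling,
asserted by the window-selection code — and reports the negated slope, so
that a faster decay is a larger, positive decay speed, consistent with a
positive dead-cell cut-off. Static voxels (numerically zero temporal
variance) are flagged, given the non-decaying `rho = 1`, and thus
`OCDS_l = 0`; negative values at noisy voxels are not clamped.

Two estimator properties shaped the package and deserve to be explicit.

**Domain bias.** The autocorrelation operates on the dB-scaled signal by
default (consistent with LIV); the Siegert oracle applies exactly to
linear intensity. The dilogarithm result above bounds the difference; for
oracle comparisons `correlation_domain = "linear"` is provided and used.

**Finite-window bias.** With only 32 frames, the per-voxel estimator
subtracts a temporal mean that soaks up fluctuations slower than the
6.35 s observation window. The consequence is large: for `m = 1` the
per-voxel `rho` can sit ~0.3–0.5 below the true curve at
`tau_c = 3200 ms`, and the region-mean per-voxel OCDS_l *increases* with
`tau_c` over most of the practically relevant range — slow-but-moving
tissue reads as fast. The pooled ensemble estimator
(`pooled_autocorrelation()`, which normalises by the grand mean and
variance over a homogeneous voxel population) is consistent as the pool
grows and matches the Siegert curve to < 0.01 at 10^4+ voxels; it is the
right empirical counterpart of the analytic oracle, and it is what the
oracle and parameter-ordering tests use. Even for the *exact* Siegert
curve the late-window OLS slope is non-monotone in `1/tau_c`: it peaks
near `tau_c ≈ 1.2 s` and falls on both sides (the in-window decay
saturates for faster processes). The ordering tests therefore work in the
unsaturated regime `tau_c` in [1200, 5000] ms.

A practical corollary for interpreting OCDS_l maps: a voxel is classified
"dead" by the `2e-4 ms⁻¹` cut-off only when its fluctuation *amplitude*
collapses into the noise floor, not merely when its motion slows — with a
short window the normalised decay of any resolvable slow fluctuation still
looks fast. The phantom embraces this: necrotic cores and drug-killed
tissue are modelled as quasi-static (`m = 0`) voxels, whose temporal
variance is then noise-dominated and whose LIV and OCDS_l both fall below
the cut-offs, matching how dead tissue actually presents in these maps.

## The phantom and the drug scenarios

`phantom_spec()`/`build_phantom()` rasterise an ellipsoidal spheroid
(viable shell, optional concentric necrotic core, smooth random boundary
perturbation for shape corruption) resting above a static bright plate
plane, plus labelled sub-regions (spheres and radial shells) stamped into
the tissue. Region labels: 0 background, 1 shell, 2 core (reserved even if
absent), 3+ overrides, last label the plate.

Drug response is encoded in one editable JSON table
(`inst/extdata/scenario_table.json`, `scenario_table()`): per condition and
treatment day it sets radii, core fraction, boundary perturbation, shell
dynamics and a **dead fraction** — the fraction of shell voxels rendered
fully static. Dead voxels are drawn as contiguous patches (a thresholded
smoothed Gaussian field, correlation length ~3 voxels) rather than
salt-and-pepper: with the finite PSF an isolated static voxel inherits a
few percent of its neighbours' dynamic power, which the finite-window
estimator reads as motion, so only patch interiors present as dead — as
focal cell death does in real images. PTX's low-dynamics spots and
contiguous domains and DOX's peripheral dead shell and concentric ring are
static sub-regions for the same reason. The table is explicitly
qualitative: it reproduces orderings (growth of controls and low-dose TAM,
TAM 10 µM collapse after day 3, PTX and DOX 1 µM shrinkage versus DOX
10 µM swelling, declining mean LIV/OCDS_l and rising dead ratios under
effective treatments), not absolute image values, whose ranges are not
publicly established. Replicates differ by a 3% radius jitter, the
boundary-perturbation phase, sub-region placement and the speckle seeds,
all derived from one replicate seed.

Defaults worth knowing: viable shell `m = 0.8`, `tau_c = 600 ms`,
reflectivity 1 (LIV ≈ 27 dB², OCDS_l ≈ 4e-4 ms⁻¹ — both "alive"); core
static with reflectivity 0.6; plate 10× shell reflectivity (exercising
plate removal); noise floor 1e-3. These were fixed once from a
characterisation of the estimators above and give comfortable margins
around the 3 dB² and 2e-4 ms⁻¹ cut-offs.

## Segmentation and quantification

`segment_spheroid()` automates the two-step semi-automatic procedure used
with such data — intensity threshold plus connected-region selection per
B-scan, then plate removal — with declared defaults so no operator is
needed: Otsu threshold on the mean-dB volume (a manual dB threshold is
accepted), automatic plate detection (the depth row whose thresholded
coverage spans ≥ 80% of the lateral extent, brightest-median tie-break; a
±2-voxel slab is excised, and a user plate mask is accepted instead),
largest connected region per B-scan, largest 3D component across B-scans,
then a per-B-scan morphological closing (radius 1 voxel by default, plate
slab re-excised afterwards). Plate removal runs *before* region selection
because the plate plane would otherwise be the largest region in edge
B-scans. An empty result is an explicit "no spheroid found" error naming
the threshold used.

Volume is voxel count × voxel volume; the voxel volume derives from the
protocol's FOV and pixel counts plus the depth pixel pitch, so absolute
volumes are protocol-dependent and documented as such. Mean LIV/OCDS_l are
arithmetic means over the raw (unsmoothed) metric volumes within the mask.
Dead-cell classification uses strict `<` at the cut-off. Day-pair
comparisons use Welch's t-test (`stats::t.test`, Satterthwaite dof) on the
replicate values, reported raw without multiple-testing correction, with
the degenerate identical-constant-groups case defined as `t = 0, p = 1`.

## Problem sizes and numerical choices

The synthetic study default (`study_protocol()`) is a 24-location ×
48-depth × 48-lateral grid over 0.75 × 0.75 mm with the full 32 repeats at
204.8 ms — chosen so one spheroid simulates and analyses in ~1 s and the
full 90-spheroid study completes in about a minute on one CPU, while
keeping spheroids tens of voxels across. The full-scale protocol
(`scan_protocol()` defaults) is used wherever only arithmetic is involved.
Oracle checks pool 10^4–10^5 voxels, where Monte-Carlo error is well below
the asserted tolerances (pooled `rho` deviations < 0.01 against an
asserted 0.02).

Other numerical details: the dB floor defaults to `1e-6 ×` the series mean
intensity (keeps zero-intensity voxels finite without biasing tissue, and
makes LIV/OCDS_l exactly invariant under linear intensity rescaling);
static-voxel flagging uses a relative variance threshold of `1e-10` times
the mean square signal; spatial filtering is circular (FFT) — fine for
phantoms whose margins are background; argmax ties (centre-plane
selection, plate detection) break to the first/brightest index; the
per-location PSF is applied within B-scans only, as the slow-axis pitch
(31 µm) exceeds the lateral FWHM.

## Known limitations

* Welch's test is conservative at n = 3 per group: its true size at
  nominal 0.05 under a normal equal-variance null is ≈ 0.034 (measured at
  2×10^5 replicates). The pipeline reports it honestly rather than
  recalibrating; with three replicates per condition, p-values should be
  read as conservative.
* The per-voxel OCDS_l estimator cannot represent slow-but-moving tissue
  as slow (finite-window bias above); comparisons of OCDS_l maps across
  conditions are meaningful mainly through amplitude collapse.
* The phantom omits depth attenuation, refraction, sample drift and
  system phase noise; passing its tests validates the estimators,
  segmentation and statistics on data satisfying the stated speckle model,
  not robustness to those instrumental effects.
* The scenario table is qualitative by construction; absolute volumes,
  LIV/OCDS_l levels and p-values from the synthetic study are properties
  of the phantom, not predictions for any real spheroid line.
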