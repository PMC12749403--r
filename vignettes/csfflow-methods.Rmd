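---
title: "Methods: cardiorespiratory CSF-flow quantification in csfflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cardiorespiratory CSF-flow quantification in csfflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfflow)
```

## The measurement model

Real-time phase-contrast MRI encodes through-plane fluid velocity into each
voxel of a 2D slice, frame by frame. At the foramen magnum (FM) and in the
lateral ventricle (LV) the CSF velocity signal is dominated by cardiac
pulsation (0.8–2.0 Hz) and modulated by respiration (0.01–0.5 Hz); in the
superior sagittal sinus (SSS) the venous signal carries more respiratory
power. The slice is acquired at 0.19 s temporal resolution for 140 s
(roughly 737 frames), with 1.26 × 1.28 mm² in-plane voxels and a 3 mm
slice.

The pipeline makes four assumptions worth stating explicitly:

* voxels carrying physiological flow show a *coherent* narrow-band spectral
  peak, so the relative spectral intensity — the power within ±Δf of the
  voxel's in-band peak frequency over the total band power, with
  Δf = 1/(acquisition time) — separates them from noise voxels;
* scanner drift and DC phase offsets are adequately described by a
  first-order polynomial in time;
* the respiratory belt's local minima mark cycle onsets, and a cycle's
  flow behaviour is well represented after temporal normalization to a
  200-point 0–100 % phase grid;
* the mean velocity over the ROI times the ROI cross-sectional area is a
  volumetric flow rate, whose running integral is the cumulative displaced
  volume.

Within one respiratory cycle, re-referencing the volume curve to its value
at the cycle onset gives *displacement* = max − min (total to-and-fro
movement, ml) and *net flow* = |max + min| (directional bias, µl). Note
that net flow is a magnitude: direction is deliberately not resolved.

## Tunable parameters

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| analysis band (FM/LV) | 0.8–2.0 | Hz | cardiac-driven CSF pulsation |
| analysis band (SSS) | 0.01–0.5 | Hz | respiration-dominated venous flow |
| frequency tolerance (FM/LV) | ±0.2 | Hz | retain voxels near the subject's cardiac peak |
| frequency tolerance (SSS) | ±0.025 | Hz | narrower respiratory peak |
| threshold percentile | 95 | — | top 5 % of the intensity map |
| peak prominence (velocity) | 0.2 × IQR | cm/s | reproducible stand-in for visual peak QC |
| peak min separation | 0.5/f_cardiac | s | at most one peak per half cardiac period |
| belt valley prominence | 0.25 × range | — | robust to belt drift |
| band-pass half-widths | ±0.2 / ±0.05 | Hz | cardiac / respiratory variants |
| upsampling factor | 10 | — | spline grid for quadrature and peak refinement |

The flow-rate conversion defaults to velocity × pixel area × voxel count,
which reduces dimensionally to ml/s; a `formula = "literal"` switch
multiplies in the slice thickness over a 1 cm reference length for
comparability with conversions that quote voxel volume. Mean-PV defaults to
the average of mean peak and mean valley velocity, with
`pv_definition = "difference"` available because the two readings coexist
in the field. Inhale is measured from the cycle-onset valley to the
intra-cycle belt maximum.

## The synthetic-data generator

No public raw data accompany this class of acquisition, so validation rests
on a generator whose every output has analytic ground truth.

**Velocity series.** ROI voxels share a waveform
`v(t) = A_c cos(2π f_c t) + dV/dt / A_ROI + net/(T · A_ROI) + drift·t + offset`,
plus i.i.d. Gaussian noise per voxel per frame; non-ROI voxels carry noise
only. The respiratory volume curve within a cycle of period `T` is

`V(τ) = a sin(u) + (net/2) · h(u)`, `u = 2πτ/T`,
`h(u) = (3/4)cos u − cos 2u + (1/4)cos 3u`.

This shape was designed around three constraints:

1. *Detrend neutrality.* Every term has zero cycle mean **and** zero
   within-cycle first moment, so a scan-level linear detrend leaves the
   curve untouched. Waveforms without this property (e.g. time-warped
   sinusoids, or pure positive/negative half-sine velocity lobes) make the
   fitted detrend line acquire a spurious slope that parabolically tilts
   the volume baseline and biases net flow by several µl — and a
   half-sine-lobe velocity waveform additionally pins the onset-referenced
   volume minimum at zero, collapsing net flow onto displacement.
2. *Exact net-flow injection.* `h` equals 1 with zero slope at both extrema
   of the sine, so the extrema do not shift and max + min equals the
   injected net volume exactly, for |net| (ml) up to 0.4 a (the feasibility
   bound reported by the generator's error message).
3. *Smoothness.* The velocity is continuous and band-limited near the
   respiratory fundamental, so spline upsampling and Boole quadrature
   behave as on real data.

The cardiac term is cosine-phased so its volume excursion (a sine) is
zero-mean within every cycle; sine phasing would ride the cardiac volume
entirely above the onset level and inflate |max + min| by twice the cardiac
volume amplitude whenever the cardiac and respiratory periods are
commensurate. The inhale:exhale timing asymmetry (default 6:4) is carried
by the belt waveform — where respiratory timing is actually measured — not
by the CSF velocity waveform, which the net-flow definition requires to
have zero within-cycle moments.

**Belt and PPG.** The belt is −cos of a piecewise-linear respiratory phase
(valleys exactly at cycle onsets, peak at end-inhale). PPG beats come from
integrating the instantaneous rate
`hr0 + (rsa/2)·sin(2π f_resp t)`; Gaussian pulses of 50 ms width are placed
at the beat times, so the ground-truth heart-rate displacement is exactly
`rsa`. Belt and PPG sampling rates are configurable (50 and 100 Hz in the
tests); no published value constrains them.

**Landmarks.** Eight landmarks trace a breathing square (corners plus edge
midpoints) scaled about its centroid, at its exhale baseline at every
respiratory valley; areas and distances then have closed forms.

**Feature tables.** `sim_feature_table()` draws correlated exogenous
respiratory features and generates each endogenous variable from its
structural equation plus an independent disturbance sized to unit
population variance. The default truth is *recursive*: the reciprocal
MeanPV↔MaxFlow direct paths are zero and their association flows through
shared upstream predictors. Per-equation OLS is consistent only for such
recursive systems — a genuinely simultaneous reciprocal pair correlates
each response's disturbance with the other equation's regressor, which is
why covariance-based estimation replaces that pair with a residual
covariance. Cyclic coefficient sets are still accepted (the implied linear
system is solved), but recovery guarantees are documented only for
recursive truths.

**What the generator does not emulate.** MRI physics (k-space, coil
sensitivity, phase wrap beyond an optional VENC clip), bulk motion
artifacts, non-Gaussian or spatially correlated noise, belt drift and
sensor nonlinearity, and pose-estimation failure modes other than
low-likelihood dropouts. Passing tests therefore demonstrate correctness of
the *computations* under controlled signal models, not robustness to every
artifact of real acquisitions.

## Numerical choices

* **Quadrature.** Composite Boole panels (weights 7, 32, 12, 32, 7 over
  four intervals) after tenfold natural-cubic-spline upsampling; a 1–3
  interval remainder falls back to Simpson/trapezoid. Exact for quintics;
  agrees with a dense trapezoid to below 10⁻⁶ relative error on
  band-limited signals.
* **Detrending.** Least squares with half-weight end samples (trapezoidal
  weighting). Ordinary LS on a sampled record has an endpoint bias in the
  slope moment that does not vanish with finer sampling (the discrete first
  moment of a cosine over integer cycles is −T/2 at any rate); the
  Euler–Maclaurin end-weighting removes it, and is asymptotically identical
  to OLS for aperiodic records.
* **Peak detection.** Prominence-gated local extrema on the upsampled
  series with three-point parabolic refinement of both location and height;
  at 0.19 s sampling of a 1.2 Hz sinusoid this recovers peak heights to
  ~1 %. The prominence search treats only *strictly* higher samples as
  bounding terrain, so plateau peaks (exact ties on the sample grid) keep
  their full prominence. Consecutive same-type extrema are collapsed to the
  most extreme to enforce peak/valley alternation.
* **Threshold percentile.** Computed over the nonzero relative-intensity
  values of the whole map (type-7 quantile). Computing it over only the
  voxels surviving the frequency tolerance would make the retained count
  depend on how many noise voxels happen to pass the tolerance (roughly a
  third of them do, for a ±0.2 Hz tolerance in a 1.2 Hz band) and shrink
  the ROI far below the map's top 5 %.
* **Denoising.** Isolated single-voxel connected components are removed
  from the thresholded mask. A median filter on the intensity map was
  considered and rejected: it erodes the corners of compact ROIs
  (a blob-edge voxel with fewer than five in-ROI neighbours is zeroed).
* **Band edges.** A band's low edge is clipped to 2/(record length) — the
  slowest resolvable frequency — so the 0.01–0.5 Hz respiratory band is
  usable on a 140 s record (effective low edge ≈ 0.014 Hz).
* **Cycle boundaries.** Half-open [onset, next onset); a record edge counts
  as a valley when the signal rises from it by at least the prominence
  threshold before any interior extremum, so a recording that starts at a
  cycle onset contributes its first cycle. Cycles extending past the flow
  record are dropped.
* **Degenerate inputs.** Flat signals, monotone belts, empty masks,
  infeasible net volumes, sub-minimal beat counts and rank-deficient
  designs raise errors that name the offending quantity; `run_pipeline()`
  records stage errors and skips dependent stages instead of failing the
  run.

## Validation design and problem sizes

The test suite validates each stage against oracles that never share code
with the pipeline: closed forms (2A/π mean speed, shoelace areas, t and CI
hand values), dense-grid quadrature of the analytic waveform, and
construction (distractor frequencies, orthogonality identities). Net-flow
recovery uses respiratory-only sessions — the analogue of a flow phantom's
respiratory conditions — with a 7.98 s period commensurate with the 0.19 s
frame grid and a record of 18 complete cycles plus the closing frame, so
quadrature and detrending are exercised on a cleanly bounded record;
injected net volumes of 0, 25, 50 and 100 µl are recovered within 5 % (the
symmetric waveform to below 1 µl). Path-model recovery uses n = 45
observations and 200 replicates at unit disturbance scale, matching the
study-scale sample size. The full suite runs in well under a minute on one
CPU; `scripts/acceptance.R` re-derives the same quantities from scratch in
a few seconds.

## Known limitations

* Net flow is a magnitude; rostral/caudal direction is not resolved.
* The |max + min| definition is sensitive to any oscillatory component
  whose within-cycle volume excursion is not zero-mean; in real data the
  cardiac phase at cycle onsets varies and this contamination partially
  averages out across cycles, but it does not vanish.
* The path model is a set of per-equation regressions under a hierarchy
  assumption, not a joint SEM; no global fit indices are produced, and
  reciprocal paths are not identifiable from per-equation OLS.
* No multiple-comparison adjustment is applied anywhere; retention at
  p < 0.05 per path implies a family-wise false-retention rate well above
  5 % across the 21 paths.
* Landmark tables are consumed, not produced: pose-estimation quality is
  the caller's responsibility beyond the likelihood-threshold interpolation.
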