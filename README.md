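# csfflow

Cardiorespiratory quantification of cerebrospinal-fluid (CSF) and venous
flow from 2D+time velocity-encoded (phase-contrast) MRI, for researchers
studying how respiration and autonomic state drive CSF motion at the
foramen magnum (FM), in the lateral ventricle (LV) and in the superior
sagittal sinus (SSS).

## What it computes

Starting from a voxel velocity series *v<sub>i</sub>(t)* (cm/s), a
respiratory-belt trace, a photoplethysmogram (PPG) and, optionally,
pose-estimation landmark tracks of the diaphragm:

1. **Spectral ROI selection.** Each voxel's one-sided periodogram
   *P<sub>i</sub>(F)* gives a relative spectral intensity

   *I<sub>pi</sub> = ∫<sub>f<sub>max,i</sub>−Δf</sub><sup>f<sub>max,i</sub>+Δf</sup> P<sub>i</sub>(F) dF ⁄ ∫<sub>band</sub> P<sub>i</sub>(F) dF*,

   with Δf = 1/(total acquisition time) and the band 0.8–2.0 Hz for
   cardiac-driven CSF (0.01–0.5 Hz for the venous SSS variant). Voxels whose
   in-band peak frequency falls outside the subject-specific centre ± 0.2 Hz
   (± 0.025 Hz for SSS) are zeroed, and the map is thresholded at the 95th
   percentile of its nonzero values.
2. **Flow quantification.** The ROI-mean velocity is linearly detrended,
   converted to volumetric flow rate *Q(t) = v(t) · A<sub>ROI</sub>* (ml/s)
   and integrated to a cumulative volume curve with composite Boole
   (Newton–Cotes 5-point) quadrature after tenfold cubic-spline upsampling.
   Within each respiratory cycle (belt-valley to belt-valley, resampled to a
   200-point 0–100 % phase grid and re-referenced to its onset), the volume
   curve yields **CSF displacement** = max − min (ml) and **CSF net flow**
   = |max + min| (µl); velocity peaks/valleys give mean peak, valley,
   peak-to-peak and mean-PV velocities, and mean speed = ⟨|v|⟩.
3. **Physiology.** Inhale/exhale lengths and respiratory rate from the
   belt; heart-rate displacement (respiratory sinus arrhythmia, ΔBPM) as
   the within-cycle max − min of the PPG-derived heart rate; band-limited
   venous displacement variants for the SSS.
4. **Diaphragm kinematics.** Shoelace lung area and five landmark-pair
   distances per frame, normalized to the exhale baseline (√ of mean lung
   area at respiratory valleys), summarized as envelope displacements.
5. **Inference.** VIF screening, a hierarchical path model of six
   structural equations fitted by OLS on z-scored variables (paths retained
   at p < 0.05), respiratory-rate residualization, group t-tests with
   t-based CIs, median splits and Pearson correlations.

A synthetic-data generator (`generate_velocity_series()`,
`generate_physio()`, `generate_landmark_tracks()`,
`generate_phantom_session()`, `sim_feature_table()`) produces every input
with analytically known ground truth, so each stage is validated against
closed forms rather than against itself.

## Worked example

```r
library(csfflow)

# a synthetic session: 140 s at 0.19 s resolution, 8 s breathing cycles,
# 1 cm/s cardiac pulsation, 20 ul net CSF transport per breath
p <- signal_params(resp_freq_hz = 0.125, resp_amp_cm_s = 0.15,
                   net_volume_per_cycle_ul = 20, noise_sd_cm_s = 0.1)
dir <- tempfile(); paths <- simulate_session(dir, p)

cfg <- pipeline_config(region = "FM",
                       velocity_path = paths$velocity,
                       belt_path = paths$belt, ppg_path = paths$ppg,
                       landmarks_path = paths$landmarks)
rec <- run_pipeline(cfg)
rec$features
```

```
  participant condition region  MeanPV mean_speed ... MaxFlow   Dis   NET Inhale  RR ie_ratio    HR  Lung Chest   Dia
1         P01        RB     FM -0.0007      0.641 ...   0.965 0.526  30.4   4.80 7.5     1.50  4.95 0.440 0.201 0.201
```

Reading the row: the cardiac sinusoid of amplitude 1 cm/s gives a mean
speed of 0.641 cm/s (2/π ≈ 0.637 plus noise), the 6:4 inhale:exhale belt
yields an I:E ratio of 1.50 at 7.5 breaths/min, the injected RSA of 5 ΔBPM
is recovered as 4.95, and the per-cycle CSF displacement and net flow are
0.53 ml and ~30 µl (20 µl injected plus cardiac/noise contamination at this
noise level). `qc_report(rec)` prints the per-stage QC summary, and
`autoplot()` methods draw the intensity map, mask, time courses, cycle
segmentation and path diagram.

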