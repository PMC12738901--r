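---
title: "Quantifying phototoxicity from label-free time-lapse imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying phototoxicity from label-free time-lapse imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phototox)
```

## The measurement problem

Intense illumination in live-cell fluorescence microscopy damages the very
specimens it observes. The damage is often sub-lethal and delayed: cells do
not die, they divide late, arrest in the cell cycle, or move less. phototox
quantifies these effects from label-free brightfield time lapses of adherent
cell populations that were synchronised at the G2/M boundary, exposed to a
controlled light dose, and then imaged under gentle transmitted light. The
cell cycle acts as a biological clock: in an unperturbed synchronised
population, mitotic rounding sweeps through the field in a narrow,
predictable time window, so any delay or flattening of that wave is a direct
readout of photodamage.

Three population-level readouts are computed:

1. **Mitotic timing.** `rounding_curve()` forms C(t), the number of
   round-cell detections at time t divided by the number of cells in the
   field of view, and `peak_time()` extracts the earliest time at which C(t)
   attains its maximum. Photodamage shifts this peak rightwards;
   at extreme doses the peak disappears altogether, which `peak_time()`
   reports as `NA` when the maximal fraction falls below a configurable
   floor (default 0.01).
2. **Cell-size dynamics.** Each detected instance's pixel area S is
   converted to an equivalent diameter through S = pi R^2, D = 2R, and
   classified as a mother (> 18 um) or daughter (otherwise);
   `population_curves()` tracks the two populations over time and
   `transition_fraction()` measures how many tracked cells complete the
   mother-to-daughter transition by a cut-off (50 min by convention).
3. **Cellular activity.** `frame_activity()` is the mean over pixels of the
   squared difference between consecutive preprocessed frames;
   `activity_trace()` accumulates it and `cumulative_activity_at()` reports
   the running sum at a fixed horizon (420 min = 7 h by convention).
   Damaged populations show reduced cumulative activity.

Event-level annotations (first rounding frame, daughter emergence) are
classified by `classify_event()`: a cell that rounds but fails to produce two
daughters by the end of the observation window counts as cell-cycle
arrested. Conditions are compared with the two-sided two-sample
Kolmogorov-Smirnov test on pooled event times (`ks_two_sided()`) and per-FOV
summaries are reported as means with percentile-bootstrap confidence
intervals (`bootstrap_ci_mean()`).

## The preprocessing chain

Frame differencing is only meaningful after intensities have been made
comparable. `preprocess_for_activity()` applies, in this order:

1. per-frame min-max normalisation to [0, 1] — this makes everything
   downstream exactly invariant to per-frame positive affine rescaling of
   the raw intensities (camera gain, exposure drift);
2. per-frame illumination ("bleach") correction: a wide Gaussian low-pass
   estimate of the illumination field is subtracted. The width defaults to
   `min(height, width) / 4` pixels — far larger than a cell (~36 px at
   0.55 um/px) so only the illumination-scale structure is removed.
   Negative residuals are kept;
3. whole-video min-max renormalisation, using one global minimum and
   maximum, so that frame-to-frame differences remain on a common scale;
4. per-frame CLAHE (contrast-limited adaptive histogram equalisation) with a
   25 x 25 px tile, clip fraction 0.01 and 256 bins;
5. per-frame Gaussian smoothing with sigma = 1 px to suppress sensor noise,
   with residual out-of-range values clipped to [0, 1].

Numerical notes. CLAHE is delegated to EBImage, whose tiling wants the image
side to be a multiple of the tile count; frames are edge-padded and cropped
back, and the scikit-image-style clip fraction is converted to EBImage's
bin-scaled limit (`limit = clip * bins` — the same underlying Zuiderveld
algorithm). The wide Gaussian low-pass caps its kernel at the image size
and, for sigma > 32 px, is evaluated on a bilinearly decimated grid and
interpolated back: the estimated field varies over hundreds of pixels, so
the decimation error is orders of magnitude below the structures being
removed, and the exact path is used whenever sigma <= 32.

For detection on a coarser grid, `resample_to_pixel_size()` downsamples
bilinearly; the output shape is `round(extent / target)` per axis and the
realised pixel size is recomputed from the shape, so it can differ from the
request by under one percent. All physical quantities derived from masks use
the mask's own calibration, which may legitimately differ from the video's.

## Illumination-dose bookkeeping

All doses are areal energy densities, J/cm^2 = power x time / area, computed
by `areal_dose()` from an `illumination_regime()`:

* **widefield**: power at the sample over the illuminated field of view
  (e.g. 84.9 mW over 0.014 cm^2 for 100 ms gives 0.61, reported as
  0.6 J/cm^2; 1 s gives 6, 10 s gives 61, reported as 60 J/cm^2);
* **scanning**: power times per-pixel dwell time over the single-pixel
  footprint (side^2, with 1 um^2 = 1e-8 cm^2). Under this convention a
  high-power fast scan (0.3 mW, 3.528 us) and a low-power slow scan
  (0.1 mW, 3 x the dwell) deliver identical doses — the compensatory
  power-time design used to separate irradiance effects from duration
  effects.

Internal values are exact; rounding to the 1-2 significant figures used in
reports happens only at the reporting layer (`dose_table()`,
`percent_of_max()`). Power is taken as measured at the sample; no objective
transmission model is applied.

## The synthetic-data generator

Real acquisitions of this kind are gigabyte-scale and detector weights are
not re-derivable, so the package ships a generator
(`synthetic_scenario()`, `render_video()`) that emulates the study
conditions and provides exact ground truth, making every analysis stage
testable end to end. Defaults mirror the acquisition this analysis targets:
126 cells per 512 x 512 field at 0.55 um/px, frames every 4 min for 8 h,
mothers of 20 um dividing into two 15 um daughters after 30 min of mitotic
rounding, and a round-cell fraction peaking 50 min after synchronisation
release. Rounding onsets follow a truncated normal law (sd 10 min by
default; a gamma option provides the skewed, high-dose-like shape);
photodamage is emulated by `extra_delay` (a rightward shift of every onset)
and `arrest_prob` (cells that round and never divide). A static illumination
gradient, a linear temporal brightness drift and Gaussian sensor noise are
layered on top.

Two generator choices deserve explanation.

* **Peak calibration.** Detections include both round mothers and the two
  briefly-round daughters each division produces, so the expected detection
  curve E[C(t)] peaks later than the onset law. Because the scenario
  parameter of interest is the observable peak time, the generator places
  the onset location at `rounding_time_mean` minus the analytically computed
  argmax offset of E[C(t)] (see `onset_distribution()` and
  `expected_rounding_fraction()`). Recovered peaks are then directly
  comparable to the configured value.
* **Daughter visibility.** Daughters remain round and detectable for 16 min
  (4 frames) after division before re-spreading — inside the 15-30 min
  window over which the mother-to-daughter transition is resolvable in
  brightfield. This value also gives E[C(t)] a well-curved maximum, so the
  per-FOV argmax estimator localises the peak to within one frame at
  n = 200 cells; with much shorter daughter visibility the synchronised
  C(t) has a nearly flat top and the argmax wanders by 1-2 frames.

Note that a tightly synchronised population with daughters counted as two
instances can push C(t) slightly above 1 around the peak; the curve is a
detection count over a fixed first-frame denominator, not a probability, and
the package warns rather than rescales.

The rendered appearance — bright ring, darker interior — is the halo
contrast of rounded mitotic cells in slightly defocused brightfield;
adherent cells are faint soft blobs and re-spread daughters two smaller
blobs. The built-in classical detector is tuned to this appearance model and
the coupling is intentional and fixture-level: the detector exists to close
the loop on synthetic data, not to replace a trained detector on real
images.

Cells are placed on a jittered grid with a guaranteed minimum
centre-to-centre separation (default: one mother diameter plus a pixel,
i.e. near-confluence, where rounded cells may touch) and an inset so mothers
never cross the field border; near a border, daughters split parallel to
it. With `min_separation_um >= 2 * daughter_diameter + ~2 um` no two round
objects ever overlap — the regime in which the classical detector's
precision/recall guarantee (>= 0.95) is stated and tested. At the confluent
default density daughter discs do overlap neighbours and detector recall
degrades substantially (roughly 0.5-0.9 depending on crowding) — the same
order as trained detectors achieve on real confluent data — which is why the
quantification layer consumes ground-truth or externally supplied masks in
the full-scale pipeline, and the classical detector is reserved for sparse
or synthetic material.

What the generator does **not** emulate: optics (point-spread function,
partial coherence), cell migration, heterogeneous cell sizes and rounding
durations, stress-induced (non-mitotic) rounding, and detector errors of a
trained model. Passing tests on synthetic data therefore validate the
analysis arithmetic and its invariances, not detection performance on real
microscopy.

## The classical round-cell detector

`detect_round_cells_classical()` smooths the frame (sigma 1), thresholds the
absolute deviation from the local mean computed over a window of the largest
expected cell (so slow illumination trends cancel and both the bright halo
and the dark interior count as foreground), fills enclosed holes, removes
sub-structure with a 3 px opening, splits touching objects by a watershed on
the distance transform, and keeps components by equivalent diameter (10-25
um by default) and circularity 4 pi A / P^2 >= 0.8. The pixel-count
perimeter underestimates true contour length, so the circularity is rescaled
by a factor calibrated on rasterised discs (discs, including
watershed-flattened ones, score >= 0.8; 3:1 ellipses score ~0.67).

## Viability quantification

`segment_positive_nuclei()` normalises the dye channel (making the result
invariant to affine intensity rescaling), applies Otsu's threshold, splits
touching nuclei with a watershed on the distance transform, and removes
components below 10 px. Dye-positive nuclei are sparse by nature, so a
thresholded foreground covering more than a quarter of the frame is treated
as a signal-free channel (blank or constant frames otherwise threshold
inside their own noise). `viability_fraction()` divides the instance count
by the fixed first-frame cell count — the same denominator convention as
C(t); a per-frame alternative is available through `viability_series()`.

## Statistical conventions

* KS comparisons use the asymptotic two-sample two-sided law (via R's
  `ks.test`), matching common practice for event-time samples of n ~ 100+;
  pooled event times per condition are the default sampling unit, per-FOV
  summaries being the alternative. Significance stars follow the
  0.05/0.01/0.001/0.0001 convention. No multiple-testing correction is
  applied by default.
* Bootstrap intervals are percentile intervals of the mean, 1000 resamples,
  level 0.95, deterministic under a seed.
* Type-I error of the KS wrapper (~4-5% at alpha = 0.05, n = 100) and
  bootstrap coverage (~93-95% at n = 50) are verified by simulation in the
  test suite.

## Tunable parameters at a glance

| Parameter | Default | Units | Where |
|---|---|---|---|
| bleach-correction sigma | min(h, w)/4 | px | `preprocess_for_activity()` |
| CLAHE kernel / clip / bins | 25 / 0.01 / 256 | px / frac / - | `enhance_contrast_clahe()` |
| smoothing sigma | 1 | px | `smooth_gaussian()` |
| detection grid | 0.865 | um/px | `resample_to_pixel_size()` |
| mother/daughter split | 18 | um | `classify_size()` |
| activity report horizon | 420 | min | `cumulative_activity_at()` |
| transition cut-off | 50 | min | `transition_fraction()` |
| detector diameters / circularity | 10-25 / 0.8 | um / - | `detect_round_cells_classical()` |
| viability min area | 10 | px | `segment_positive_nuclei()` |
| no-peak floor | 0.01 | fraction | `peak_time()` |

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data,
sized to exercise the statistics without waste: parameter-recovery and
transition scenarios use 200 cells on 800 x 800 px fields (schedule-level
ground truth, no rendering); the detector loop uses 30 non-overlapping cells
on 416 x 416 px over 160 min; the full two-condition pipeline demonstration
uses 2 x 10 fields of view of 120 frames at 512 x 512 with the default 126
cells; calibration simulations use 1000 (KS) and 500 (bootstrap) trials.

## Known limitations

* The activity metric is population-level by design; it does not resolve
  single-cell motility and it conflates division dynamics with migration.
* `peak_time()` on a noisy, nearly flat C(t) is an argmax and inherits its
  instability; the no-peak floor flags the degenerate case but per-FOV peaks
  should be aggregated (mean with bootstrap CI) before interpretation.
* The classical detector is an appearance-model detector for the synthetic
  halo look; it is not a substitute for a trained instance-segmentation
  model on real brightfield data.
* Dose bookkeeping assumes uniform illumination over the stated area;
  non-uniform irradiance maps and photochemical wavelength dependence are
  out of scope.
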