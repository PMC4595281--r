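---
title: "Methods: task performance and lateralized activation in motor fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: task performance and lateralized activation in motor fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemiscope)
```

## The problem

Studies of upper-limb recovery after stroke compare task-related brain
activation between hemiparetic patients and controls while the subjects
perform a paced finger flexion-extension task in the scanner. Two
confounds dominate the interpretation of such comparisons: how well the
subject actually performed the task (amplitude, rate, timing), and
whether the "inactive" hand covertly moved or contracted along with the
instructed hand (mirror movements). hemiscope implements the full
quantitative chain for such a study: kinematic scoring of data-glove
traces, EMG mirror-contraction scoring, proportional-threshold ROI
summaries of activation maps with laterality indices, and the group and
brain-behavior statistics — plus a synthetic-data generator so every
stage can be validated by recovering known ground truth.

## Task paradigm

The paradigm is an alternating block design: 20 s of cued finger
flexion-extension, 20 s of rest, for 6 minutes per run, starting with
rest (`makeTaskBoxcar(blockS = 20, totalS = 360)`). The binary move/rest
indicator (the *task boxcar*, `T`) is the regressor of the first-level
GLM and the correlation target for all envelope-based performance
scores.

## Glove kinematics

The glove records the mean finger extension angle (degrees, 0-90 after
calibration). Processing:

1. **Drift correction** — zero-phase Butterworth high-pass at 0.05 Hz
   (`detrendResample`). Movement is at ~0.5-1 Hz, sensor drift well
   below 0.05 Hz, so the band between them is a safe cutoff. The filter
   is applied forward-backward so peaks are not shifted in time.
2. **Resampling** — linear interpolation onto a uniform 15 ms grid. The
   signal is smooth at movement frequencies, so linear interpolation is
   adequate.
3. **Movement counting** (`countMovements`) — the number of local
   maxima plus minima, divided by two, so a full flexion-extension
   cycle counts once. Extrema are detected with a hysteresis rule: an
   extremum is committed only when the signal swings away from it by
   more than a prominence threshold, by default 5% of the trace's
   5th-95th percentile range. Without this, sensor noise wiggles would
   be counted as movements.
4. **Compliance correlation** (`complianceCorrelation`) — the Pearson
   correlation between the envelope of the movement signal and the task
   boxcar; near 1 when the subject moves exactly when (and as much as)
   cued.
5. **Glove mirror score** (`mirrorGloveScore`) — the same correlation
   computed for the hand that was *not* instructed to move. Overt
   mirror movements produce a high score; in well-performing cohorts
   the mean sits near zero.

The *envelope* is defined once for the whole package: the magnitude of
the analytic (Hilbert) signal followed by a 0.5 s moving average
(`computeEnvelope`). 0.5 s is short against the 20 s blocks but long
against single movement cycles and EMG bursts, which is what an
amplitude envelope should resolve here.

## EMG mirror-contraction score

Surface EMG over the finger extensors of the non-instructed hand
detects isometric contractions that produce no overt movement. The
preprocessing chain (`preprocessEmg`) applies, in order: notch filters
at 45 and 90 Hz (scanner gradient artifacts; 2nd-order zero-phase IIR,
quality factor 30), a 10 Hz high-pass (movement artifacts), full-wave
rectification (regains the low-frequency contraction envelope), and a
2-130 Hz band-pass. The stated cutoffs are the contract; the filter
realizations (Butterworth orders, zero-phase application) are this
package's choices, standard in EMG practice.

Contraction strength is normalized to a maximal voluntary extension
(MVE) recording made before each run:

$$\%\bar{MVE} = \frac{\bar{EMG}}{\bar{MVE}} \cdot 100$$

Because the preprocessed signal is zero-mean by construction (the final
band-pass removes DC), the "average signal" is computed as the mean
*rectified* amplitude, which is proportional to contraction strength;
the common gain of task and MVE recordings cancels, removing
between-subject factors such as skin conductivity and electrode
placement. The task average runs over move-block samples only (the
quantity of interest is contraction *during the task*), configurable to
the full run.

The mirror-contraction score is

$$MM_{EMG} = r_{T, E_{EMG}} \cdot \%\bar{MVE}$$

the envelope-boxcar correlation weighted by contraction strength
(`mirrorEmgScore`). The identity `mm_score = task_corr * pct_mve_mean`
holds exactly on every computed row, and `|MM_EMG| <= %MVE` always.

## ROI analysis of activation maps

Per-voxel beta (task-regressor) coefficients are summarized over an
integer label atlas of six bilateral motor segments (cerebellum, SMA,
premotor, precentral, postcentral, insula; twelve labels):

- **Proportional threshold** (`selectTopVoxels`): within a segment, the
  top 15% of voxels by beta value are selected (`k = floor(0.15 N)`);
  a proportional rather than absolute threshold cancels global signal
  differences between subjects — multiplying all betas by a positive
  constant changes nothing. Selections with `k = 0` raise an error
  rather than degrade silently. Ties at the threshold are broken by
  linear voxel index for cross-platform determinism. Ranking is by
  signed beta (the *highest* values), not absolute value.
- **Mean beta** (`roiMeanBeta`): the arithmetic mean over the selected
  voxels represents the segment's activation level.
- **Laterality index** (`lateralityIndex`): voxels of both hemispheres
  of a segment are pooled, the top 15% of the pooled set is selected,
  and selected voxels are counted per hemisphere:
  $LI = (vox_i - vox_c)/(vox_i + vox_c)$, where $i$/$c$ are the
  ipsi-/contralesional hemispheres. $LI = 1$ means all activated voxels
  are ipsilesional. Pooled selection is used for the LI; per-hemisphere
  selection for the per-ROI mean betas.
- **Hemisphere flipping** (`flipHemispheres`): volumes of subjects with
  right-sided lesions are mirrored across the mid-sagittal plane so the
  affected hemisphere is on a common side across subjects. The
  left-right voxel axis is identified from the affine's first row; an
  ambiguous affine is an error, not a guess. Flipping twice is the
  identity.
- **Smoothing** (`smoothVolume`): the voxelwise group-comparison path
  smooths with a separable Gaussian, FWHM 8 mm
  (sigma = FWHM / (2*sqrt(2*ln 2)) per axis in mm); the ROI path runs
  on unsmoothed data.

The first-level fit (`fitBlockGlm`) is a deliberately simplified
emulation: per voxel, the time series is regressed on the raw
(unconvolved) boxcar plus an intercept after a discrete-cosine
high-pass at 1/128 s^-1^, with optional AR(1) prewhitening from the
pooled lag-1 residual autocorrelation. It recovers planted block
effects on synthetic data; it does not reproduce any specific
neuroimaging package's betas, and no hemodynamic convolution is
modeled (fast-sequence block designs make the unconvolved boxcar a
tolerable approximation at the simulation scale used here).

## Group statistics

- `rmAnova` — univariate repeated-measures ANOVA with
  subject-partitioned error strata (ROI x hemisphere x level within
  subjects, group between). Computed via base R's `aov` with an
  `Error(subject/...)` term; an independent sums-of-squares oracle in
  the test suite confirms the decomposition to 6 decimals. No
  sphericity correction is applied by default (matching the common
  reporting style for this design); Greenhouse-Geisser is available via
  `ggCorrect = TRUE` for single within-factor strata. For the
  laterality index — a segment-pair quantity — the hemisphere factor is
  dropped. Incomplete designs are an error that lists the missing
  cells.
- `tTests` — classic Student statistics with complete-case handling
  per test, mirroring equipment-failure gaps in performance tables.
- `oneSampleWilcoxon` — signed-rank test against a scale value (e.g.
  ARAT maximum 57). Zeros are dropped (classic convention). Clinical
  scales tie heavily, so the default is the tie-corrected normal
  approximation without continuity correction — the form mainstream
  statistics packages report for this test; the exact distribution is
  available for small untied samples.
- `stepwiseRegression` — forward entry (partial-F p < 0.05), backward
  removal (p > 0.10), iterated to a fixed point. Ties enter by lowest
  column index; collinear candidates are skipped with a warning. With
  `p_in = p_out` the procedure reduces to pure forward selection, which
  the test suite checks against exhaustive enumeration.
- `voxelwiseGroupTtest` — per-voxel two-sample t after smoothing, with
  family-wise error controlled by the permutation distribution of the
  maximum |t| (default 1000 label permutations). This is a
  self-contained, assumption-light substitute for parametric corrected
  thresholds and is labeled as such in the result metadata.

## The synthetic-data generator

`simulateCohort` produces everything the pipeline consumes, with a
ground-truth sidecar per subject. What it emulates, and why those
choices:

- **Glove traces**: raised-cosine flexion-extension cycles during move
  blocks with a three-level amplitude schedule (30/60/90 degrees,
  emulating the low/medium/full cue), slow sinusoidal drift (5 degrees
  at 0.01 Hz), and band-limited sensor noise (SD 0.5 degrees, 5 Hz
  bandwidth — a resistive bend sensor tracks mechanical motion and has
  no broadband power). The default movement rate is 0.5 Hz: with 180 s
  of movement per run this yields counted movements near 90, the
  magnitude observed with this paradigm (reported per-subject counts
  span roughly 64-105 even though the visual cue cycles at 1 Hz; the
  generator follows the observed counts). Mirror leakage is injected as
  `mirrorGain` times the active-hand oscillation.
- **EMG**: a broadband Gaussian carrier amplitude-modulated by the
  boxcar, scaled so the mean rectified burst amplitude equals
  `targetPctMve`% of the MVE burst; sinusoidal artifacts at exactly 45
  and 90 Hz; 0.2 Hz motion drift; a small rest-level floor (1% of MVE —
  physiological recordings are never silent). Simulated at 1000 Hz by
  default (hardware rates are not part of the contract; 1000 Hz is
  conventional for surface EMG and safely above the 130 Hz band edge).
- **Beta volumes**: per segment pair, a planted set of "active" voxels
  sized to the pooled top-15% count, split between hemispheres so the
  expected LI equals `liTrue`, on a noise background. A per-subject
  multiplicative global gain (SD 0.2) models between-subject BOLD
  responsiveness — the very variation proportional thresholds exist to
  absorb — and makes per-ROI activation levels correlate across ROIs
  within subject, as in real data. Per-run laterality jitter
  (SD 0.15) reflects between-run variability of lateralization.
- **Cohort tables**: Fugl-Meyer ~ N(60.5, 5.6) clamped to [0, 66],
  ARAT ~ N(56, 2.1) clamped to [0, 57], %NHPT ~ N(69.3, 22.6) truncated
  positive — a moderately-to-well recovered chronic cohort; controls at
  scale maxima. Lesion sides alternate L/R so hemisphere flipping is
  exercised. An optional linear FM-on-activation dependence
  (`fmSlope`) supports power checks of the brain-behavior regression.

What the generator does **not** emulate: raw k-space/EPI data, head
motion, hemodynamic convolution, lesion anatomy, spatial normalization
error, or the spatial covariance structure of real BOLD noise. Passing
recovery tests therefore shows the *estimators* are correct and
unbiased under the stated signal model — not that the pipeline is
robust to every artifact of real acquisitions.

## Numerical choices and degenerate inputs

- All filters are applied forward-backward (`signal::filtfilt`), so
  effective orders are twice the design order; cutoffs are the stated
  contract. Filter edge transients inflate the envelope near run
  boundaries; with drift present this biases envelope-boxcar
  correlations slightly negative (about -0.03 on null cohorts — the
  same scale as observed in practice), which is why the null-mirror
  property is asserted as a band around zero rather than exact zero.
- The analytic signal is computed by the frequency-domain Hilbert
  construction; the moving average uses partial windows at the edges
  rather than NA padding.
- Zero-variance envelopes (flat recordings) yield correlation 0 with a
  warning, so cohort tables never contain missing-by-computation cells.
- A constant voxel time series gets beta 0 with a warning; a degenerate
  MVE recording (mean amplitude ~ 0) is an error, since nothing can be
  normalized against it.
- Seeds: every simulator takes an explicit seed and scopes it
  (`withr::with_seed`); no function reads or mutates global RNG state.
  The same seed reproduces a cohort byte-identically, including all
  written files.

## Problem sizes used in validation

The test suite and the acceptance script run at desk scale, chosen so
each stochastic check is stable without being slow: parameter-recovery
checks average 20 seeds; EMG recovery simulations use a 400 Hz sampling
rate (above the 260 Hz floor the band edge requires); ANOVA size is
estimated from 500 null cohorts of 8 patients and 6 controls on an
8x8x6 voxel grid; the stepwise null uses cohorts with the study's 20
patients; atlas grids of 8-12 voxels per axis keep segment sizes
comfortably above the point where a 15% selection degenerates. The
defaults of every user-facing function remain the full study
conditions (20/20 s blocks over 6 min, 100 Hz glove, 1000 Hz EMG,
16x16x18 atlas, 20 patients / 15 controls).

## Known limitations

- The published group-comparison F/p values and voxelwise results for
  this design cannot be reproduced without the original raw scans; the
  statistical layer is validated instead by oracle equivalence, type-I
  error calibration, and parameter recovery.
- The simplified GLM is an emulation (unconvolved regressor, global
  AR(1) estimate); it is not a drop-in replacement for a full
  first-level analysis.
- The label atlas generator builds rectangular slab segments — adequate
  for exercising selection logic, not anatomically realistic. Real
  atlases are read from NIfTI with a label table and need not be
  mirror-symmetric.
- Printed summary rows of the packaged reference tables are reproduced
  by recomputation where the underlying per-subject values are printed;
  two printed cells (the movement-count mean and the %NHPT mean)
  disagree slightly with the mean of their own printed columns, and the
  package reports the recomputed values rather than forcing agreement.
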