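---
title: "Methods: BAT quantification from PET-MRI and PET-CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BAT quantification from PET-MRI and PET-CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(batquant)
```

## The quantification problem

Active brown adipose tissue (BAT) takes up the glucose analogue 18F-FDG
during cold exposure or adrenergic stimulation. Quantifying that uptake
from hybrid imaging requires deciding, voxel by voxel, (i) whether a
voxel is adipose tissue and (ii) whether its tracer uptake is high
enough to call the tissue active. The two imaging branches implemented
here answer (i) differently — Dixon fat-fraction mapping on PET-MRI,
a Hounsfield-unit window on PET-CT — and share the logic of (ii), an
SUV threshold.

All volumes entering a pipeline are assumed co-registered;
`validate_geometry()` makes that assumption explicit by requiring
identical lattice shapes and voxel spacings within a tolerance
(default 0.01 mm). Registration and reconstruction are out of scope.

## SUV scales

The standardized uptake value normalizes activity concentration
(kBq/ml) by injected dose per unit mass:

* SUV_bw uses body weight: `SUV_bw = A / (dose / W)`, dose in kBq,
  W in grams, giving g/ml.
* SUV_lean uses lean body mass from the Janmahasatian formula
  (male `9270 W / (6680 + 216 BMI)`, female `9270 W / (8780 + 244 BMI)`),
  because the BARCIST consensus defines its BAT activity threshold
  (>= 1.2 g/ml) on the lean scale. Using lean mass avoids calling high
  perceived uptake in adipose-rich subjects, where tracer distributes
  into a smaller lean compartment.

No radioactive-decay correction is applied to the injected dose: the
acquisitions this models follow a fixed 60-min uptake protocol, so decay
scales all subjects identically and cancels from comparisons. PET inputs
may be supplied either as kBq/ml plus subject metadata or as pre-computed
SUV maps; vendor consoles differ in which they export.

The MRI branch thresholds on SUV_lean but reports SUV_mean on the
body-weight scale by default (`bat_config(suv_scale = )`), since
clinical SUV_mean values are conventionally body-weight-normalized;
both maps are returned, so either convention can be reported.

## The PET-MRI pipeline, stage by stage

**Fat fraction.** `FF(%) = 100 * SI_fat / (SI_fat + SI_water)` from the
two-point Dixon signals. Where both signals are zero (air, outside the
body) the ratio is undefined; such voxels are flagged invalid and
excluded from every downstream neighborhood and mask, never silently
mapped to 0 % (which would look like pure water). No T2*/B0-corrected
proton-density fat fraction is attempted — the method is the plain
signal ratio.

**Median filter.** A median spatial filter suppresses isolated
fat-fraction speckle before thresholding. The window size is a free
parameter; the default is 3x3x3, the smallest isotropic window.
Borders are reflect-padded (edge voxel duplicated) so the field of view
does not shrink; invalid voxels are simply dropped from each
neighborhood's order statistics. Because the median is an order
statistic, filtering can never produce values outside the observed
range, and a constant region is a fixed point.

**Adipose mask.** Voxels *below* 50 % fat fraction are removed as
non-adipose, which we read literally: a voxel at exactly 50.0 % is
retained. The threshold is configurable (`ff_threshold_pct`).

**PET mask.** SUV_lean >= 1.2 g/ml, boundary included per the
criterion's ">=".

**Exclusions and depot tagging.** Brain gray matter is FDG-avid and,
in some fields of view, survives the masks; removal is modeled as a
supplied exclusion mask rather than automatic brain detection,
mirroring the manual step it replaces. Candidate voxels are then
partitioned by a user-supplied depot-region label map:
cervical, supraclavicular and axillary depots are grouped as
"supraclavicular", paraspinal BAT is tagged separately. Candidates
outside every region are reported as unassigned — they are never
silently attributed to a group, so partition conservation
(group counts + unassigned = candidates) always holds.

**Erosion.** A (3, 3, 1) structuring element — 3x3 in-plane, single
slice axially — erodes each depot mask to strip PET blooming and
boundary artefacts. Full-footprint semantics: a voxel survives iff
every voxel under the centered footprint is set, and out-of-volume
neighbors count as background, so masks also shrink at the volume edge
(conservative for blooming removal). Arrays are indexed (x, y, z) with
z the axial slice axis, which is what makes the "1" of the footprint
axial. Metrics are computed both pre- and post-erosion, since effects
of interventions on BAT are expected to be robust to this choice.

**Metrics.** Per depot group and combined: SUV_mean (arithmetic mean
over the mask), volume (voxel count x voxel volume, ml), total uptake
(SUV_mean x volume, the mask-sum of SUV in ml·g/ml), and mean fat
fraction. An empty group reports volume 0 with SUV_mean `NA` —
undefined, not 0 — so averaging metrics across subjects cannot be
dragged down by empty segmentations.

## The PET-CT pipeline

Retrospective clinical PET-CT lacks Dixon imaging, so adiposity comes
from radiodensity: HU in [−190, −10], inclusive at both ends ("between"
read inclusively). Activity uses SUV_bw > 1.5 g/ml, strict per the
defining ">". A subject is BAT-positive when at least `min_voxels`
voxels satisfy both; the default is 1 voxel because the underlying
protocol states no minimum-cluster rule, but the knob exists because a
single-voxel criterion is noise-brittle on real scans. An optional
anatomical search-region mask can restrict the analysis (whether the
original retrospective analysis did so is not documented; we accept one
but do not require it). Classification is monotone: raising either
threshold can only shrink the BAT voxel set, never convert a negative
scan to positive.

## Physiology metrics

* **Indirect calorimetry.** Each hood measurement spans 15 min; the
  first 5 min are equilibration and are discarded, the mean over
  (5, 15] min is the measurement's EE (kcal/day). Condition-level EE is
  the mean over that condition's measurements (two in the emulated
  design; any number >= 1 is accepted). CIT = EE_cold − EE_warm, signed.
  EE is taken as the calorimeter's output; no Weir-equation
  recomputation from VO2/VCO2 is attempted.
* **Thermal imaging.** Per image, the supraclavicular value is the
  unweighted mean of the left and right ROI means; laterality averaging
  is our choice (left/right are also emitted separately). Condition
  summaries are means over images of the per-image values
  ("mean of means"); ROI maxima are carried along but excluded from the
  headline summaries. Temperatures outside (−10, 45) °C are rejected as
  physiologically implausible for skin.
* **Respirometry.** Cycles are labeled by injection phase in the fixed
  order basal → noradrenaline → oligomycin → FCCP → rotenone/antimycin.
  Non-mitochondrial respiration is the mean of all post-rotenone cycles
  (their count is not fixed by the protocol; all are used, configurable)
  and is subtracted from every metric. Basal is the mean of the *last*
  three pre-noradrenaline cycles — the protocol does not say first or
  last three; we chose the cycles closest to the injection as the most
  current baseline, and the count is configurable. Stimulated is the
  6th post-noradrenaline cycle, uncoupled the mean of the first three
  post-oligomycin cycles, maximal the first post-FCCP cycle. Adding a
  constant to every cycle cancels exactly through the subtraction.

Applying these operations to published condition-level group means
reproduces the published derived rows (CIT 158 kcal/day normal-weight;
supraclavicular cold-induced change −1.0 °C; obese sternal change
−2.6 °C; warm/cold SCV–sternal differentials 1.1/1.7 °C). Two published
rows differ from group-mean arithmetic because they were derived from
unrounded subject-level data before rounding: the obese CIT prints 86
where the printed means give 87, and the normal-weight sternal change
prints −1.7 where the printed means give −1.6. The package computes
from its inputs; it does not special-case these.

## The phantom generator

`generate_phantom()` emits co-registered Dixon fat/water, PET (kBq/ml)
and CT (HU) volumes plus a ground-truth label map. The default phantom
is a 48 x 48 x 24 grid at 2.5 mm isotropic spacing (55,296 voxels) —
coarse relative to clinical matrices, chosen so that full-pipeline
Monte-Carlo loops run in seconds while every depot still spans hundreds
of voxels. Compartments are rasterized painter's-algorithm style (later
compartments overwrite earlier ones; overwrites are recorded in the
bundle's log), which is how a body compartment can underlie organs.

Parameter choices and what they emulate:

* **BAT depots** (two supraclavicular, one paraspinal ellipsoid):
  fat fraction 70 % — inside the 60–80 % range typical of BAT, whose
  triglyceride content sits below white fat's; SUV_lean 4.0 —
  comfortably in the range of cold-activated BAT and far enough from
  both thresholds (1.2 lean, 1.5 bw) that 5 % noise cannot flip depot
  voxels; HU −100, mid-adipose window.
* **Adipose shells**: each depot is embedded in a surrounding fat shell
  (2 voxels thicker per semi-axis) of matched fat fraction, because
  supraclavicular and paraspinal BAT sit inside fat depots in vivo.
  The matched FF also makes the programmed depot FF an exact fixed
  point of the median filter, keeping ground truth analytic; with a
  lean-tissue boundary instead, the median filter would reclassify
  high-curvature surface voxels and the programmed truth would no
  longer be exactly recoverable.
* **Subcutaneous WAT** (FF 85 %, SUV 0.5, HU −100): passes the adipose
  criteria but not the activity thresholds — the tissue the SUV
  threshold exists to reject.
* **Muscle** (FF 5 %, SUV 0.8, HU +40) and **brain** (FF 5 %, SUV 6,
  HU +40): the confounders each branch must reject — muscle by fat
  fraction and HU, brain by fat fraction plus the explicit exclusion
  mask.
* **Body** (FF 20 %, SUV 0.5, HU +20) and air background (zero MR
  signal, so fat fraction is undefined there — exercising the validity
  mask; zero activity; −1000 HU).
* **Subject**: 65 kg, 1.70 m, 75 MBq — the imaging cohort's means.
* **Noise**: additive Gaussian per modality, with the PET sigma
  specified in SUV units and converted to activity. The noisy study
  condition used in validation is sigma = 5 % of the depot SUV for PET,
  2 signal units for each Dixon channel, 10 HU for CT. Rician MR noise
  and PET point-spread/blooming are deliberately not modeled; noise is
  the only corruption.

SUV targets are programmed on the lean scale by default (the scale the
MRI threshold is defined on) and converted to stored activity through
dose/LBM, so recovering them exercises the SUV arithmetic; `"bw"` is
available for the CT branch, whose threshold is body-weight-scaled.

What passing phantom tests does and does not show: they verify the
masking logic, threshold boundary semantics, morphology, SUV/FF
arithmetic and metric bookkeeping exactly, and the pipeline's noise
robustness under idealized (piecewise-constant, additive-Gaussian)
images. They do not certify performance on real scans, where partial
volume, PET blooming, registration error, bias fields and Rician noise
all blur the boundaries the phantom keeps sharp — which is precisely
why the erosion step and the configurable thresholds exist.

`simulate_study()` wraps the generator into a paired placebo/treated
crossover: per subject, an anatomy (depot radii jittered ±10 %) shared
by both arms, active-BAT status drawn with a programmed prevalence
(default 13/15, the detectable-BAT rate in the emulated crossover), and
a treated arm whose BAT SUV and depot radii are scaled multiplicatively
and whose fat fraction is shifted (default +5 %, in the direction of
reduced lipolysis). Inactive subjects carry depots at background SUV.
Everything derives from one integer seed, and generation saves and
restores the session RNG state.

## Numerical and degenerate-input choices

* Exact threshold semantics everywhere: FF >= 50 kept, SUV_lean >= 1.2
  kept, SUV_bw > 1.5 kept, HU boundaries inclusive. Tests pin each
  boundary.
* Median of an even count (possible next to invalid voxels) follows the
  usual midpoint convention of `stats::median`.
* All-invalid neighborhoods stay invalid; invalid voxels stay `NA`
  through filtering and are excluded from masks and means.
* Empty masks: volume 0, SUV_mean and FF_mean `NA`; BAT-negative CT
  results leave SUV_mean `NA`.
* Erosion at the volume edge treats outside as background.
* Masks, label maps and volumes are validated for shape/spacing
  agreement at every module boundary; mismatches raise geometry errors
  naming the offending axis.

## Validation problem sizes

The test suite validates the vectorized morphology against brute-force
voxel-loop oracles on 16^3 random volumes, exact phantom recovery at
zero noise on the 48 x 48 x 24 default phantom, noisy recovery over 20
seeds (SUV_mean within 2 %, pre-erosion volume within 5 % of truth),
CT classification on a 50-subject cohort, and crossover effect recovery
(programmed 0.5; exact at zero noise, mean ratio within 2 % over 20
noisy subjects). These sizes keep the full suite around a minute on one
CPU while leaving each Monte-Carlo check hundreds of voxels or tens of
replicates of resolution.

## Known limitations

* Piecewise-constant phantoms cannot probe partial-volume or
  point-spread effects; reported volumes on real data depend on both.
* The Dixon model is the two-point signal ratio; field inhomogeneity
  and T2* decay are unmodeled.
* Depot assignment relies on user-supplied anatomical regions; there is
  no automatic anatomy detection.
* Group statistics beyond the arithmetic implemented here (paired
  tests, ANOVA) are left to standard tools on the exported tables.
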