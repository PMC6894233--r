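---
title: "Methods: longitudinal HR-pQCT lesion analysis with pqctlong"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal HR-pQCT lesion analysis with pqctlong}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pqctlong)
```

## The measurement problem

Psoriatic arthritis damages peripheral joints in two opposite directions at
once: catabolic *erosions* (breaks in the outer cortical margin with
underlying bone loss) and anabolic *enthesiophytes* (new bone growing
outward from the periosteal cortex at capsule, ligament and tendon
insertions). High-resolution peripheral quantitative CT (HR-pQCT) resolves
both at 82 um isotropic voxels at the second and third metacarpal heads
(MCH2, MCH3). Whether an individual lesion *changed* over years is,
however, a measurement question: two scans of the same hand are acquired
in different positions and with different axial coverage (a 110-slice,
9.02 mm baseline stack against a 322-slice, 26.404 mm follow-up stack),
volumes are read semi-automatically with reader-dependent error, and a
volume difference is only evidence of biology once it exceeds the
measurement-error floor.

`pqctlong` implements that measurement chain end to end:

1. **baseline-indexed rigid co-registration** of the follow-up volume onto
   the baseline grid by mutual-information maximization, with trilinear
   re-slicing (the baseline is never resampled);
2. **slice matching and ROI definition** producing co-localized
   measurement regions at both time points;
3. **seeded region-growing volumetry** of individual erosions and
   enthesiophytes, paired across time points;
4. **smallest detectable change** (SDC) estimation from repeated readings,
   `SDC = 1.96 x SD(change scores) / (sqrt(2) x sqrt(k))`, and
   SDC-thresholded classification of each lesion as progression, stable or
   regression (new lesions count as progression);
5. **cohort statistics**: DAPSA-based patient grouping (sustained low
   disease activity; long-term TNF-inhibitor exposure) and lesion-level
   group comparisons by uncorrected Pearson chi-square and
   normality-gated location tests.

Because no patient scans ship with the package, every stage is exercised
against a **digital phantom** whose ground truth — lesion masks and
volumes at both time points, the rigid motion between acquisitions — is
known exactly, and against a **tabular cohort generator** reproducing the
statistical structure of a 60-patient, 5-year cohort.

## The phantom

`make_phantom()` renders two metacarpal heads as hemispherically capped
cylindrical shafts with a cortical shell (default outer radius 3.5 mm,
thickness 0.6 mm) over a trabecular interior, in one grid at 0.082 mm
isotropic spacing. The intensity model is three-level piecewise-constant
(background 100, trabecular 800, cortical bone 2000, arbitrary units —
scanner calibration in mg HA/cm^3 is out of scope) plus optional additive
Gaussian noise; `noise_sd = 100` corresponds to 5% of cortical intensity.
MCH2 is rendered at 90% of the MCH3 radius, which both reflects anatomy
and breaks the in-plane mirror symmetry that would otherwise make
principal-axis initialization ambiguous. Axial slice 1 is the distal end
of the scan; physical coordinates are `(index - 1) * spacing` with no
origin offset.

**Lesions.** `implant_lesion()` selects the `round(volume / voxel)`
eligible voxels nearest to a cortical surface anchor — inside the
periosteal mask for erosions (a spherical-cap-like carve, set to
background intensity), outside it for enthesiophytes (a dome of
bone-intensity voxels). Rank selection with a deterministic tie-break
achieves the target volume to within half a voxel (5.5e-4 mm^3 at this
spacing), makes masks at different volumes nested (growth contains its
past), and guarantees `volume = mask cardinality x voxel volume` exactly.
An erosion must break the cortical shell on at least two consecutive
axial slices — the imaging definition of an erosion — or it is rejected.

**Follow-up.** `make_followup()` re-renders the (delta-updated) anatomy on
an axially extended grid and samples it into a moved frame. The follow-up
stack is longer (default 322 slices) and starts 80 slices distal to the
baseline scan start, so even under identity motion the ground-truth
transform carries a 6.56 mm axial offset that registration must recover —
mirroring the real acquisition protocol. The user motion is applied about
the baseline grid centre (repositioning rotates the anatomy, not the
scanner origin).

## Registration

`register_rigid()` maximizes the mutual information (in nats) of a 32-bin
joint histogram over the overlap of the baseline volume and the follow-up
volume resampled through the candidate transform, with per-volume min/max
intensity normalization. The optimizer is a deterministic derivative-free
pattern search over the 6 pose parameters (rotations about the fixed
foreground centroid plus translation), with steps halved whenever no
parameter move improves the metric, under a fixed coarse-to-fine schedule
(downsampling factors 4, 2, 1 by block averaging). Determinism was chosen
over stochastic optimizers for testability: identical inputs give
identical transforms.

Initialization follows the coarse-alignment recipe — match intensity
centroids, rotate the principal axes of the thresholded moving foreground
onto the fixed ones. Two practical complications arise from the differing
fields of view and are handled explicitly:

* the moving volume's principal axes can be tilted or *reordered* by
  field-of-view truncation, so the axis correspondence is resolved over
  all 24 proper signed permutations toward the smallest rotation, and the
  optimizer races the principal-axes start against a centroid-only
  (identity rotation) fallback through the coarsest level, keeping the
  better mutual-information basin;
* the centroid match is systematically biased along the scan axis (the
  two stacks cover different amounts of shaft), so the coarsest level
  begins with a deterministic axial-translation sweep (default +/- 4 mm
  at coarse-voxel steps).

The final full-resolution MI is guaranteed not to fall below the MI at
initialization. `resample_to_baseline()` re-slices by trilinear
interpolation and flags voxels whose pre-image leaves the moving volume;
flagged voxels are excluded from all downstream measurement.

Tolerances: the search stops when rotation steps fall below 0.02 degrees
and translation steps below 0.005 mm; on noiseless phantom pairs with
motions up to 10 degrees and 2 mm, the test suite requires recovery
within 0.5 degrees and 0.5 voxel.

## Slice matching, ROI and volumetry

`match_slices()` returns the maximal contiguous axial range over which the
registered follow-up has valid data across the baseline's in-plane bone
extent (ranges containing no bone do not qualify). `define_roi()`
restricts the periosteal mask to that range, removes the three proximal
and three distal boundary slices, and drops connected components that do
not reach the proximal face (phalangeal stubs and debris; metacarpal
shafts continue proximally). Trimming is applied whenever no lesion
touches the would-be-trimmed slabs; otherwise the slices are kept with a
warning so the guard band never clips a lesion.

`segment_lesion()` reproduces semi-automated reading as seeded region
growing (6-connectivity) with fixed thresholds: an erosion grows over
low-intensity voxels *inside* the reference periosteal surface from a
seed point, and is flagged if it fails to contact a cortical break on two
consecutive slices; an enthesiophyte grows over bone-intensity voxels
*outside* that surface. The reference surface is always the *baseline*
periosteal envelope (ground truth on phantoms, or `segment_periosteal()`:
threshold, spherical closing, per-slice hole fill), carried unchanged
into follow-up space — so anabolic growth is measured against a fixed
anatomical datum and deltas are well-defined. Baseline seeds are
propagated to the follow-up reading; follow-up-only seeds accommodate new
lesions.

Each growth threshold sits midway between the two intensity levels that
meet at the boundary it detects: erosion cavities against trabecular bone
(450), cortical bone against trabecular tissue (1400, for the periosteal
surface), and enthesiophytes against *background* (1050). The midway
choice makes thresholding interpolation-neutral: after trilinear
re-slicing the blurred boundary crosses the threshold where the true
boundary was, so re-sliced volumes are asymptotically unbiased. A single
threshold cannot be neutral at every face of an erosion (its cavity
borders both trabecular and dense cortical bone), leaving a small
negative bias on re-sliced erosion volumes that stays well inside the
0.5 mm^3 SDC across the tested 0.5–15 mm^3 range. This is also why the
test suite judges absolute volumetric accuracy (within max(5%, 2 voxels))
on the native acquisition grid, while *changes* measured through the full
registration chain are judged against the SDC of the lesion's kind.

`pair_lesions()` matches lesions across time points by greedy
nearest-centroid assignment among same-kind, same-compartment records
within a 1.0 mm gate (about 12 voxels), ties broken by lesion id.
Unmatched follow-up lesions are *new* (their change equals their
follow-up volume, and they count in follow-up totals); unmatched baseline
lesions are *lost*.

## SDC and progression classification

`smallest_detectable_change()` implements the Bland–Altman-type floor
`1.96 x SD(change scores) / (sqrt(2) x sqrt(k))` with the n-1 SD
denominator; with per-reading error sigma and k = 2 the estimate
converges to `1.96 x sigma / sqrt(2)`, and the scaling law
`SDC(k) = SDC(2) x sqrt(2/k)` holds identically. The package honours the
study-design thresholds — 0.5 mm^3 for erosions, 0.3 mm^3 for
enthesiophytes — as configuration (`default_sdc()`), so classification is
reproducible independently of any re-estimated SDC. Whether `k` counts
readings or readers is immaterial at the k = 2 design used here; the
implementation treats it as readings.

`classify_lesion_change()` uses strict exceedance: progression iff
`delta > SDC` or the lesion is new; regression iff `delta < -SDC`;
stable otherwise. A delta of exactly +0.5 mm^3 against an SDC of 0.5 is
stable. Deltas are compared at full floating precision.

## The cohort generator

`cohort_spec()` describes a two-time-point cohort; its defaults are the
study conditions: 60 patients, Poisson lesion counts averaging 108
baseline erosions and 99 enthesiophytes (the per-patient count
distribution is not published, so a Poisson rate is the exposed free
parameter), about 3 new erosions and no new enthesiophytes over
follow-up, progression/stable/regression mixtures of 37/64/10 over 111
(erosions) and 50/38/11 over 99 (enthesiophytes), 26/60 patients
sustaining the DAPSA low-disease-activity target and 14/60 on a TNF
inhibitor throughout, and progression odds that depend on sustained-LDA
status (erosions 12/51 vs 25/60; enthesiophytes 17/40 vs 33/59 — these
per-group rates marginalize back to the overall mixture).

Three modelling choices deserve explanation:

* **Class-consistent change laws.** The published per-class change
  statistics (e.g. progressing erosions grew 1.9 +/- 1.8 mm^3) describe
  subgroups *defined* by the SDC thresholds. The generator therefore
  draws each class's change inside its own region with the stated mean
  and SD matched exactly: threshold plus a gamma-distributed exceedance
  for the one-sided classes (right-skewed, as threshold-selected change
  data are — no truncated normal can even represent an SD of 1.8 above a
  cut only 1.4 below the mean), and a moment-matched truncated normal
  within the +/- SDC band for the stable class. Every drawn class is then
  consistent with the classification of its drawn change. Regression
  magnitudes are additionally capped by the lesion's own baseline volume
  (you cannot lose more than you have): regressing lesions have their
  baseline volume drawn conditional on exceeding the SDC — regressors are
  the larger lesions — and complete resorption bounds the loss, which
  slightly attenuates the deepest losses relative to the printed subgroup
  mean while leaving the class mixture exact.
* **Observed change equals drawn change by default.** Because the printed
  mixture is an observed-data summary, it already embeds reading error;
  adding fresh reader noise on top would double-count measurement error
  and inflate the observed progression fraction far above the published
  one. `apply_reading_noise = TRUE` enables that layer for sensitivity
  analyses; the repeated-reading machinery
  (`simulate_repeated_readings()`) always models reader noise explicitly,
  at a per-reading SD (0.36 / 0.22 mm^3) calibrated so the implied SDC
  matches the published thresholds.
* **DAPSA components.** The DAPSA is the sum of tender joints, swollen
  joints, patient pain VAS (cm), patient global VAS (cm) and CRP (mg/dL)
  — the component formula comes from the instrument, as the study cites
  it. Group-conditional score trajectories (sustained-LDA patients hold
  scores in (0, 14] at both time points) are decomposed into plausible
  components that re-sum to the score exactly. Baseline lesion volumes
  are gamma-distributed at the printed scales (erosions 4.2 +/- 4.2,
  enthesiophytes 3.4 +/- 2.3 mm^3).

## Cohort statistics

Group comparisons are lesion-level (denominators like 12/51 vs 25/60),
matching the published tables; patient-level clustering is acknowledged
and not modelled — a per-lesion covariate table can be exported for any
external mixed-model fitter, which is out of scope here. Progression
counts are compared by Pearson chi-square *without* continuity
correction: the uncorrected statistic reproduces the published erosion
p-values (0.043 and 0.751) from their printed 2x2 tables, the corrected
one does not. `permutation_chisq_p()` provides an independent conditional
permutation oracle; it reports the *mid-p* (half weight on ties), which
is the quantity the asymptotic chi-square p approximates — the inclusive
tail of the discrete conditional distribution exceeds the asymptotic p by
up to ~0.1 at these table sizes, a gap verified by hypergeometric
enumeration, so oracle comparisons allow the enumerated residual error on
top of Monte-Carlo noise.

Location comparisons gate on normality (Shapiro–Wilk at alpha = 0.05 —
the source protocol says only that Gaussianity was tested) and then apply
Welch's t or the Mann–Whitney test; paired baseline-vs-follow-up change
uses the paired t or Wilcoxon signed-rank test under the same gate, with
all-zero differences reported as p = 1 with a flag. One power note: with
111 erosions whose mean change is ~0.6 mm^3 against an SD of ~1.5, the
paired noncentrality is ~4.0, so detection at the 0.001 level succeeds in
only ~70–75% of simulated cohorts (the enthesiophyte series, with
noncentrality ~5.8, exceeds 95%); the test suite asserts these
oracle-derived rates rather than a uniform one.

## Problem sizes and runtime choices

Tests and the acceptance script exercise the image chain on reduced
phantoms — registration sweeps at roughly 64 x 48 x 88 voxels (head
radius 1.4 mm), volumetry sweeps at 76 x 110 x 196 voxels (radius
2.4 mm, large enough to host 15 mm^3 lesions with clearance) — with the
full 110/322-slice, 3.5 mm-radius geometry reserved for single-shot
checks such as the re-slicing round-trip. These sizes keep each
registration in seconds while preserving the surface-to-volume regime
that drives interpolation error. Reliability and classification
properties run at n = 10,000; cohort-level checks use the study's own
n = 60 patients with 40 replicate cohorts where replicate rates are
asserted.

## Known limitations

* The phantom has no trabecular microarchitecture, beam hardening or
  motion-artifact grading; its three-level intensity model makes
  threshold-based segmentation easier than on real scans, so passing
  volume-recovery tests demonstrates correctness of the chain, not
  clinical segmentation performance.
* Registration assumes the bones are rigid between visits (true for
  metacarpal heads short of fracture) and is single-modality by design.
* Seeds are inputs, as in semi-automated reading; there is no automatic
  lesion detection.
* Quadrant labels (palmar/ulnar/dorsal/radial) are annotations on
  lesions, not geometric partitions with their own measurements.
* Group comparisons ignore within-patient correlation of lesions, as the
  published lesion-level tables do.
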