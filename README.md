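# pqctlong

Longitudinal HR-pQCT analysis of bone erosions and enthesiophytes at the
metacarpal heads.

## What this is for

In psoriatic arthritis, chronic inflammation produces both catabolic bone
damage — *erosions*, breaks in the outer cortical margin with underlying
bone loss — and anabolic damage — *enthesiophytes*, new bone growing
outward from the periosteal cortex. High-resolution peripheral
quantitative CT (HR-pQCT, 82 um isotropic voxels) can follow individual
lesions at the second and third metacarpal heads over years, but turning
two scans into a per-lesion verdict of *progression*, *stable* or
*regression* is a measurement-chain problem: the scans are acquired in
different positions with different axial coverage (110 baseline slices,
9.02 mm, against 322 follow-up slices, 26.404 mm), lesions are read
semi-automatically, and a volume difference only counts as change once it
exceeds the measurement-error floor.

`pqctlong` implements that chain for imaging methodologists and
rheumatology researchers, driven entirely by simulation (a digital
phantom with exact ground truth, and a tabular cohort generator), so no
patient data is needed to develop, test or teach the method:

* **Phantom** (`phantom_spec()`, `make_phantom()`, `implant_lesion()`,
  `make_followup()`) — two cortical-shell metacarpal heads with implanted
  lesions of exactly known volume, rendered at both time points under a
  known rigid motion plus the axial acquisition offset.
* **Registration** (`initialize_transform()`, `register_rigid()`,
  `resample_to_baseline()`) — baseline-indexed rigid co-registration by
  mutual-information maximization (32-bin joint histogram, deterministic
  multi-resolution pattern search) and trilinear re-slicing into baseline
  space; the baseline volume is never resampled.
* **VOI** (`match_slices()`, `define_roi()`) — slice-matched, co-localized
  measurement regions: metacarpal bone only, boundary slices trimmed,
  non-metacarpal components removed.
* **Volumetry** (`segment_periosteal()`, `segment_lesion()`,
  `pair_lesions()`) — seeded region growing against a fixed baseline
  periosteal reference surface; erosions must break the cortex on two
  consecutive slices; lesions are paired across time points by
  nearest-centroid matching with new/lost handling.
* **Reliability and classification** (`smallest_detectable_change()`,
  `classify_lesion_change()`, `summarize_dynamics()`,
  `cumulative_probability_data()`) — the smallest detectable change from
  repeated readings,

  `SDC = 1.96 x SD_delta(change scores) / (sqrt(2) x sqrt(k))`,

  and strict-exceedance classification against per-kind thresholds
  (defaults 0.5 mm^3 for erosions, 0.3 mm^3 for enthesiophytes; a new
  lesion is always progression).
* **Cohort statistics** (`simulate_cohort()`, `dapsa_score()`,
  `assign_groups()`, `compare_progression_counts()`,
  `compare_mean_deltas()`, `paired_change_test()`, `build_report()`) —
  DAPSA-based patient grouping (sustained low disease activity = DAPSA
  <= 14 at both time points; long-term TNF-inhibitor exposure),
  uncorrected Pearson chi-square on lesion-level 2x2 progression tables,
  and normality-gated paired/two-group change tests.

## Worked example

Simulate a paired acquisition with four lesions, recover the motion, and
classify the five-year changes (this is `analysis/01` + `analysis/02`
condensed; all numbers below are the scripts' actual output):

```r
library(pqctlong)

spec <- phantom_spec(grid_shape = c(72L, 84L, 160L),
                     cortex_outer_radius_mm = 2.0,
                     cortex_thickness_mm = 0.5,
                     noise_sd = 100, seed = 11L)   # 5% of bone intensity
ph <- make_phantom(spec)
ph <- implant_lesion(ph, "erosion",
                     surface_point(ph, "MCH3", "palmar"), 4.2, "E1")
ph <- implant_lesion(ph, "enthesiophyte",
                     surface_point(ph, "MCH3", "radial"), 3.4, "B1")

fu <- make_followup(ph,
  motion = rigid_transform(angles_rad = c(4, 1, -2) * pi / 180,
                           translation_mm = c(0.6, -0.25, 0.3)),
  volume_deltas_mm3 = c(E1 = 0.9, B1 = 1.0),
  followup_slices = 150L, distal_margin_slices = 24L)

q <- quantify_pair(ph, fu)
q$dynamics[, c("lesion_id", "kind", "vol_t0_mm3", "vol_t5_mm3",
               "delta_mm3", "category")]
```

Running the full four-lesion version through the file-based pipeline
(`analysis/01_simulate_phantom.R`, then `analysis/02_register_quantify.R`)
prints:

```
Registration: MI 0.426 -> 0.643 (700 metric evaluations)
Recovered motion within 0.099 deg of truth
Co-localized slices 4..69; ROI of 194826 bone voxels
Measured vs true volume change (mm^3):
  B1 enthesiophyte +1.00 (true +1.00) -> progression
  B2 enthesiophyte +0.10 (true +0.10) -> stable
  E1 erosion       +0.70 (true +0.90) -> progression
  E2 erosion       -0.87 (true -0.80) -> regression
```

The registration recovered the simulated repositioning (4.6 degrees plus
a 1.97 mm axial acquisition offset) to 0.099 degrees; each measured
change lands within one smallest-detectable-change of its implanted
truth, and the classification calls follow: +1.00 exceeds the 0.3 mm^3
enthesiophyte threshold (progression), +0.10 does not (stable), and the
erosion changes clear the 0.5 mm^3 threshold in either direction.

The reliability step (`analysis/03_sdc_reliability.R`) re-derives the
thresholds from simulated repeated readings — 30 erosions and 25
enthesiophytes scored twice:

```
erosion: SDC 0.570 mm^3 from 30 lesions read twice (large-n limit 0.497)
enthesiophyte: SDC 0.234 mm^3 from 25 lesions read twice (large-n limit 0.304)
```

and `analysis/04_cohort_statistics.R` simulates the 60-patient cohort and
prints the study-style report (lesion counts, paired change tests,
per-category summaries, chi-square group comparisons), writing every
table under `results/`.

## Repository layout

```
R/, src/          package code (R + Rcpp)
analysis/         numbered narrative drivers: 01 simulate phantom pair,
                  02 register + quantify, 03 SDC reliability,
                  04 cohort statistics; tables go to results/,
                  volumes to scratch/
scripts/          acceptance.R (see above)
tests/testthat/   unit, property and acceptance test suites
vignettes/        methods vignette (model, assumptions, parameter
                  choices, limitations)
```
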