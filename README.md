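# tiltQA

Quality assurance of auto-segmented head-and-neck radiotherapy contours,
stratified by neck tilt.

Deep-learning auto-segmentation (DLAS) tools are trained mostly on
patients positioned with little neck flexion or extension. For patients
set up with pronounced sagittal neck tilt, auto-contours of organs that
move with the cervical spine — the parotid glands in particular — can
degrade substantially, with direct dosimetric consequences. tiltQA is an R
package for medical physicists and image-analysis researchers who want to
measure that effect in a cohort: it quantifies neck tilt from cervical
spinal-cord segmentations, splits the cohort into normal/abnormal tilt
groups, scores auto-contours against gold-standard contours, propagates
the geometric differences into mean-dose differences, and tests the groups
for significant differences.

## What it computes

**Neck tilt.** The spinal cord is restricted to the axial slices spanned
by the C1–C4 vertebrae; a 3D PCA of the retained voxel coordinates gives
the dominant cord direction `v` (oriented superiorly), and the tilt angle
is the sagittal angle between `v` and the longitudinal axis,

    theta = atan2(-v_y, v_z)    (LPS; flexion positive, extension negative)

cross-checked against the slope of a least-squares line through the four
vertebral centroids in the sagittal plane. Cohort thresholds are
nearest-rank percentiles (12th/88th by default, labelling exactly 8 of 35
patients abnormal); a patient is abnormal iff its tilt falls strictly
outside the closed threshold interval.

**Contour agreement.** For gold mask A and test mask B on one grid, with
boundary-face surfaces S_A, S_B (face centres and areas) and
nearest-face-centre distances d:

- volumetric Dice `DSC = 2|A∩B| / (|A|+|B|)`,
- surface Dice at tolerance τ (2 mm default):
  `sDSC = (area{e∈S_A : d(e,S_B)≤τ} + area{e∈S_B : d(e,S_A)≤τ}) / (area S_A + area S_B)`,
- mean distance to agreement (symmetric, area-weighted):
  `MDA = (Σ_A a_e d(e,S_B) + Σ_B a_e d(e,S_A)) / (area S_A + area S_B)`.

**Dose.** Mean dose is the average of the dose trilinearly interpolated at
the structure's voxel centres; the signed difference is test − gold, and
records whose gold mean dose is below 5 Gy are excluded from cohort
statistics.

**Statistics.** Each (structure, source, metric) cell is compared between
tilt groups with a two-tailed Wilcoxon rank-sum test (exact for small
tie-free samples, tie-corrected normal approximation otherwise), tiered at
p < 0.05 (`*`) and p < 0.01 (`**`), with medians and abnormal − normal
median differences. No multiple-testing correction is applied.

Because real cohorts with curated gold-standard contours cannot be
shipped, the package includes a deterministic phantom-cohort generator
(tilted cord cylinder, stacked vertebral boxes, lateral parotid-like
ellipsoids whose simulated vendor error grows with tilt deviation, a
tilt-insensitive control organ, Gaussian dose grids) that provides ground
truth for every stage; see the methods vignette
(`vignettes/neck-tilt-contour-qa.Rmd`).

## Worked example

```r
library(tiltQA)

cfg <- generator_config(n_patients = 35, seed = 1, n_vendors = 2)
res <- run_all(simulate = cfg, out_dir = "qa_report")

res$stratification
#> <cohort_stratification> n=35, thresholds [-2.00, 34.10] deg (pct 12/88): 27 normal, 8 abnormal

subset(res$results, source == "vendor1" & structure == "parotid_l",
       select = c(metric, median_diff, p, tier))
#>          metric median_diff          p tier
#>             dsc -0.06102834 0.01569430    *
#>            sdsc -0.21740370 0.02334604    *
#>          mda_mm  0.55529431 0.01569430    *
#>     abs_diff_gy  0.56135777 0.04998154    *
#>  signed_diff_gy  0.92844013 0.31593176   ns
```

The 35 phantom patients split 27 normal / 8 abnormal at tilt thresholds of
−2.0° and 34.1°. For the left parotid under the first simulated vendor,
the abnormal group's median surface Dice is 0.22 lower and its median MDA
0.56 mm higher than the normal group's, both significant at p < 0.05 —
while the brainstem-like control organ shows no significant difference on
any metric. `qa_report/` holds the per-stage CSVs (`tilt.csv`,
`cohort.csv`, `metrics.csv`, `dose.csv`, `results.csv`), box-plot
summaries, tilt histogram bins, and a `run_log.json` with every constant
and seed.

A thin command-line wrapper with `simulate` / `tilt` / `stratify` /
`metrics` / `dose` / `analyze` / `run-all` subcommands is installed at
`inst/cli/tiltqa.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/tiltqa.R", package="tiltQA"))')" \
    run-all --simulate --n 35 --seed 1 --out qa_report
```

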