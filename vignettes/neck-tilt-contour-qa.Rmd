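---
title: "Neck-tilt stratified QA of auto-segmented head-and-neck contours"
author: "tiltQA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neck-tilt stratified QA of auto-segmented head-and-neck contours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiltQA)
```

## The problem

Deep-learning auto-segmentation (DLAS) tools contour organs at risk (OARs)
on head-and-neck planning CTs, but their training data are dominated by
patients positioned with little neck flexion or extension. When a patient
is set up with pronounced sagittal neck tilt, auto-contours of organs that
move with the cervical spine — the parotid glands in particular — can
degrade, while rigidly anchored midline structures such as the brainstem
are much less affected. tiltQA packages the full analysis chain needed to
detect and quantify that failure mode in a cohort:

1. measure each patient's neck tilt from a cervical spinal-cord
   segmentation,
2. stratify the cohort into *normal* and *abnormal* tilt groups by
   percentile cutoffs,
3. score every auto-contour against a gold-standard contour geometrically
   (volumetric Dice, surface Dice at a tolerance, mean distance to
   agreement) and dosimetrically (mean-dose difference under the clinical
   dose grid), and
4. test whether the two tilt groups differ, per organ and per
   auto-segmentation source, with two-tailed Wilcoxon rank-sum tests.

All spatial data are axis-aligned 3D grids in the LPS convention
(x right-to-left, y anterior-to-posterior, z inferior-to-superior), read
and written as NIfTI-1 with voxel-centre semantics. Oblique acquisitions
are rejected rather than silently resampled; resampling policy is outside
the package's scope, and geometric metrics require each gold/test pair to
share one grid.

## Tilt measurement

The tilt measurement uses the spinal cord restricted to the longitudinal
extent of the first four cervical vertebrae: a cord voxel is kept when its
axial slice contains at least one foreground voxel of the C1–C4 union.
"Longitudinal extent" is deliberately a slice-range notion, not a 3D
intersection — the cord never intersects the vertebral bodies themselves.

A principal component analysis of the retained voxels' physical
coordinates gives the dominant cord direction. The PCA is performed in 3D
and the first principal component is then projected to the sagittal
(y, z) plane; this differs from a 2D PCA on (y, z) when lateral spread
dominates, and the 3D-then-project form is the one implemented. The
principal vector is oriented superiorly (`vz >= 0`) and the tilt angle is

\[
\theta = \operatorname{atan2}(-v_y, v_z)\,,
\]

so that in LPS an anterior lean of the superior cord — flexion, chin
toward chest — is positive, and extension is negative. The coordinate
handedness behind this sign choice is a package convention; it is
self-consistent and verified by construction in the test suite (mirroring
all y coordinates negates the angle exactly, rotating the point cloud
about x by φ adds φ).

Two degenerate cases are rejected explicitly: fewer than 20 voxels (the
covariance of a handful of 2 mm-slice samples is unreliable) and
coincident points. Near-ties between the two largest eigenvalues are
resolved deterministically (eigenvalue order, then sign convention) and
flagged in the result.

As an internal cross-check, the centroids of the four vertebrae are fit by
least squares in the sagittal plane (y regressed on z — the regression
direction is a package choice) and the slope angle `atan(-a)` is reported
next to the PCA angle, with an agreement flag at a 2° tolerance. On
phantom cohorts the two estimators agree to well under 2° per patient with
correlation above 0.99.

### Stratification

Cohort thresholds are *nearest-rank* percentiles: the value at rank
`ceiling(p/100 * n)` of the sorted tilts, at the 12th and 88th percentile
by default. A patient is abnormal iff the tilt falls strictly outside the
closed threshold interval. This convention is pinned because it is the
simple convention that labels exactly 8 of 35 patients abnormal (4 in each
tail) at 12/88 — the cohort balance the analysis is designed around.

## Contour agreement metrics

The surface operand of the surface metrics is the set of boundary voxel
faces: every face between a foreground voxel and a background voxel (the
volume is implicitly padded with background, so structures touching the
array edge still contribute faces). Each face carries its centre point and
its area — the product of the two spacing components orthogonal to its
normal. Marching-cubes style surfaces were rejected deliberately: the face
representation admits an exact brute-force oracle, so the accelerated
implementation (a uniform-grid spatial index over face centres, written in
C++) can be verified *exactly* against an O(n²) all-pairs computation, and
is in the test suite, down to set membership at the tolerance.

With surfaces \(S_A, S_B\) and nearest-face-centre distances \(d\):

- **DSC** \(= 2|A\cap B| / (|A|+|B|)\) by voxel counts;
- **surface DSC at τ** \(=\big(\mathrm{area}\{e \in S_A : d(e,S_B) \le
  \tau\} + \mathrm{area}\{e\in S_B : d(e,S_A)\le\tau\}\big) /
  (\mathrm{area}\,S_A + \mathrm{area}\,S_B)\), default τ = 2 mm;
- **MDA** \(=\big(\sum_{e\in S_A} a_e d(e,S_B) + \sum_{e\in S_B} a_e
  d(e,S_A)\big) / (\mathrm{area}\,S_A + \mathrm{area}\,S_B)\).

MDA is implemented symmetric and area-weighted; directed and
element-count variants exist in the literature and the choice is stated
here and in the function documentation. Distances are Euclidean between
face centres; no subvoxel surface interpolation is attempted. An empty
test mask produces a *missing* record (status `"missing_empty_mask"`)
rather than a 0 or an infinity, and such records are dropped from cohort
statistics — silently scoring an empty auto-contour as 0 would conflate
"tool failed to produce a structure" with "tool produced a bad structure".

## Dose analysis

Mean dose over a structure is the average of the dose trilinearly
interpolated at the physical centres of the structure's foreground voxels.
The dose grid is *not* resampled onto the mask grid: trilinear sampling at
voxel centres is exact for dose fields linear in position (a property the
tests exercise), introduces no resampling artifacts, and keeps an analytic
oracle. A mask voxel outside the dose grid's physical extent is an error
naming the voxel; silent clamping would bias mean doses near the grid
edge.

The signed mean-dose difference is defined as **test − gold**, so negative
values mean the auto-contour sits in lower-dose tissue than the gold
contour; the convention is recorded in output headers because the
opposite order is equally defensible. Records whose *gold* mean dose is
below 5 Gy are flagged excluded — they carry their values but are omitted
from cohort statistics, since mean-dose differences in near-zero-dose
regions are clinically meaningless noise.

## Cohort statistics

Each (structure, source, metric) cell is compared between the normal and
abnormal groups with a two-tailed Wilcoxon rank-sum (Mann–Whitney U) test:
exact p by the U distribution when the combined sample is at most 20 with
no ties, otherwise the normal approximation with tie-corrected variance
and continuity correction (the typical cohort split of 27 vs 8 uses the
approximation). When every pooled value is identical the tie-corrected
variance vanishes and p = 1 is returned explicitly. The method actually
used is logged per test. Median differences are reported as
abnormal − normal, so degradation appears as negative Dice deltas and
positive MDA deltas. **No multiple-testing correction is applied** — each
cell is tested at raw p < 0.05 with a second tier at p < 0.01, which is
the convention of per-organ per-vendor QA summaries; users scanning many
cells should keep the resulting false-positive rate in mind. Cells where
either group has fewer than 2 usable records are flagged untestable
rather than given a p-value.

## The phantom cohort generator

Real head-and-neck cohorts with gold-standard contours cannot ship with a
package, so every stage is validated against a synthetic phantom cohort
with known ground truth. The generator emulates the statistical structure
the analysis assumes:

- **Tilt**: Normal(12°, 15°) truncated to [−25°, 70°], spanning roughly
  −20° to 66° with a median near 12° — the range reported for clinical
  head-and-neck setups with occasional severe flexion.
- **Anatomy**: a 60 mm cord cylinder of radius 5 mm along the tilted axis
  `(0, −sin θ, cos θ)`; four 15 mm vertebral boxes stacked along the same
  axis; two parotid-like ellipsoids (semi-axes 12 × 18 × 22 mm) placed
  ±35 mm laterally of the cord's superior end; one brainstem-like control
  ellipsoid (10 × 10 × 20 mm) at the superior midline. CT spacing is
  1.27 × 1.27 × 2 mm.
- **Vendor error**: each simulated vendor's test mask is the gold mask
  translated by a per-axis Gaussian with SD
  `σ(θ) = σ0 + k · max(0, |θ − 12°| − Δ)` (σ0 = 1 mm, k = 0.15 mm/deg,
  deadband Δ = 15°), then dilated or eroded by a random radius of 0 or 1
  voxels. The deadband makes patients across the normal tilt range
  statistically indistinguishable, reproducing the flat normal-cohort
  scatter the analysis should report; beyond it, error grows linearly with
  tilt deviation. The control organ always uses σ0 — it is the built-in
  negative control.
- **Dose**: an isotropic Gaussian, 70 Gy peak, 30 mm SD, centred 40% of
  the way up the cord axis (an oropharyngeal-target-like position) and
  jittered per patient by Normal(0, 10 mm) per axis. Under these defaults
  most gold organs receive well above 5 Gy mean dose, and a few per cohort
  fall below it, so the exclusion rule is exercised without dominating.

Rigid translation plus light morphology was chosen over elastic
deformation deliberately: it is the simplest error model that produces the
tilt-dependent metric degradation the cohort statistics must detect, and
it admits exact bookkeeping (`truth.json` stores every applied
perturbation). Grids are purpose-sized per structure — a spine grid shared
by cord and vertebrae, a grid per organ shared by gold and vendor masks
with a 16 mm margin for perturbations, and a coarser 2.5 mm dose grid, as
clinical dose grids are coarser than CT. Downstream stages never assume a
single common grid per patient. Geometry placements not listed above
(vertebral box width/depth of 20 mm, parotid centres 5 mm inferior of the
cord tip, control organ 15 mm superior) are single fixed choices of
plausible cervical anatomy.

The same configuration and seed reproduce a cohort bit for bit. What the
phantoms do **not** emulate: real CT intensities (no HU image exists, and
none is needed by any stage), elastic or anatomy-specific contour errors,
inter-observer variability in the gold standard, and realistic dose
distributions from optimized plans. Passing tests therefore demonstrate
that the measurement chain is correct and sensitive to a tilt-dependent
error signal of realistic magnitude — not that any particular commercial
tool degrades, which only real cohorts can show.

## Numerical choices and problem sizes

- PCA requires ≥ 20 cord voxels; covariance eigen-decomposition uses the
  symmetric solver with a deterministic tie-break.
- Nearest-surface distances use a uniform-grid index with cell size twice
  the largest spacing; the search is exact (shell lower bounds), not
  approximate.
- Affines are accepted as axis-aligned when each column of the rotation
  block has a single non-negligible entry (relative tolerance 1e-4);
  anything else is an unsupported-orientation error.
- Percentile thresholds are inclusive at both ends; box-plot whiskers use
  the 1.5 × IQR rule.
- Validation studies in the tests use 35-patient cohorts (the design
  cohort size) with two simulated vendors; the repeated-seed significance
  study uses 100 cohorts, and the bundled acceptance script summarizes 60.
  These sizes give stable fractions while keeping a full run of the suite
  comfortable on one CPU.

## A worked run

```{r example, eval = FALSE}
cfg <- generator_config(n_patients = 35, seed = 1, n_vendors = 2)
res <- run_all(simulate = cfg, out_dir = "qa_report")

res$stratification          # thresholds and the 27/8 split
subset(res$results, metric == "sdsc" & structure == "parotid_l")
plot_tilt_histogram(res$tilt, res$stratification)
plot_metric_deltas(res$results, "sdsc")
```

On disk, `qa_report/` then holds the per-stage CSVs (`tilt.csv`,
`cohort.csv`, `metrics.csv`, `dose.csv`, `results.csv`), the box-plot
summary (`boxstats.csv`), the tilt histogram bins (`tilt_hist.csv`), and
`run_log.json` with every constant and seed that shaped the run. Re-running
with the same configuration reproduces the CSVs byte for byte.

## Known limitations

- Only axis-aligned NIfTI volumes are supported; DICOM RTSTRUCT/RTDOSE
  ingest and polygon rasterization are out of scope by design.
- Geometric metrics require shared grids per gold/test pair; cohorts whose
  vendors resample the CT must be harmonized upstream.
- The Wilcoxon tests are unpaired two-group comparisons; paired or
  mixed-effects designs across vendors are not modelled.
- Surface distances are face-centre to face-centre; for structures a few
  voxels across, the discretization of the surface dominates the metric.
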