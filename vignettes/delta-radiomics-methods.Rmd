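---
title: "Delta-radiomics screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delta-radiomics screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltarad)
```

## The problem and the method

During MR-guided radiotherapy of locally advanced rectal cancer, a
hybrid low-field (0.35 T) unit produces an MR scan at simulation and at
regular intervals during treatment. The question this package
operationalises is whether the *change* of quantitative image features
of the gross tumour volume (GTV) during treatment — "delta radiomics" —
discriminates patients who go on to show a clinical complete response
(cCR) from those who do not.

The pipeline is:

1. **Feature extraction.** Each observation (one patient at one
   cumulative-dose timepoint: `t0`, `t11`, `t22`, `t33`, `t44`, `t55`,
   labels in Gy at 2.2 Gy/fraction, imaging every 5 fractions) is an MR
   volume plus a co-registered binary GTV mask on a 1.5 mm isotropic
   grid. From the raw intensities inside the mask — no image filter is
   applied — a fixed 53-feature panel is computed: 17 first-order
   statistical, 14 morphological, 6 fractal and 16 grey-level run-length
   (GLRLM) features.
2. **Delta features.** For every on-treatment timepoint t and feature f,
   the delta feature is the ratio f(t) / f(t0). A zero or missing
   baseline leaves the cell *undefined* — clamping it to 0 or infinity
   would fabricate data. With 6 timepoints this yields 53 absolute
   baseline features plus 5 × 53 = 265 delta features = 318 testable
   quantities.
3. **Screening.** Each of the 318 quantities is compared between cCR and
   non-cCR patients with an exact two-sided Wilcoxon–Mann–Whitney (WMW)
   test; cells with p < 0.05 are flagged. No multiplicity correction is
   applied by default, mirroring the univariate hypothesis-generating
   design; this inflates the family-wise error rate, which the rendered
   report states prominently, and Benjamini–Hochberg adjustment is one
   switch away (`p_adjust = "BH"`).

The package deliberately stops at univariate screening: multivariable
model building, cross-validation and AUC estimation are out of scope, as
is everything upstream of voxel grids (DICOM-RT contour voxelisation,
inter-scan registration, restaging adjudication).

## The feature panel as a reconstruction

The institutional 53-feature panel that motivated this package is not
published in full; only the four family names, the total count, and the
25 significant feature names are on record. The panel here is therefore
a *convention, not a recovered fact*: it totals exactly 53, contains
every published feature name, and fills the remainder with standard
first-order, shape and run-length definitions. Absolute values of the
completion members should not be compared against the original
implementation; the headline features (`energy`, `glnu`, `L_least`,
`volume`, ...) use their standard textbook definitions, and delta
*ratios* are additionally invariant to any constant factor in a
feature's definition.

## Definitions and numerical choices

**First-order statistics** (17): min, max, range, mean, median, sample
sd and variance, raw median absolute deviation (constant 1), Fisher
bias-uncorrected skewness g1, excess kurtosis g2, energy = Σx²
(unnormalised — the common first-order definition; its confounding with
ROI volume is accepted), histogram entropy (bits) and uniformity, RMS,
IQR, 10th/90th percentiles (type-7 quantiles). The entropy/uniformity
histogram uses **64 equal-width bins** over the ROI range — fixed for
reproducibility. A constant ROI reports skewness = kurtosis = 0,
entropy = 0, uniformity = 1, so every vector stays finite.

**Morphology** (14): volume = voxel count × voxel volume; surface from
an iso-surface mesh at the 0.5 occupancy level (below); principal axis
lengths L_major ≥ L_minor ≥ L_least = 4·√λᵢ of the population
covariance of occupied-voxel physical coordinates (the full axis
lengths of the fitted ellipsoid — for a solid ellipsoid with semi-axes
aᵢ, λᵢ = aᵢ²/5, so L recovers 4aᵢ/√5 ≈ 1.79aᵢ and all axis *ratios*
exactly); elongation √(λ₂/λ₁) and flatness √(λ₃/λ₁);
sphericity = (36πV²)^⅓/A, compactness1 = V/(√π·A^{3/2}),
compactness2 = 36πV²/A³ = sphericity³, sphdispr = A/(4πR²) = 1/sphericity
with R the equivalent-sphere radius, asphericity = 1/sphericity − 1.
Degenerate (collinear/coplanar) ROIs report missing eigenvalues as 0.
The 4·√λ convention is one of several in circulation; delta ratios are
invariant to the constant.

**Surface area.** Meshing the *raw* binary occupancy at the 0.5 level
pins every mesh vertex to an edge midpoint and inflates the area of
smooth shapes by a staircase bias we measured at ≈ +8.5% (marching
cubes) to ≈ +28% (midpoint marching tetrahedra) on a digital 15 mm
ball — enough to push sphericity far from 1 for a sphere. The package
therefore lightly smooths the occupancy field with a Gaussian of
**σ = 0.8 voxel** and extracts the 0.5 iso-surface by marching
tetrahedra with linear edge interpolation; on the 15 mm ball at 1.5 mm
spacing this is accurate to a few tenths of a percent, and it converges
under grid refinement. σ = 0.8 was chosen from that accuracy experiment
across ball radii 6–15 mm (larger σ erodes small lesions, smaller σ
reverts to the staircase). Because the smoothed estimate is unbiased
rather than one-sided, a near-perfect digital ball can report
sphericity marginally above 1 (≈ 1.002); clearly non-spherical shapes
stay strictly below 1. Tiny ROIs whose smoothed field never reaches the
iso-level fall back to meshing the raw occupancy. The exposed-voxel-face
surface remains available (`surface_method = "voxel_face"`) but
overestimates a sphere's area by ~50%.

**Fractal dimension** (6 summaries). Per axial (z) slice containing ROI,
the box-counting dimension of the *binary* ROI region: dyadic box sides
s = 1, 2, 4, … up to half the larger slice dimension, grids anchored at
the slice origin, least-squares slope of log N(s) vs log(1/s) over all
scales. At least three scales are required, otherwise the slice is
skipped (and counted); if every slice is skipped the mask errors. The
six summaries (mean/median/sd/min/max/range of the per-slice profile)
complete the family; members beyond the median and minimum are
panel-completion conventions. Whether the original implementation used
boundary- or region-based, binary or grey-level counting is
unpublished; region/binary is the canonical reading of a "fractal"
family that coexists with a separate texture family, and it admits
exact oracles (a filled plane fits slope 2 exactly). Anchored grids
make the estimate only approximately translation invariant; deviations
stay well under 0.1 when several scales are available.

**GLRLM texture** (16). Intensities are quantized to **Ng = 32**
equal-width levels over the ROI range (fixed-bin-number; a common
radiomics default — the original quantization is unpublished, so the
choice is config-exposed). Runs are maximal same-level voxel sequences
along each of the 13 unique 3D directions, broken by any non-ROI voxel;
features use the classical Galloway forms (sre, lre, glnu and its
normalised variant, rlnu, rlnu_norm, rperc, lgre, hgre, the four joint
variants, glvar, rlvar, run entropy) and are averaged unweighted over
the 13 per-direction matrices rather than computed on a merged matrix
(a 2D/4-direction mode would be a straightforward variant; the 3D mode
is the default). `glnu` keeps the unnormalised classical definition
matching its name. Every matrix satisfies the conservation identity
Σ r(i,j)·j = ROI voxel count, which the tests enforce against an
independent brute-force run enumerator.

**Exact WMW test.** Mid-ranks handle ties. The two-sided p-value is the
probability, over all C(n, n₁) equally likely assignments of the pooled
values to the group sizes, that the group-A rank sum deviates from its
null mean at least as far as observed (mean-symmetric tail rule — fixed
here since only the test's name is on record). The assignment
distribution is computed exactly by a shift (dynamic-programming)
algorithm on doubled mid-ranks, which is mathematically identical to
full enumeration but stays cheap up to the default exact-path bound of
n ≤ 30 (at the study scale, 5 vs 11, there are C(16,5) = 4368
assignments). Above the bound the tie-corrected normal approximation is
used without continuity correction, and the result is tagged with the
path taken. Exactness is tested against an explicit `combn` enumerator
for all n ≤ 12 at 10⁻¹².

## The synthetic cohort

No imaging data accompany the study, so the generator is a first-class
module that emulates the study conditions: **16 patients**, **31%
responders** (5 of 16), **6 scans** each on a shared per-patient grid at
**1.5 mm isotropic** spacing. Each lesion is an axis-aligned ellipsoid
(semi-axes drawn uniformly from 10–18 mm — mid-sized rectal GTVs;
ellipsoids because they admit analytic volume/axis/sphericity oracles; a
lobulated option would be more realistic but has no oracle). Responders
shrink geometrically to a volume ratio of **0.3** at 55 Gy
(ratio^{d/55} at dose d), non-responders drift to **0.9**; a per-scan
log-normal jitter (sd 0.05) adds mild inter-patient response
variability. Interior texture is a spatially correlated Gaussian field
(correlation length 4.5 mm, sd 15 on a base intensity of 100) whose sd
shrinks by a factor 0.85 per scan in responders — operationalising
texture homogenisation without claiming the underlying biology.
Magnitude-MR noise is Rician with σ = 5 (SNR ≈ 20, a deliberately
low-SNR choice motivated by the 0.35 T context; a convention, not a
recorded fact). All values are the generator's fixed study conditions,
not tuning knobs.

What the phantoms do *not* emulate: real lesion shapes and
infiltration, scanner drift and bias fields, registration error between
scans, contouring variability. Passing recovery tests therefore shows
the *pipeline* recovers a strong programmed effect at the study's
sample size — not that the clinical effect sizes are reproduced.

## Calibration and recovery checks

Two cohort-level properties are exercised routinely (problem sizes
chosen to keep a full run of the suite within a few minutes):

- **Null calibration.** On a cohort generated with *identical*
  trajectories for both groups, outcome labels are randomly permuted 50
  times and the fraction of flagged cells recorded. Because the exact
  test's null rejection rate at α = 0.05 is the discretely attainable
  rate just below α, and cells within one replicate are correlated, the
  check compares the mean flag rate against the 95% binomial band of α
  at the *replicate* count (n = 50) — the honest unit of replication.
- **Signal recovery.** Twenty seeded default cohorts are generated,
  extracted and screened; the volume and L_least delta features at
  55 Gy must be flagged in at least 18 of 20 replicates. With the
  default effect (0.3 vs 0.9 volume ratio) separation is essentially
  complete and the observed exact p equals the attainable minimum
  2/C(16,5) ≈ 4.6 × 10⁻⁴.

## Degenerate inputs, tie-breaks, tolerances

- Empty masks error at every entry point (`empty ROI`).
- A single-voxel ROI yields volume = one voxel, axis lengths 0,
  elongation/flatness 0, one run of length 1 per direction, and a small
  positive raw-mesh surface.
- Constant intensities quantize wholly to level 1 and set the
  documented degenerate statistical values.
- Delta cells with zero baseline are undefined and excluded pairwise;
  screening cells left with fewer than two patients per class are
  reported as untested rather than silently dropped.
- The exact/normal switch in the WMW test is a sample-size bound
  (default 30), logged per result via the `method` attribute.
- Floating-point tail comparisons in the exact test use a 10⁻⁹ slack on
  doubled-rank deviations, so equal-magnitude deviations count as ties.

## Reference tables

The study's patient-characteristics table and its significant-feature
grid ship as plain CSVs (`study_patients()`, `study_significance()`),
with tally operations reproducing the printed counts: 5/16 (31%) cCR;
6 significant baseline cells; 57 significant delta cells; exactly
`energy`, `glnu` and `L_least` significant at every delta scan; minimum
tabulated p = 0.001 at `t22` for `L_least` and `glnu`. One patient row
is typographically ambiguous in the published layout; the transcription
resolves it by the column domains and is marked in the fixture's `note`
column. The p-values themselves are *not* recomputable without the
patient images; the tables exist so that the bookkeeping is
machine-checkable.

## Known limitations

- The panel is a faithful-count reconstruction, not the original
  implementation; absolute values of completion members are
  package-specific conventions (documented above).
- Box-counting FD on anchored dyadic grids is translation sensitive at
  the 0.0x level and needs slices of at least 8 pixels extent.
- The mesh surface is accurate for lesions a few voxels across and
  larger; sub-voxel structures fall back to the raw-occupancy mesh.
- Screening without multiplicity correction is a hypothesis-generating
  design; expect ~5% false-positive cells under the null by
  construction.
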