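# deltarad

Delta-radiomics feature screening for MR-guided radiotherapy (MRgRT) of
rectal cancer — for medical-physics and radiation-oncology researchers
who have serial on-treatment MR scans with lesion contours and want to
ask, early in a course of chemoradiotherapy, *which quantitative image
features change differently in patients heading for a clinical complete
response (cCR)?*

## What it computes

Each observation is an MR volume with a binary gross-tumour-volume mask
on an isotropic grid (1.5 mm default), at one of six cumulative-dose
timepoints: the simulation scan t₀ and on-treatment scans every five
2.2 Gy fractions (t₁₁, t₂₂, t₃₃, t₄₄, t₅₅ Gy).

1. **53-feature panel** from the raw masked intensities (no filtering):
   17 first-order statistics (min, range, energy = Σx², entropy, ...),
   14 shape features (volume V, mesh surface A, principal axis lengths
   L_major ≥ L_minor ≥ L_least = 4√λᵢ from the coordinate covariance,
   sphericity = (36πV²)^⅓ / A, compactness, asphericity, ...),
   6 per-slice box-counting fractal-dimension summaries, and
   16 grey-level run-length (GLRLM) features (sre, lre, glnu, rperc,
   run entropy, ...) averaged over the 13 unique 3D directions after
   32-level equal-width quantization.
2. **Delta features**: Δf(t) = f(t) / f(t₀) at each on-treatment
   timepoint — 265 ratios per patient, 318 testable quantities in all
   (53 absolute at t₀ + 5 × 53 deltas).
3. **Exact Wilcoxon–Mann–Whitney screening** of every quantity against
   the binary cCR outcome: mid-ranks for ties, two-sided p from the
   full assignment distribution (C(16,5) = 4368 assignments at the
   study scale), flag at p < 0.05, no multiplicity correction by
   default (hypothesis-generating design; Benjamini–Hochberg is a
   switch).

A longitudinal phantom-cohort simulator (shrinking, texture-homogenising
ellipsoidal lesions with Rician noise; 16 patients, 31% responders)
makes the whole pipeline testable without any data download, and the
study's patient table and significance grid ship as machine-readable
CSVs with tally functions.

## Worked example

```r
library(deltarad)

# a noiseless 15 mm spherical phantom through the full stack
ball <- generate_lesion(c(15, 15, 15), noise_sigma = 0, texture_sd = 0,
                        seed = 1)
round(extract_all(ball)[c("volume", "surface", "sphericity", "L_least")], 2)
#>     volume    surface sphericity    L_least
#>   14256.00    2837.26       1.00      26.91
```

Volume is within 1% of the analytic 4/3·π·15³ ≈ 14 137 mm³, the mesh
surface within 0.4% of 4π·15² ≈ 2827 mm², sphericity is 1, and L_least
is 4·15/√5 ≈ 26.83 mm under the 4√λ axis convention.

```r
# simulate the default 16-patient cohort, extract, form deltas, screen
coh  <- generate_cohort(cohort_config(seed = 1))
long <- extract_cohort(coh$observations)           # 5088 rows = 96 x 53
res  <- run_screen(long, coh$outcomes)             # 318 exact WMW tests
res$report[res$report$feature %in% c("energy", "volume", "L_least", "glnu"), ]
#>   feature        family t0   t11   t22   t33   t44   t55
#>    energy   statistical      0.000 0.000 0.000 0.000 0.000
#>    volume morphological      0.000 0.000 0.000 0.000 0.000
#>   L_least morphological      0.000 0.000 0.000 0.000 0.000
#>      glnu      textural      0.009 0.000 0.000 0.000 0.000
```

Blank cells are not significant at α = 0.05; `0.000` is the attainable
minimum exact p of 2/C(16,5) ≈ 4.6 × 10⁻⁴ displayed at three decimals.
The programmed strong effect (responder lesions shrinking to 30% of
baseline volume versus 90% in non-responders, with texture
homogenisation) is recovered at every delta timepoint.

```r
# the shipped study tables and their tallies
count_ccr(study_patients())                        # $count 5, $percentage 31
tally_significant(study_significance(), "t0")      # 6
tally_significant(study_significance(), TIMEPOINTS[-1])  # 57
features_significant_at_all_deltas()               # "L_least" "energy" "glnu"
```

On-disk cohorts use NIfTI or NRRD volumes plus a CSV manifest
(`patient_id, timepoint, image_path, mask_path, outcome`); see
`run_extract()` / `write_cohort()`, or the thin command-line front end
in `inst/cli/deltarad.R` (`extract`, `delta-screen`, `simulate`,
`fixtures` subcommands).

## Scope

Masks are consumed as voxel grids: DICOM-RT contour voxelisation,
inter-scan registration, intensity normalisation across scanners,
restaging adjudication and multivariable model training are out of
scope. See the methods vignette
(`vignettes/delta-radiomics-methods.Rmd`) for definitions, numerical
choices, the panel-reconstruction caveat, and known limitations.
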