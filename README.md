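# bcellsynovitis

Quantification and classification of B cell synovitis in rheumatoid
arthritis (RA) tissue, for pathologists and computational biologists who
need the three quantification routes of a B cell score validation study in
one tested toolbox:

1. **Digital image analysis** of CD20 immunohistochemistry: H-DAB color
   deconvolution of brightfield RGB slides, isodata ("Default")
   auto-thresholding of the DAB channel inside an operator ROI, and the
   stained **area fraction**
   `AF = 100 × stained area / tissue area` (percent).
2. **Semiquantitative histology**: gradability assessment (synovial lining
   or sublining present, no artifact), and the B cell–rich/poor
   classification — CD20 score ≥ 2 is *rich*, ≤ 1 is *poor*, with a CD138
   (plasma cell) score ≥ 2 triggering a deeper-cut CD20 recheck.
3. **Molecular scoring**: derivation of a B cell–specific gene module from
   a reference expression atlas (per-gene Z across tissues, target rank
   ≤ 3, Z > 5, specificity score < 10), and per-sample **module scores** as
   the first principal component (σ₁·v₁) of the module-restricted,
   gene-centered expression matrix via SVD.

A validation-statistics layer provides the agreement and association tests
used to tie the three routes together: two-way random-effects absolute
agreement ICC(2,1) from the ANOVA mean squares, Bland–Altman limits of
agreement (mean ± 1.96 SD of the differences), Mann–Whitney, Pearson
chi-square (no continuity correction), Fisher's exact, and Spearman
correlation.

Because patient slides and RNA are not distributable, the package ships a
first-class **synthetic-data layer**: slides rendered through the same
Beer–Lambert model the deconvolution inverts (with pixel-exact ground-truth
masks), atlases with planted marker genes, bulk mixtures with controlled B
cell fractions, paired-observer readings, and clinical cohorts with
configurable B cell–rich prevalence and stratum effect sizes. Every
pipeline stage is therefore testable end to end with known truth.

## Worked example

```r
library(bcellsynovitis)

# 1) simulate a grade-3 slide and quantify it
s <- generate_slide(slide_spec(grade = 3, seed = 42))
quantify_slide(s$image, s$tissue_mask)
#> DAB quantification:
#>   tissue area:  22124 px
#>   stained area: 1387 px
#>   area fraction: 6.269%
#>   threshold: 0.45
s$truth_area_fraction   # 6.269 — recovered exactly at zero noise

# 2) classify a CD138-fallback sample
st <- classify_b_cell_status(score_panel("pt01", cd20 = 1, cd138 = 3),
                             score_panel("pt01", level = 2, cd20 = 2))
st$status  # "rich"      (deeper-cut CD20 governs)
st$basis   # "cd138_fallback_level2_cd20"

# 3) derive a B cell module and score bulk mixtures
atlas <- generate_atlas(atlas_spec(seed = 1))
mod <- derive_cell_module(atlas)      # 30/30 planted markers, rank 1, Z ~ 6.7
mix <- generate_bulk_mixtures(atlas, seq(0, 0.5, length.out = 50),
                              noise_sd = 0.2, seed = 2)
sc <- svd_module_score(subset_to_module(mix, mod))
correlate_with_histology(sc, mix$b_fractions)
#> rho = 0.999, p = 5.7e-65, n = 50

# 4) paired-observer agreement
pr <- generate_paired_readings(runif(100, 0, 5), noise_sd = 0.15, seed = 3)
icc_two_way(pr)$icc                   # 0.99
bland_altman(pr)                      # bias -0.004, LoA -0.42 to 0.41
```

The numbers mean: the image pipeline recovers the known stained-area
fraction of the rendered slide without error; the fallback rule promotes a
CD20-low/CD138-high sample to *rich* on the deeper cut; the module score
tracks the planted B cell fraction almost perfectly under noise; and two
simulated observers with 0.15-point measurement noise agree at ICC ≈ 0.99
with tight limits of agreement.

`run_simulate()` / `run_validate()` orchestrate the whole study (two
cohorts of 165 and 164 patients, slides at every grade, atlas, mixtures,
paired readings) and return the full validation report: per-slide
quantification, grade-vs-area-fraction Spearman, per-cohort ICC and
Bland–Altman, module and fraction recovery, disposition tables with a
chi-square prevalence comparison, and a stratified clinical comparison per
cohort.

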