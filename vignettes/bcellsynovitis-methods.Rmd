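---
title: "Methods: quantifying and classifying B cell synovitis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and classifying B cell synovitis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcellsynovitis)
```

# Scope

Synovial B cell infiltration in rheumatoid arthritis ranges from absent to
dense follicle-like aggregates, and classifying patients as B cell *rich*
or *poor* is a candidate stratification axis for therapy. This package
implements the three measurement routes such a classification rests on —
digital image analysis of CD20 immunohistochemistry, semiquantitative
observer scoring with a decision algorithm, and transcriptomic module
scoring — together with the agreement statistics that tie them together,
and a synthetic-data layer that makes the whole pipeline verifiable against
known ground truth.

# Image quantification model

Brightfield IHC follows the Beer–Lambert law: a pixel's optical density
`OD_c = -log10(I_c / 255)` in each RGB channel `c` is (approximately) a
linear mixture of per-stain contributions, `OD = c_H · V_H + c_D · V_D`,
where `V_H` and `V_D` are unit OD direction vectors for hematoxylin and
DAB. Color deconvolution inverts this 3×3 system (the third channel is the
normalized cross product of the first two, a residual) to recover the
concentration planes `c_H`, `c_D` per pixel. We use the standard
Ruifrok–Johnston H-DAB constants — hematoxylin (0.650, 0.704, 0.286), DAB
(0.269, 0.568, 0.872) — configurable via `hdab_stain_matrix()` or a YAML
file. The OD conversion guards `max(I, 1)` so a zero intensity cannot
produce an infinite density; negative concentrations (8-bit rounding
noise) are clamped to zero.

The stained area is defined by the isodata (iterative intermeans)
threshold on the DAB plane: the masked values are rescaled to a 256-bin
histogram and `t ← (mean_below(t) + mean_above(t)) / 2` is iterated to its
fixed point. Thresholding uses only pixels inside the operator's region of
interest, matching the pipeline order (ROI → deconvolution → threshold).
A pixel is *stained* when its DAB value is strictly greater than the
threshold (ties count as unstained — an explicit deterministic tie-break).
The area fraction is `100 × stained / tissue` in percent.

Numerical edge cases are handled explicitly:

* A constant DAB plane (within 1e-6) has no defined threshold;
  `isodata_threshold()` errors, while `quantify_slide()` treats the slide
  as stain-free and returns area fraction 0 with a warning.
* A DAB plane whose maximum never exceeds 0.02 OD — the magnitude of 8-bit
  quantization noise — is likewise reported as 0. Without this rule a
  stain-free slide whose ROI touches background would have its rounding
  noise thresholded.
* Isodata has no unimodality guard by construction: on a stain-free slide
  with additive noise it happily splits the noise histogram and reports a
  large spurious stained area. Operators handle this by manual
  adjustment; the pipeline exposes the same control as an explicit
  numeric `override_threshold` (recorded in the result), plus a
  config-level policy in `run_validate()`: an automatic threshold below
  `min_threshold` (default 0.2 OD, far below the rendered DAB signal of
  0.9) is replaced by the floor and flagged as a manual override. No
  other automatic adjustment heuristic is applied.

ROI polygons are rasterized by an even-odd scanline fill with the
pixel-center convention (the pixel at row r, column c belongs to a polygon
iff its center (c−0.5, r−0.5) in 0-based coordinates is inside), clipped
to the canvas. The tissue mask is the union of all polygon rasters.

# Classification algorithm

A sample is *gradable* iff it shows a synovial lining (CD68+ cells in
linear arrangement) or a recognizable sublining, and no artifact. On
gradable samples the decision table is:

1. level-1 CD20 ≥ 2 → **rich**;
2. level-1 CD20 ≤ 1 and CD138 < 2 → **poor**;
3. level-1 CD20 ≤ 1 and CD138 ≥ 2 → governed by the CD20 score of an
   additional stain at a deeper cutting level (≥ 2 rich, else poor).

Design choices where the procedure leaves room: a missing CD138 score is
treated as CD138 < 2 (the fallback is an additional check, so an absent
plasma-cell stain defaults to the direct CD20 ruling); only the
deeper-cut CD20 governs branch 3 (no second-round CD138 recheck — the
recursion terminates at level 2); branch 3 without a level-2 panel is an
error rather than a silent default. The classification is monotone in
CD20 by construction. Cohort accounting reports
`gradable_rate = 100 × graded / total` and
`prevalence_rich = 100 × rich / graded`, with prevalence undefined (NA
plus warning) when nothing is gradable.

# Gene module derivation

Given a normalized log-scale atlas (genes × tissues/cell types, at least
12 columns), each gene is Z-scored across columns and ranked by
expression. A gene is specific to the target cell type when all three
criteria hold at the target column: expression rank ≤ 3, Z > 5, and a
specificity score (number of columns with Z > 3) < 10.

Conventions fixed here: the SD in the Z score is the **population** form
(divide by N) — the criteria are scale-free so this only shifts the
boundary cases, but it must be held fixed; rank ties share the best
(minimum) rank, so a target tied into the top 3 qualifies; the
specificity count includes the target column itself (a perfect marker has
specificity 1); both the Z > 5 and Z > 3 comparisons are strict, matching
the strictness of the rank criterion; zero-variance genes get an all-zero
Z row and a flag rather than NaN, which silently excludes them from any
module. Module membership is invariant to column order and to per-gene
monotone affine rescaling; both are asserted in the test suite.

One sizing constraint worth knowing: at zero noise a marker expressed in
exactly one of `n` columns has target Z = √(n−1) under the population SD,
so the Z > 5 criterion is only attainable for atlases with more than 26
columns. The synthetic atlas default is 50 columns.

# SVD module score

The expression matrix is restricted to module genes (≥ 2 required; absent
genes are reported), each gene is centered, and the matrix is decomposed
by SVD. The per-sample score is the first principal component score
`σ₁ · v₁`. Whether to also scale genes to unit variance is exposed as
`scale_genes` (default off: centering only — module genes are already on
a common log scale, and scaling would up-weight low-signal genes). The
SVD sign is arbitrary, so the score is oriented to correlate positively
with the per-sample mean module expression: higher score = more B cell
signal. On rank-1 data the score equals the latent factor up to a
positive scale and the explained-variance share is 1.

Association with histology uses Spearman correlation (average ranks for
ties; exact null for n ≤ 10 without ties, t approximation otherwise). A
median-of-ratios size-factor + log2 utility (`normalize_counts()`) is
provided for raw-count inputs; it is a simple normalization stand-in, not
a variance-stabilizing transform, and the synthetic matrices do not need
it.

# Agreement and association statistics

The inter-observer ICC is the two-way random-effects,
absolute-agreement, single-measurement form ICC(2,1), computed from the
two-way ANOVA mean squares:
`(MSR − MSE) / (MSR + (k−1)·MSE + (k/n)(MSC − MSE))`, k = 2. This form is
chosen because two fixed observers rate the same slides and *agreement*
(not merely consistency) is the question; the test suite checks the
closed form against `stats::aov` mean squares. Bland–Altman analysis
reports the mean difference and limits of agreement
`mean ± 1.96 · SD(differences)`; the "95% interval" lines on an agreement
plot are these limits (not the CI of the mean difference), and both the
summary and the per-pair points are returned so either can be drawn.

Group comparisons wrap the standard tests: Mann–Whitney (exact for
combined n ≤ 12 without ties, tie-corrected normal approximation
otherwise), Pearson chi-square on 2×2 tables **without** continuity
correction, and Fisher's exact test. The continuity-correction choice is
deliberate: on the published stratum counts (93/50 vs 81/74) the
uncorrected test reproduces the reported p = 0.025 while the Yates
version gives ≈ 0.034. The stratified clinical report applies
Mann–Whitney to continuous variables and, for binary variables, Fisher's
exact when any expected cell is below 5 and chi-square otherwise; p
values are reported unadjusted, one per variable, matching the
single-table reporting convention. Strata with fewer than two patients
get summaries but no test, with a flag.

# What the synthetic data emulates — and what it does not

**Slides.** Tissue is an ellipse sized to a target canvas fraction;
grades map to a declared convention (0: none; 1: four scattered single
cells; 2: one small ~12-cell aggregate; 3: one medium ~60-cell aggregate;
4: one large ~250-cell follicle-like aggregate), with cells as 3–4 px
disks packed Gaussian around an aggregate center and clipped to tissue.
Background is pure white so the OD origin is exact. Rendering uses the
same forward Beer–Lambert model the deconvolution inverts, with optional
per-channel Gaussian OD noise before 8-bit quantization; ground-truth
masks give the exact stained-area fraction. This exercises
deconvolution, thresholding and area accounting — it does *not* attempt
photorealism (no stroma texture, vessels, folds, or sectioning
artifacts), so passing round-trip tests shows algorithmic correctness,
not robustness to real histology variation.

**Atlas and mixtures.** Markers are planted `log2(fold)` above their own
baseline in the target column only (default fold 16, log-noise 0.25, 50
columns, 30 markers in 1000 genes); bulk samples are convex combinations
of the target column and the mean background profile on the linear
scale, re-logged, plus noise. Real marker genes are not this clean:
expression bleeds across related lineages, and real deconvolution
problems have correlated backgrounds.

**Observers and cohorts.** Paired readings are truth plus independent
Gaussian error (SD 0.15 points at a 0–5% truth range, biases optional),
clamped at zero. Cohorts draw gradability and B cell status from
Bernoulli rates (defaults: 165 patients, 143/165 gradable, 35% rich;
164 patients, 155/164 gradable, 47.7% rich) and clinical variables from
independent Gaussians/Bernoullis with the published stratum parameters
(`table_effects()`). Variables are uncorrelated because only marginal
summaries are published; CRP and ESR are left un-truncated even though a
Gaussian with SD ≫ mean produces negative values, because truncation
would bias the stratum means the generator is supposed to hit. Score
panels are then drawn consistently with each patient's status, including
a ~10% CD138-fallback rate among B cell-poor samples with a deeper-cut
panel; deeper-cut *images* are never simulated, only scores.

# Problem sizes and determinism

Default study sizes keep a full simulate-validate cycle under a few
seconds on one core: 15 slides of 160×160 px (three per grade), a
1000×50 atlas, 50 bulk mixtures, paired readings at n = 15 and n = 100,
and two cohorts of 165/164 patients. Null-calibration checks use 2,000
replicates. All generators are bit-reproducible given a seed; the
orchestration layer derives per-stage child seeds from one master seed,
and a YAML config round-trips all constants.

# Known limitations

* Stain vectors are fixed, never estimated from the image; slides whose
  chromogens deviate from the configured vectors will leak concentration
  between channels.
* Isodata thresholding assumes a bimodal DAB histogram; the minimum
  threshold policy catches the stain-free failure mode but a faint,
  diffuse true signal below the floor would be missed.
* The semiquantitative grade-to-aggregate mapping is a simulation
  convention, not a claim about the original grading criteria; absolute
  area fractions per grade should not be read as calibrated.
* The clinical generator cannot reproduce joint distributions
  (e.g., DAS28 correlating with ESR) and therefore cannot be used to
  study multivariate clinical structure.
* No whole-slide pyramids, nucleus segmentation, or cell counting; the
  quantification is strictly area-based at a single resolution.
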