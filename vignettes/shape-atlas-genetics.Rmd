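---
title: "Shape atlases and the genetics of biventricular morphology: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape atlases and the genetics of biventricular morphology: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapegwas)
```

## The problem

Conventional cardiac structural phenotypes (mass, volume, ejection
fraction, one-dimensional sphericity indices) compress ventricular
anatomy into single numbers. A statistical shape atlas instead treats
each heart as a vector of `P` corresponded 3-D surface points, models the
population by its mean shape plus orthogonal modes of variation from
principal component analysis, and assigns every subject a Z-score per
mode. Those PC Z-scores become quantitative phenotypes: they can be
correlated with risk factors, regressed against disease outcomes, scanned
genome-wide against genotype dosages, given heritability estimates and
polygenic scores, and fed into Mendelian randomization. `shapegwas`
implements that full chain, together with a synthetic-data module that
generates every input with known ground truth, so each stage is testable
at desk scale without any individual-level cohort data.

## The shape model

A subject's mesh is a `P x 3` matrix in mm with fixed point
correspondence across subjects. The atlas pipeline is:

1. **Generalized Procrustes alignment.** Each mesh is rigidly aligned
   (translation + proper rotation via the SVD/Kabsch solution; scale is
   *not* removed and reflections are never applied) to a consensus that
   is iteratively replaced by the pointwise mean, until the consensus
   moves less than `1e-9` mm RMS or 100 iterations are reached. The first
   mesh seeds the consensus; the consensus is kept centred at the origin.
2. **PCA.** The sample covariance of the stacked `3P` vectors
   (divisor `n - 1`) is eigendecomposed through the thin SVD of the
   centred data matrix — numerically stable when `3P >> n`. Modes are
   sign-fixed so each one's largest-magnitude loading is positive.
3. **Scoring.** `z_k = v_k' (x - mu) / sqrt(lambda_k)`. Dividing by the
   root eigenvalue gives training-set scores unit variance per mode, so
   downstream "per SD of PC" odds ratios are well defined. The raw
   projection variant would only rescale effect sizes, not directions.

Mode selection uses the strict rule `variance fraction > threshold`
(default 1%). Reconstruction is `mu + sum z_k sqrt(lambda_k) v_k`;
setting one score to ±2 renders a mode's two-SD extreme shapes.
`subgroup_variance_explained()` reports
`100 * (variance of the subgroup's projections onto the listed modes) /
(total subgroup variance)`, both measured about the subgroup's own mean
after rigid alignment to the atlas mean. The wording "variance explained
in a subgroup" is ambiguous between subgroup-centred and atlas-centred
baselines; the subgroup-centred choice is used because it makes the
training set score exactly 100% with all modes and is invariant to a
constant offset of the subgroup.

## Quality control

Four shape-based scores per subject: mean contour-to-model distance in mm
(nearest model *vertex* stands in for the nearest surface point; with
dense meshes the difference is negligible and no face connectivity is
required), the individual Z-scores of the first 10 modes, the Mahalanobis
distance `sqrt(sum z10^2)`, and the RMS residual after projection onto
those modes. Each score gets a wide Tukey fence
`[Q1 - 5*IQR, Q3 + 5*IQR]` (quartiles by linear interpolation,
`stats::quantile` type 7 — fence placement depends on the convention, so
it is fixed and documented). The literal asymmetric reading of the fence
rule ("above the lower quartile or below the upper quartile") is
available via `fence_variant = "literal"`; the symmetric form is the
default because removing extremes is the evident intent. A zero IQR with
non-constant data flags values away from the median; constant data flags
nothing. A subject is excluded if any score is flagged.

One genuine limitation surfaced by simulation: if the atlas is trained on
a cohort that already contains outliers concentrated along a single mode,
those outliers inflate that mode's eigenvalue (1% contamination at 8 SD
inflates it by a factor ~1.6) and thereby shrink their own standardized
scores — the Mahalanobis fence can no longer isolate them, although the
per-component Z fence still does. Scoring cohorts against a reference
atlas fitted to clean data does not suffer this masking, which is how the
QC sensitivity checks are run. This is the classic non-robustness of PCA
to concentrated contamination, worth knowing when QC-ing the atlas's own
training cohort.

## Genetic analyses

**Variant QC** keeps variants with MAF > 1%, exact Hardy-Weinberg
p ≥ 1e-6 (enumeration test on hard calls, dosages rounded to the nearest
integer) and missing rate < 1.5%.

**Association scan.** Each PC score is regressed on each variant's dosage
plus covariates (age, sex, height, BMI, systolic blood pressure, heart
rate in the simulated cohorts) by OLS. The phenotype and all dosages are
residualized on the covariates once; by Frisch–Waugh–Lovell the
per-variant slope, SE (`df = n - rank(covariates) - 1`) and p-value are
identical to the joint fit, at a fraction of the cost. Genome-wide
significance is declared at `p < 5e-8`, suggestive at `1e-6`. The
genomic inflation factor is the median-based
`lambda = median(chi2(p)) / qchisq(0.5, 1)`; a large-cohort mixed model
is out of scope here, so the scan is plain OLS and the simulated cohorts
contain no relatedness or stratification for it to mishandle.

**Loci, signals, conditional analysis.** A locus is the ±500 kb window
around a lead variant; a signal is the lead plus window variants with
`r^2 > 0.1`; proxies are `r^2 >= 0.8`. Construction is greedy from the
smallest p (ties by chromosome, position). Secondary signals refit each
locus variant with the lead dosage as a covariate and are declared when
the original p is below 1e-6 *and* the lead-to-secondary and
marginal-to-conditional `-log10(p)` ratios are both below 1.5. The
source wording joins the three conditions with an ambiguous "or"; the
conjunction is the conservative default and `rule = "any"` gives the
literal disjunction.

**Heritability.** Haseman–Elston regression: the off-diagonal phenotype
cross-products are regressed on the genomic relationship entries
`G_ij = Z Z' / m` from standardized dosages; the slope estimates `h2_g`,
and with two phenotypes the symmetrised cross-products estimate the
genetic covariance, giving `r_g = gcov / sqrt(h2_a h2_b)`. Standard
errors come from a delete-one-block jackknife over subjects (20 blocks by
default). HE is used instead of a REML mixed model because it is exact,
dependency-free and unbiased at the simulated scale; its larger variance
is priced into the tests. Heritability-recovery checks run at linkage
equilibrium (`ld_rho = 0`) so the HE estimand equals the generator's
`per_mode_h2` without LD-weighting corrections.

**Percent variance explained** is the incremental `R^2` of the
significant dosages over the covariate-only model, times 100.

## Polygenic risk scores

A PRS model is the list of lead variants with effect alleles and GWAS
betas; scoring sums effect-allele dosages times weights, flipping `2 - g`
when a cohort stores the opposite allele, substituting pre-declared
proxies for missing variants, and z-standardizing on the scoring cohort.
Associations are logistic odds ratios per SD of PRS with Wald 95% CIs;
transferability reports the incremental variance in the PC explained by
the PRS per cohort plus per-variant effect-allele frequencies with a
flag below 1% (the regime where a score derived in one ancestry loses
information in another).

## Mendelian randomization

Two-sample MR from summary statistics. Harmonization aligns outcome
effects to the exposure's effect allele (sign flip + EAF complement on
swapped rows), drops strand-ambiguous palindromic variants with exposure
EAF in (0.42, 0.58) — the window is configurable since the source is
silent — and can substitute the highest-`r^2` proxy present in the
outcome table, sign-aligned by reference-dosage correlation. Instruments
require `F = (b_x/s_x)^2 > 10`; LD clumping is greedy by ascending
exposure p within 10 Mb at `r^2 > 0.001`. Estimators:

- **IVW**: `sum(w b_x b_y) / sum(w b_x^2)` with `w = 1/s_y^2`;
  fixed-effect SE, inflated by `sqrt(Q/(k-1))` when Cochran's Q exceeds
  its df (multiplicative random effects). One instrument reduces to the
  Wald ratio.
- **Weighted median** of Wald ratios with inverse-variance weights of the
  first-order delta SEs; SE by parametric bootstrap (1000 replicates,
  fixed internal seed, caller's RNG state restored).
- **Egger**: WLS of `b_y` on `b_x` with intercept after orienting
  exposure effects positive; the intercept estimates directional
  pleiotropy. SEs use the conventional residual-SD floor at 1 and a t
  reference with `k - 2` df.

`mr_bidirectional()` runs the whole pipeline in both directions.

## The synthetic-data generator

The generator defines the study conditions; its defaults are fixed, not
tuning knobs.

- **Template**: deterministic Fibonacci-lattice points on two
  intersecting ellipsoidal shells (LV-like: semi-axes 35/35/50 mm at the
  origin; RV-like: 45/30/45 mm centred at (40, 0, −5)). Only point
  correspondence and mode structure matter downstream, not anatomy.
- **Shape population**: subject `i` is
  `template + sum_k z_ik sd_k sqrt(3P) U_k + noise`, then an independent
  random rotation and translation. The `U_k` are orthonormal `3P` fields
  drawn once per configuration and projected off the template's
  6-dimensional rigid-motion subspace — a rigid component of a "mode" is
  pose, not shape, and Procrustes alignment would quotient it out anyway
  (hence `K <= 3P - 6`). The `sqrt(3P)` scaling makes `mode_sds[k]` the
  per-point RMS displacement in mm, so the population eigenvalue of mode
  `k` is `3P sd_k^2` and its variance fraction
  `sd_k^2 / (sum sd^2 + noise_sd^2)`.
- **Genotypes**: within a block of `ld_block_size` variants, latent
  Gaussians share pairwise correlation `ld_rho` (single common factor)
  and are thresholded at the Hardy–Weinberg genotype frequencies of the
  block's MAF; blocks are independent. Realized dosage correlation is
  attenuated relative to the latent `ld_rho` (tetrachoric thresholding),
  so LD-dependent checks measure the realized `r^2`. MAF is drawn per
  block because attainable `r^2` is bounded by allele-frequency mismatch;
  high-LD variants are necessarily frequency-matched.
- **Genetic architecture**: each latent score splits into a genetic part
  (equal-magnitude, random-sign weights on `causal_per_mode` standardized
  dosages, one causal variant per LD block, blocks assigned round-robin
  so one mode's causal variants land in distinct loci) and an
  environmental part, rescaled in-sample to exact shares `per_mode_h2` and
  `1 - per_mode_h2`.
- **Covariates/outcomes**: age N(62, 7.5²) yr, sex Bernoulli(0.48),
  sex-specific height, BMI N(26.5, 4²), SBP N(137, 17²) +15 mmHg under
  medication (20%), heart rate N(61, 9²). Outcomes are Bernoulli with
  logit = intercept + per-SD log-ORs on the latent scores + small fixed
  standardized-covariate terms; the intercept is solved by `uniroot` to
  hit the target prevalence. Defaults mirror the headline observational
  effects: an AF-like outcome at log-OR log(1.5) on mode 3, a
  diabetes-like outcome at −log(2) on mode 1.
- **MR summary statistics**: exposure betas N(0.15, 0.03²) with SE 0.01
  (F ≈ 225) and outcome SE 0.008 — strong biobank-scale instruments;
  outcome beta = causal effect × true exposure beta + optional constant
  pleiotropy + noise. Allele scrambling emits half the outcome rows with
  swapped alleles and negated betas to exercise harmonization.
- **Seeding**: one integer seed per configuration; each generator uses a
  fixed documented offset (+101 shapes, +202 genotypes, +303 cohort,
  +404 MR), so outputs are bitwise reproducible and individually stable.

What the generator does **not** emulate: anatomically realistic
geometry, image segmentation error structure, relatedness/kinship,
population stratification, covariate–shape confounding, missing
covariates, or realistic genome-wide LD. Passing tests therefore
demonstrate the correctness and calibration of the estimators under the
stated generative model, not robustness to those real-data complications.

## Problem sizes and numerical choices

Validation runs use cohorts of 400–2000 subjects, meshes of 120–300
points, panels of up to 5000 variants and 10–100 seeded replicates —
sizes at which every property checked (eigenstructure recovery,
subspace angles, scan calibration, heritability and effect-size
recovery, greedy-procedure equivalence) is already sharp. At `n = 500`
the variance fraction of a latent draw itself fluctuates with relative
SD `sqrt(2/(n-1)) ≈ 6%`; recovery checks therefore either compare
against the realized draw or average over seeds. Convergence tolerances:
GPA `1e-9` mm RMS; IRLS `1e-8`; HE regression is closed-form. Degenerate
inputs (coincident points, zero-variance dosages, zero IQR, perfect
separation, monomorphic PRS variants) error or warn explicitly rather
than returning silent numbers.
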