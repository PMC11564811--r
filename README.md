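# shapegwas

Statistical shape atlases of the heart's ventricles, and the genetics of
the shape phenotypes they produce.

Cardiac structure is usually summarised by single numbers — mass, volume,
ejection fraction, a sphericity index. A biventricular *shape atlas*
instead represents every heart as `P` corresponded 3-D surface points,
aligns the cohort by generalized Procrustes analysis (translation and
rotation only; size is part of shape here), and decomposes the variation
by PCA. Each subject then carries a Z-score per principal component,

```
z_k = v_k' (x - mu) / sqrt(lambda_k),
```

unit-variance and mutually uncorrelated in the training cohort. Those PC
Z-scores are quantitative phenotypes for everything downstream:

- **shape QC** — four scores (contour fit error, per-PC Z-scores,
  Mahalanobis distance `sqrt(sum z10^2)`, projection residual) with
  5×IQR fences;
- **observational analysis** — Pearson correlations, AIC-stepwise
  covariate selection, logistic odds ratios per SD of PC;
- **GWAS** — variant QC (MAF > 1%, exact HWE ≥ 1e-6, missingness
  < 1.5%), additive dosage scans by residualized OLS, median-based
  genomic inflation, greedy locus (±500 kb) / signal (r² > 0.1) /
  proxy (r² ≥ 0.8) definition, conditional secondary signals
  (1.5-fold −log10 p rules), Haseman–Elston heritability and genetic
  correlation, percent variance explained;
- **PRS** — lead-variant scores (effect-allele dosage × GWAS beta),
  per-SD disease odds ratios, cross-cohort transferability and
  allele-frequency checks;
- **MR** — bidirectional two-sample Mendelian randomization with allele
  harmonization, F > 10 instrument filtering, LD clumping, IVW,
  weighted median and Egger regression.

A first-class synthetic-data module (`sim_config()`, `make_template()`,
`sample_shape_population()`, `sample_genotypes()`,
`sample_covariates_outcomes()`, `make_mr_summary_stats()`) generates
mesh populations with latent shape modes under genetic control,
LD-structured dosages, covariates, binary outcomes and summary
statistics — all seedable, with the ground truth returned alongside — so
every estimator in the package is validated against known answers. See
the methods vignette (`vignettes/shape-atlas-genetics.Rmd`) for the
models, assumptions and design choices.

## Worked example

Simulate a genotype-linked cohort, build the atlas, and run the genetic
stack on PC1:

```r
library(shapegwas)

cfg <- sim_config(n_subjects = 600, n_points = 120, n_latent_modes = 5,
                  mode_sds = c(10, 6, 4, 2, 1), noise_sd = 0.5,
                  n_variants = 2000, ld_rho = 0,
                  per_mode_h2 = rep(0.3, 5), causal_per_mode = 5, seed = 42)
geno  <- sample_genotypes(cfg)
pop   <- sample_shape_population(cfg, make_template(120), geno)
gpa   <- generalized_procrustes(pop$meshes)
atlas <- build_atlas(gpa$aligned)
atlas
#> <shape_atlas> 600 training shapes, 120 points, 360 modes
#>   leading variance fractions: 0.648 0.221 0.099 0.025 0.006

select_modes(atlas, 0.01)
#> [1] 1 2 3 4

scores <- score_shapes(atlas, gpa$aligned, align = FALSE, modes = 1:5)
qcv    <- variant_qc(geno$geno, geno$variants)
scan   <- association_scan(qcv$geno, scores$z1, pc = "PC1")
genomic_inflation(scan$p)
#> [1] 0.998

define_loci_and_signals(scan, qcv$geno, qcv$variants)
#> <locus_set> 4 loci (p < 5e-08, +/-500 kb)

he_heritability(qcv$geno, scores$z1)
#> <heritability_estimate> h2 = 0.3440 (SE 0.1099), HE regression
```

Reading the output: the five generative modes carry per-point RMS
amplitudes 10/6/4/2/1 mm against 0.5 mm noise, so their theoretical
variance fractions are 0.636/0.229/0.102/0.025/0.006 — the estimated
leading fractions land on top of them, and mode 5 (0.6%) correctly falls
below the 1% selection rule. The null-calibrated scan (`lambda ≈ 1.00`)
finds 4 of PC1's 5 causal loci at genome-wide significance — the
per-variant variance share is 6%, right at the detection edge for 600
subjects — and Haseman–Elston recovers the generative heritability of
0.30 within one standard error.

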