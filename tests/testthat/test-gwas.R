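# Variant QC, association scan, inflation, loci, conditional, heritability.

test_that("exact HWE test matches enumeration oracle", {
  expect_equal(hwe_exact_test(0, 0, 50), 1)
  expect_equal(hwe_exact_test(100, 0, 0), 1)
  # perfect HWE proportions at EAF 0.5 are the modal configuration
  expect_equal(hwe_exact_test(25, 50, 25), 1, tolerance = 1e-12)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-6)
  # random configurations against the independent choose()-based oracle
  set.seed(6)
  for (i in 1:25) {
    cts <- as.integer(rmultinom(1, sample(30:300, 1),
                                prob = c(0.4, 0.4, 0.2)))
    expect_equal(hwe_exact_test(cts[1], cts[2], cts[3]),
                 oracle_hwe(cts[1], cts[2], cts[3]), tolerance = 1e-9)
  }
})

test_that("variant QC applies the three filters and spares clean data", {
  set.seed(7)
  n <- 1000
  mk <- function(maf) rbinom(n, 2, maf)
  geno <- cbind(v1 = mk(0.005),                 # fails MAF
                v2 = mk(0.02), v3 = mk(0.3),    # clean
                v4 = c(rep(0, 500), rep(2, 500)),  # fails HWE
                v5 = mk(0.3))
  geno[sample(n, 25), "v5"] <- NA               # 2.5% missing
  variants <- data.frame(variant_id = paste0("v", 1:5), chr = 1,
                         pos = (1:5) * 1e6, EA = "A", NEA = "G",
                         EAF = NA, maf = NA, hwe_p = NA, missing_rate = NA)
  qc <- variant_qc(geno, variants)
  expect_identical(qc$variants$variant_id, c("v2", "v3"))
  expect_equal(unname(qc$n_excluded["hwe"]), 1L)

  clean <- variant_qc(geno[, c("v2", "v3")], variants[2:3, ])
  expect_equal(ncol(clean$geno), 2)

  # HWE-consistent simulated panel: at least 99% survive
  cfg <- sim_config(n_subjects = 1000, n_variants = 2000, ld_rho = 0,
                    outcome_log_odds = NULL, seed = 8)
  gt <- sample_genotypes(cfg)
  qc2 <- variant_qc(gt$geno, gt$variants)
  expect_gte(ncol(qc2$geno) / 2000, 0.99)
})

test_that("association scan is exact OLS with calibrated nulls", {
  set.seed(9)
  n <- 500
  g <- matrix(rbinom(n * 20, 2, 0.3), n, 20,
              dimnames = list(NULL, paste0("v", 1:20)))
  # deterministic phenotype: beta recovered exactly, p ~ 0
  y <- 0.1 * g[, 7]
  res <- association_scan(g, y)
  expect_equal(res$beta[7], 0.1, tolerance = 1e-12)
  expect_lt(res$p[7], 1e-200)

  # scan equals per-variant lm with covariates (Frisch-Waugh identity)
  covars <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  y2 <- rnorm(n) + 0.2 * g[, 3] + 0.5 * covars$age
  res2 <- association_scan(g, y2, covars)
  fit3 <- summary(lm(y2 ~ g[, 3] + age + sex, data = covars))
  expect_equal(res2$beta[3], fit3$coefficients[2, 1], tolerance = 1e-10)
  expect_equal(res2$se[3], fit3$coefficients[2, 2], tolerance = 1e-10)
  expect_equal(res2$p[3], fit3$coefficients[2, 4], tolerance = 1e-10)

  # betas invariant to affine covariate rescaling
  covars2 <- data.frame(age = covars$age * 100 + 7, sex = covars$sex * 3 - 1)
  res3 <- association_scan(g, y2, covars2)
  expect_equal(res2$beta, res3$beta, tolerance = 1e-8)

  # type-I calibration at 1e-3 on a null scan
  cfg <- sim_config(n_subjects = 1000, n_variants = 3000, ld_rho = 0,
                    outcome_log_odds = NULL, seed = 10)
  gt <- sample_genotypes(cfg)
  set.seed(11)
  y0 <- rnorm(1000)
  res0 <- association_scan(gt$geno, y0)
  k <- sum(res0$p < 1e-3)
  expect_true(k >= qbinom(0.025, 3000, 1e-3) &&
                k <= qbinom(0.975, 3000, 1e-3))
})

test_that("scan confidence intervals cover a true effect", {
  covered <- 0L
  for (s in 1:60) {
    set.seed(1200 + s)
    n <- 800
    g <- rbinom(n, 2, 0.3)
    beta <- sqrt(0.02 * 1 / var(g))  # per-variant R^2 about 2%
    y <- beta * g + rnorm(n, sd = sqrt(1 - 0.02))
    res <- association_scan(matrix(g, ncol = 1), y)
    if (abs(res$beta - beta) <= 1.96 * res$se) covered <- covered + 1L
  }
  expect_gte(covered / 60, 0.88)
})

test_that("genomic inflation is calibrated and tracks construction", {
  expect_equal(genomic_inflation(rep(0.5, 200)), 1, tolerance = 1e-12)
  set.seed(12)
  expect_equal(genomic_inflation(runif(1e5)), 1, tolerance = 0.02)
  chi <- rchisq(1e5, 1) * 1.2
  p_inf <- pchisq(chi, 1, lower.tail = FALSE)
  expect_equal(genomic_inflation(p_inf), 1.2, tolerance = 0.03)
  expect_error(genomic_inflation(runif(50)), "100")
})

test_that("LD r2 is flip-invariant and matches direct recomputation", {
  set.seed(13)
  g1 <- rbinom(300, 2, 0.4)
  expect_equal(ld_r2(g1, g1), 1)
  expect_equal(ld_r2(g1, 2 - g1), 1)
  g2 <- rbinom(300, 2, 0.4)
  expect_equal(ld_r2(g1, g2), cor(g1, g2)^2, tolerance = 1e-12)
  expect_error(ld_r2(g1, rep(1, 300)), "zero variance")
})

test_that("locus definition matches the brute-force greedy oracle", {
  # no significant variants: empty set
  set.seed(14)
  cfg <- sim_config(n_subjects = 300, n_variants = 40, ld_block_size = 4,
                    ld_rho = 0.6, maf_range = c(0.2, 0.5),
                    outcome_log_odds = NULL, seed = 15)
  gt <- sample_genotypes(cfg)
  res0 <- association_scan(gt$geno, rnorm(300))
  expect_equal(length(define_loci_and_signals(res0, gt$geno,
                                              gt$variants)$loci), 0)

  # constructed p-values on <= 50 variants, several configurations
  for (s in 1:5) {
    set.seed(20 + s)
    res <- data.frame(pc = 1, variant_id = gt$variants$variant_id,
                      beta = 0, se = 1,
                      p = 10^(-runif(40, 0, 12)))
    ours <- define_loci_and_signals(res, gt$geno, gt$variants)
    orc <- oracle_loci(res, gt$variants, gt$geno)
    expect_equal(length(ours$loci), length(orc))
    for (i in seq_along(orc)) {
      expect_identical(ours$loci[[i]]$lead_id, orc[[i]]$lead)
      expect_identical(sort(ours$loci[[i]]$member_ids), orc[[i]]$members)
      expect_identical(sort(ours$loci[[i]]$signal_ids), orc[[i]]$signal)
    }
  }

  # two strong variants far apart and uncorrelated: two loci
  v2 <- data.frame(variant_id = c("a", "b"), chr = c(1, 1),
                   pos = c(1e6, 3e6), EA = "A", NEA = "G")
  g2 <- cbind(a = rbinom(500, 2, 0.3), b = rbinom(500, 2, 0.3))
  r2 <- data.frame(pc = 1, variant_id = c("a", "b"), beta = 1, se = 0.1,
                   p = c(1e-10, 1e-9))
  expect_equal(length(define_loci_and_signals(r2, g2, v2)$loci), 2)
  # same two variants 300 kb apart: one locus
  v2$pos <- c(1e6, 1.3e6)
  expect_equal(length(define_loci_and_signals(r2, g2, v2)$loci), 1)
})

test_that("conditional scan declares true secondaries and gates on p", {
  # two causal variants in weak LD at one locus
  set.seed(30)
  n <- 3000
  shared <- rnorm(n)
  l1 <- sqrt(0.22) * shared + sqrt(0.78) * rnorm(n)
  l2 <- sqrt(0.22) * shared + sqrt(0.78) * rnorm(n)
  thr <- function(l, p) (l > qnorm((1 - p)^2)) +
    (l > qnorm((1 - p)^2 + 2 * p * (1 - p)))
  g1 <- thr(l1, 0.4); g2 <- thr(l2, 0.4)
  filler <- sapply(1:8, function(i) rbinom(n, 2, 0.3))
  geno <- cbind(g1, g2, filler)
  colnames(geno) <- paste0("v", 1:10)
  variants <- data.frame(variant_id = paste0("v", 1:10), chr = 1,
                         pos = seq(1e6, by = 5e4, length.out = 10),
                         EA = "A", NEA = "G")
  y <- 0.25 * g1 + 0.25 * g2 + rnorm(n)
  res <- association_scan(geno, y)
  loci <- define_loci_and_signals(res, geno, variants)
  expect_equal(length(loci$loci), 1)
  sec <- conditional_secondary_scan(loci$loci[[1]], geno, y, results = res)
  expect_true("v2" %in% sec$variant_id || "v1" %in% sec$variant_id)

  # gate: original p above the suggestive bound is never declared
  res_gate <- res
  res_gate$p[res_gate$variant_id == "v2"] <- 1e-5
  sec_gate <- conditional_secondary_scan(loci$loci[[1]], geno, y,
                                         results = res_gate)
  expect_false("v2" %in% sec_gate$variant_id)
})

test_that("Haseman-Elston recovers h2, null and perfect genetic overlap", {
  cfg <- sim_config(n_subjects = 1500, n_points = 24, n_latent_modes = 2,
                    mode_sds = c(4, 2), n_variants = 1500, ld_rho = 0,
                    per_mode_h2 = c(0.4, 0.4), causal_per_mode = 10,
                    outcome_log_odds = NULL, seed = 31)
  gt <- sample_genotypes(cfg)
  pop <- sample_shape_population(cfg, make_template(24), gt)
  z <- pop$truth$true_latent_scores

  he <- he_heritability(gt$geno, z[, 1])
  expect_lt(abs(he$estimate - 0.4), 3 * he$se)
  expect_gt(he$se, 0)

  # pure-noise phenotype: estimate within 2 SE of zero
  set.seed(32)
  he0 <- he_heritability(gt$geno, rnorm(1500))
  expect_lt(abs(he0$estimate), 2 * he0$se)

  # identical phenotypes: genetic correlation exactly 1
  rg <- he_heritability(gt$geno, z[, 1], z[, 1])
  expect_equal(rg$estimate, 1, tolerance = 1e-6)

  expect_error(he_heritability(gt$geno[, 1:5], z[, 1]), "10 variants")
})

test_that("bivariate HE recovers a shared-architecture genetic correlation", {
  # same causal variants, correlated effect sizes (rho = 0.75)
  set.seed(33)
  n <- 2000; m <- 1500; nc <- 20; h2 <- 0.4
  geno <- matrix(rbinom(n * m, 2, 0.3), n, m)
  Zs <- scale(geno)
  j <- seq(1, m, length.out = nc)
  b1 <- rnorm(nc); b2 <- 0.75 * b1 + sqrt(1 - 0.75^2) * rnorm(nc)
  mk <- function(b) {
    g <- Zs[, j] %*% b
    g <- g * sqrt(h2) / sd(g)
    g + rnorm(n, sd = sqrt(1 - h2))
  }
  y1 <- mk(b1); y2 <- mk(b2)
  rg <- he_heritability(geno, y1, y2)
  expect_lt(abs(rg$estimate - cor(b1, b2)), 0.15)
})

test_that("percent variance explained is an incremental R-squared", {
  set.seed(34)
  n <- 500
  g <- rbinom(n, 2, 0.3)
  expect_equal(pct_variance_explained(0.3 * g, matrix(g, ncol = 1)), 100,
               tolerance = 1e-10)

  # null dosages: expected inflation ~ 100 * k / n, within 2x
  gnull <- matrix(rbinom(2000 * 10, 2, 0.3), 2000, 10)
  pv <- pct_variance_explained(rnorm(2000), gnull)
  expect_lt(pv, 2 * 100 * 10 / 2000)

  # 20 causal dosages each contributing ~0.1%
  n2 <- 4000
  g20 <- matrix(rbinom(n2 * 20, 2, 0.3), n2, 20)
  beta <- sqrt(0.001 / apply(g20, 2, var))
  y <- g20 %*% beta + rnorm(n2, sd = sqrt(1 - 0.02))
  expect_lt(abs(pct_variance_explained(y, g20) - 2), 0.7 * 2)
})
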