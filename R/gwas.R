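# Variant QC, dosage association scan, inflation and LD utilities.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test obtained by enumerating all heterozygote counts
#' compatible with the observed allele counts and summing the conditional
#' probabilities no larger than that of the observed genotype configuration
#' (the standard exact HWE construction).
#'
#' @param n_AA,n_Aa,n_aa nonnegative genotype counts (total at least 1).
#' @return exact p-value.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("counts must be nonnegative")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("need at least one genotype")
  n_a <- 2 * n_aa + n_Aa                 # rare-allele count (after swap)
  n_A <- 2 * n_AA + n_Aa
  if (n_a > n_A) { tmp <- n_a; n_a <- n_A; n_A <- tmp }
  if (n_a == 0) return(1)
  hets <- seq(n_a %% 2, n_a, by = 2)     # feasible heterozygote counts
  # log P(h) up to a constant: conditional on allele counts
  lp <- vapply(hets, function(h) {
    hom_r <- (n_a - h) / 2
    hom_c <- (2 * n - n_a - h) / 2
    h * log(2) - lgamma(h + 1) - lgamma(hom_r + 1) - lgamma(hom_c + 1)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- min(n_Aa, n_a)                  # observed het count on rare scale
  p_obs <- pr[match(obs, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-10)]))
}

#' Variant quality control
#'
#' Recomputes per-variant statistics from the dosage matrix and keeps
#' variants with minor allele frequency above `maf_min`, exact
#' Hardy-Weinberg p-value at or above `hwe_min`, and missing rate below
#' `missing_max`. Hardy-Weinberg counts come from hard calls (dosages
#' rounded to the nearest integer).
#'
#' @param geno subjects x variants dosage matrix in `[0, 2]` (NA allowed).
#' @param variants variant table (matching column order).
#' @param maf_min,hwe_min,missing_max filter thresholds, each in (0, 1).
#' @return list with filtered `geno` and `variants` (statistics updated)
#'   and `n_excluded`, a named vector of per-filter exclusion counts.
#' @export
variant_qc <- function(geno, variants, maf_min = 0.01, hwe_min = 1e-6,
                       missing_max = 0.015) {
  stopifnot(ncol(geno) == nrow(variants))
  miss <- colMeans(is.na(geno))
  eaf <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(eaf, 1 - eaf)
  hard <- round(geno)
  hwe_p <- vapply(seq_len(ncol(geno)), function(j) {
    g <- hard[, j]
    g <- g[!is.na(g)]
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))
  fail_maf <- maf <= maf_min
  fail_hwe <- hwe_p < hwe_min
  fail_miss <- miss >= missing_max
  keep <- !(fail_maf | fail_hwe | fail_miss)
  if (!any(keep)) stop("no variants survive QC")
  variants <- variants[keep, , drop = FALSE]
  variants$EAF <- eaf[keep]
  variants$maf <- maf[keep]
  variants$hwe_p <- hwe_p[keep]
  variants$missing_rate <- miss[keep]
  rownames(variants) <- NULL
  list(geno = geno[, keep, drop = FALSE], variants = variants,
       n_excluded = c(maf = sum(fail_maf), hwe = sum(fail_hwe),
                      missing = sum(fail_miss)))
}

#' Per-variant additive association scan
#'
#' Ordinary least squares of the phenotype on each variant's dosage plus
#' covariates, vectorised by residualising phenotype and dosages on the
#' covariates once (mathematically identical to the per-variant joint fit
#' by Frisch-Waugh-Lovell, with degrees of freedom `n - rank(covars) - 1`).
#' Missing dosages are mean-imputed; constant dosages are skipped with a
#' warning. Betas are per copy of the effect allele.
#'
#' @param geno subjects x variants dosage matrix (column names = ids).
#' @param phenotype numeric vector, complete.
#' @param covars optional data.frame/matrix of covariates (complete).
#' @param pc label recorded in the `pc` column of the result.
#' @return data.frame: `pc`, `variant_id`, `beta`, `se`, `p`.
#' @export
association_scan <- function(geno, phenotype, covars = NULL, pc = NA) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  if (length(phenotype) != n) stop("phenotype length mismatch")
  if (anyNA(phenotype)) stop("phenotype must be complete")
  if (anyNA(geno)) {
    mu <- colMeans(geno, na.rm = TRUE)
    idx <- which(is.na(geno), arr.ind = TRUE)
    geno[idx] <- mu[idx[, 2L]]
  }
  C <- if (is.null(covars)) matrix(1, n, 1L)
       else cbind(1, as.matrix(as.data.frame(covars)))
  if (anyNA(C)) stop("covariates must be complete")
  qc <- qr(C)
  my <- qr.resid(qc, phenotype)
  mg <- qr.resid(qc, geno)
  gg <- colSums(mg^2)
  const <- gg < 1e-10 * n
  if (any(const)) {
    warning(sprintf("skipping %d constant dosage column(s)", sum(const)))
    mg <- mg[, !const, drop = FALSE]
    gg <- gg[!const]
  }
  gy <- colSums(mg * my)
  beta <- gy / gg
  df <- n - qc$rank - 1L
  rss <- sum(my^2) - beta^2 * gg
  sigma2 <- pmax(rss, 0) / df
  se <- sqrt(sigma2 / gg)
  tstat <- beta / se
  ids <- colnames(geno)
  if (is.null(ids)) ids <- sprintf("var%05d", seq_len(ncol(geno)))
  data.frame(pc = pc, variant_id = ids[!const], beta = beta, se = se,
             p = 2 * pt(abs(tstat), df, lower.tail = FALSE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Genomic inflation factor
#'
#' Median-based lambda: the median of the 1-df chi-square statistics
#' implied by the p-values divided by the null median `qchisq(0.5, 1)`
#' (about 0.4549).
#'
#' @param p_values vector of at least 100 p-values.
#' @return lambda.
#' @export
genomic_inflation <- function(p_values) {
  if (length(p_values) < 100L) stop("need at least 100 p-values")
  chi <- qchisq(p_values, df = 1, lower.tail = FALSE)
  median(chi) / qchisq(0.5, df = 1)
}

#' Squared dosage correlation (LD r^2)
#'
#' @param g1,g2 dosage vectors of equal length with nonzero variance.
#' @return squared Pearson correlation.
#' @export
ld_r2 <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("dosage vectors differ in length")
  ok <- !is.na(g1) & !is.na(g2)
  if (sd(g1[ok]) == 0 || sd(g2[ok]) == 0) stop("zero variance dosage")
  cor(g1[ok], g2[ok])^2
}
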