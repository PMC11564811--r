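# Synthetic genotype dosages with block LD structure.

#' Simulate biallelic genotype dosages with LD blocks
#'
#' Within each block of `cfg$ld_block_size` consecutive variants, latent
#' standard Gaussians share a pairwise correlation `cfg$ld_rho` (single
#' common factor); across blocks variants are independent. Each latent value
#' is thresholded at the Hardy-Weinberg genotype frequencies of the
#' variant's simulated minor-allele frequency, yielding hard 0/1/2 effect
#' allele counts. The realized dosage correlation is attenuated relative to
#' the latent `ld_rho` (tetrachoric thresholding), which the LD-dependent
#' procedures are tested against empirically rather than analytically.
#'
#' Variants are laid out on synthetic chromosomes at `cfg$pos_spacing_bp`
#' intervals (1-based positions), at most 22 chromosomes, with LD blocks
#' never straddling a chromosome break. If `cfg$missing_rate > 0`, dosages
#' are masked at random (pre-QC missingness).
#'
#' @param cfg a [sim_config].
#' @param variants optional variant table from a previous call: reuses its
#'   positions, alleles, LD blocks and simulated MAFs so a second cohort
#'   (e.g. a held-out scoring cohort) is drawn from the same population.
#' @return list with `geno` (subjects x variants dosage matrix, dimnames
#'   set) and `variants` (data.frame: variant_id, chr, pos, EA, NEA, EAF,
#'   maf, hwe_p, missing_rate, block; attribute `sim_maf` carries the
#'   generating MAFs).
#' @export
sample_genotypes <- function(cfg, variants = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 202L)
  n <- cfg$n_subjects
  m <- cfg$n_variants
  bsz <- cfg$ld_block_size
  if (!is.null(variants) && nrow(variants) != m)
    stop("`variants` does not match `cfg$n_variants`")
  n_blocks <- if (is.null(variants)) ceiling(m / bsz)
              else max(variants$block)
  block <- if (is.null(variants)) rep(seq_len(n_blocks), each = bsz)[seq_len(m)]
           else variants$block

  # MAF is drawn per block: variants in strong LD are necessarily
  # frequency-matched (r^2 is bounded by allele-frequency mismatch)
  maf <- if (is.null(variants))
    runif(n_blocks, cfg$maf_range[1], cfg$maf_range[2])[block]
  else attr(variants, "sim_maf")
  rho <- cfg$ld_rho
  shared <- matrix(rnorm(n * n_blocks), n, n_blocks)
  lat <- sqrt(rho) * shared[, block, drop = FALSE] +
    sqrt(1 - rho) * matrix(rnorm(n * m), n, m)

  f0 <- (1 - maf)^2                      # P(0 copies of EA) under HWE
  t1 <- qnorm(f0)
  t2 <- qnorm(f0 + 2 * maf * (1 - maf))
  geno <- sweep(lat, 2, t1, ">") + sweep(lat, 2, t2, ">")
  storage.mode(geno) <- "double"

  if (cfg$missing_rate > 0)
    geno[matrix(runif(n * m) < cfg$missing_rate, n, m)] <- NA_real_

  if (is.null(variants)) {
    blocks_per_chr <- ceiling(n_blocks / 22)
    chr <- (block - 1L) %/% blocks_per_chr + 1L
    idx_in_chr <- stats::ave(seq_len(m), chr, FUN = seq_along)
    pos <- as.integer(idx_in_chr) * cfg$pos_spacing_bp + 1L
    nts <- c("A", "C", "G", "T")
    ea <- sample(nts, m, replace = TRUE)
    nea <- vapply(ea, function(a) sample(setdiff(nts, a), 1L), character(1))
    variant_id <- sprintf("var%05d", seq_len(m))
  } else {
    chr <- variants$chr
    pos <- variants$pos
    ea <- variants$EA
    nea <- variants$NEA
    variant_id <- variants$variant_id
  }
  dimnames(geno) <- list(sprintf("S%05d", seq_len(n)), variant_id)

  eaf <- colMeans(geno, na.rm = TRUE) / 2
  hard <- round(geno)
  hwe_p <- vapply(seq_len(m), function(j) {
    g <- hard[, j]
    g <- g[!is.na(g)]
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))

  vt <- data.frame(
    variant_id = variant_id, chr = chr, pos = pos, EA = ea, NEA = unname(nea),
    EAF = unname(eaf), maf = pmin(eaf, 1 - eaf),
    hwe_p = hwe_p, missing_rate = colMeans(is.na(geno)),
    block = block, row.names = NULL, stringsAsFactors = FALSE)
  attr(vt, "sim_maf") <- maf
  list(geno = geno, variants = vt)
}
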