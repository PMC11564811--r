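#' Simulation configuration
#'
#' Collects every tunable of the synthetic cohort generator with validation.
#' All stochastic generators derive their RNG stream from `seed` plus a fixed
#' documented per-operation offset (shape population +101, genotypes +202,
#' covariates/outcomes +303), so one config reproduces the whole cohort
#' bitwise and the individual generators remain independently reproducible.
#'
#' @param n_subjects cohort size.
#' @param n_points template points `P` per mesh.
#' @param n_latent_modes number of latent shape modes `K`.
#' @param mode_sds length-`K`, strictly decreasing, non-negative: per-point
#'   RMS displacement amplitude of each latent mode, in mm (one latent-score
#'   SD moves every coordinate by `mode_sds[k]` mm RMS).
#' @param noise_sd iid per-coordinate measurement noise SD, mm.
#' @param n_variants number of biallelic variants `m`.
#' @param maf_range range of simulated minor-allele frequencies, within
#'   `(0, 0.5]`.
#' @param ld_block_size variants per LD block.
#' @param ld_rho latent pairwise correlation within a block, in `[0, 1)`.
#' @param per_mode_h2 length-`K` additive heritability of each latent score,
#'   each in `[0, 1)`.
#' @param causal_per_mode causal variants per latent mode (one per LD block).
#' @param outcome_log_odds named list, one entry per binary outcome: a
#'   length-`K` vector of log odds ratios per SD of each latent score.
#' @param outcome_prevalence named vector of target outcome prevalences.
#' @param missing_rate dosage missingness rate (pre-QC).
#' @param pos_spacing_bp base-pair spacing between adjacent variants on a
#'   synthetic chromosome.
#' @param n_outliers,outlier_sd,outlier_mode number of injected shape
#'   outliers, their latent-score displacement (SD units) and the mode they
#'   are displaced along (for QC validation).
#' @param seed integer master seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 500L, n_points = 300L,
                       n_latent_modes = 5L,
                       mode_sds = c(10, 6, 4, 2, 1), noise_sd = 0.5,
                       n_variants = 1000L, maf_range = c(0.05, 0.5),
                       ld_block_size = 10L, ld_rho = 0.3,
                       per_mode_h2 = rep(0.3, n_latent_modes),
                       causal_per_mode = 5L,
                       outcome_log_odds = list(
                         af = c(0, 0, log(1.5), 0, 0)[seq_len(n_latent_modes)],
                         diabetes = c(-log(2), 0, 0, 0, 0)[seq_len(n_latent_modes)]),
                       outcome_prevalence = c(af = 0.05, diabetes = 0.08),
                       missing_rate = 0, pos_spacing_bp = 20000L,
                       n_outliers = 0L, outlier_sd = 8, outlier_mode = 1L,
                       seed = 1L) {
  K <- as.integer(n_latent_modes)
  if (length(mode_sds) != K) stop("`mode_sds` must have length n_latent_modes")
  if (K > 1 && any(diff(mode_sds) >= 0))
    stop("`mode_sds` must be strictly decreasing")
  if (any(mode_sds < 0)) stop("`mode_sds` must be non-negative")
  if (length(per_mode_h2) != K)
    stop("`per_mode_h2` must have length n_latent_modes")
  if (any(per_mode_h2 < 0 | per_mode_h2 >= 1))
    stop("`per_mode_h2` entries must lie in [0, 1)")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("`maf_range` must lie within (0, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1) stop("`ld_rho` must be in [0, 1)")
  if (n_variants < ld_block_size)
    stop("`n_variants` must be at least `ld_block_size`")
  if (!is.null(outcome_log_odds)) {
    if (!all(lengths(outcome_log_odds) == K))
      stop("each `outcome_log_odds` entry must have length n_latent_modes")
    if (!all(names(outcome_log_odds) %in% names(outcome_prevalence)))
      stop("every outcome needs a target prevalence")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_points = as.integer(n_points),
    n_latent_modes = K, mode_sds = as.numeric(mode_sds),
    noise_sd = as.numeric(noise_sd), n_variants = as.integer(n_variants),
    maf_range = as.numeric(maf_range),
    ld_block_size = as.integer(ld_block_size), ld_rho = as.numeric(ld_rho),
    per_mode_h2 = as.numeric(per_mode_h2),
    causal_per_mode = as.integer(causal_per_mode),
    outcome_log_odds = outcome_log_odds,
    outcome_prevalence = outcome_prevalence,
    missing_rate = as.numeric(missing_rate),
    pos_spacing_bp = as.integer(pos_spacing_bp),
    n_outliers = as.integer(n_outliers), outlier_sd = as.numeric(outlier_sd),
    outlier_mode = as.integer(outlier_mode), seed = as.integer(seed)),
    class = "sim_config")
}
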