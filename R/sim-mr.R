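# Synthetic two-sample GWAS summary statistics for Mendelian randomization.

#' Simulate exposure/outcome GWAS summary statistics
#'
#' Two-sample design: per-variant true exposure effects are drawn, then
#' observed exposure and outcome estimates get independent Gaussian noise at
#' their stated standard errors (independent samples). The true outcome
#' effect is `causal_effect * beta_exposure + pleiotropy`. With
#' `allele_scramble = TRUE` every second variant is emitted in the outcome
#' table with effect/non-effect alleles swapped, beta negated and EAF
#' complemented, which [harmonize_instruments] must undo. Allele pairs are
#' non-palindromic so no instrument is lost to the strand-ambiguity filter
#' by default.
#'
#' Defaults emulate strong instruments at biobank scale: exposure betas
#' N(0.15, 0.03^2) with SE 0.01 (F around 225) and outcome SE 0.008.
#'
#' @param cfg list overriding any of `n_instruments` (>= 3),
#'   `causal_effect`, `beta_exposure_mean`, `beta_exposure_sd`,
#'   `se_exposure`, `se_outcome`, `pleiotropy` (constant added to every
#'   outcome effect), `allele_scramble`, `seed`.
#' @return list with `exposure_stats` and `outcome_stats` (data.frames:
#'   variant_id, chr, pos, EA, NEA, EAF, BETA, SE, P) and `truth`
#'   (causal_effect, true betas, pleiotropy, scrambled ids).
#' @export
make_mr_summary_stats <- function(cfg = list()) {
  par <- utils::modifyList(
    list(n_instruments = 30L, causal_effect = 0.2,
         beta_exposure_mean = 0.15, beta_exposure_sd = 0.03,
         se_exposure = 0.01, se_outcome = 0.008,
         pleiotropy = 0, allele_scramble = FALSE, seed = 1L), cfg)
  k <- as.integer(par$n_instruments)
  if (k < 3L) stop("`n_instruments` must be at least 3")
  set.seed(par$seed + 404L)

  bx_true <- rnorm(k, par$beta_exposure_mean, par$beta_exposure_sd)
  bx <- bx_true + rnorm(k, sd = par$se_exposure)
  by_true <- par$causal_effect * bx_true + par$pleiotropy
  by <- by_true + rnorm(k, sd = par$se_outcome)

  pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                c("G", "A"), c("C", "A"))  # non-palindromic
  al <- pairs[sample(length(pairs), k, replace = TRUE)]
  ea <- vapply(al, `[`, character(1), 1L)
  nea <- vapply(al, `[`, character(1), 2L)
  eaf <- runif(k, 0.1, 0.9)

  ids <- sprintf("iv%03d", seq_len(k))
  chr <- rep(seq_len(22), length.out = k)
  pos <- as.integer(stats::ave(seq_len(k), chr, FUN = seq_along)) * 20000000L

  zstat <- function(b, se) 2 * pnorm(-abs(b / se))
  se_x <- rep(par$se_exposure, k)
  se_y <- rep(par$se_outcome, k)
  exposure <- data.frame(variant_id = ids, chr = chr, pos = pos, EA = ea,
                         NEA = nea, EAF = eaf, BETA = bx, SE = se_x,
                         P = zstat(bx, pmax(se_x, 1e-300)),
                         stringsAsFactors = FALSE)
  outcome <- data.frame(variant_id = ids, chr = chr, pos = pos, EA = ea,
                        NEA = nea, EAF = eaf, BETA = by, SE = se_y,
                        P = zstat(by, pmax(se_y, 1e-300)),
                        stringsAsFactors = FALSE)

  scrambled <- character(0)
  if (isTRUE(par$allele_scramble)) {
    flip <- seq_len(k) %% 2L == 1L     # half of the variants
    scrambled <- ids[flip]
    tmp <- outcome$EA[flip]
    outcome$EA[flip] <- outcome$NEA[flip]
    outcome$NEA[flip] <- tmp
    outcome$BETA[flip] <- -outcome$BETA[flip]
    outcome$EAF[flip] <- 1 - outcome$EAF[flip]
  }
  list(exposure_stats = exposure, outcome_stats = outcome,
       truth = list(causal_effect = par$causal_effect,
                    beta_exposure_true = bx_true,
                    beta_outcome_true = by_true,
                    beta_exposure_obs = bx, beta_outcome_obs = by,
                    pleiotropy = par$pleiotropy, scrambled_ids = scrambled))
}
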