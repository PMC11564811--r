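# Locus/signal definition and conditional secondary-signal analysis.

#' Define loci and signals from a scan
#'
#' Greedy locus construction: take the smallest-p genome-wide significant
#' variant as lead (ties broken by chromosome then position), open a
#' `+/- window_kb` closed window around it (the locus), record the signal
#' members (variants inside the window with LD `r^2 > signal_r2` to the
#' lead, i.e. within 1 Mb at the defaults) and the high-LD proxies
#' (`r^2 >= proxy_r2`), remove all window variants from candidacy, repeat.
#'
#' @param results scan results ([association_scan] output).
#' @param geno dosage matrix with columns named by variant id (for LD).
#' @param variants variant table (id, chr, pos).
#' @param gw_p genome-wide significance threshold (default 5e-8).
#' @param window_kb half-window in kb (default 500).
#' @param signal_r2 LD threshold defining signal membership (default 0.1).
#' @param proxy_r2 LD threshold defining high-LD proxies (default 0.8).
#' @return A `locus_set`: list of loci, each with `lead_id`, `chr`, `pos`,
#'   `p_lead`, `window` (bp bounds), `member_ids`, `signal_ids`,
#'   `proxy_ids`. Empty when nothing is significant.
#' @export
define_loci_and_signals <- function(results, geno, variants, gw_p = 5e-8,
                                    window_kb = 500, signal_r2 = 0.1,
                                    proxy_r2 = 0.8) {
  df <- merge(results, variants[, c("variant_id", "chr", "pos")],
              by = "variant_id", sort = FALSE)
  cand <- df[df$p < gw_p, , drop = FALSE]
  cand <- cand[order(cand$p, cand$chr, cand$pos), , drop = FALSE]
  win <- window_kb * 1000
  loci <- list()
  while (nrow(cand) > 0L) {
    lead <- cand[1L, ]
    in_win <- variants$chr == lead$chr &
      abs(variants$pos - lead$pos) <= win
    member_ids <- variants$variant_id[in_win]
    g_lead <- geno[, lead$variant_id]
    r2 <- vapply(member_ids, function(id) {
      if (id == lead$variant_id) return(1)
      tryCatch(ld_r2(g_lead, geno[, id]), error = function(e) 0)
    }, numeric(1))
    loci[[length(loci) + 1L]] <- list(
      lead_id = lead$variant_id, chr = lead$chr, pos = lead$pos,
      p_lead = lead$p,
      window = c(lead$pos - win, lead$pos + win),
      member_ids = member_ids,
      signal_ids = member_ids[r2 > signal_r2],
      proxy_ids = member_ids[r2 >= proxy_r2])
    drop_ids <- member_ids
    cand <- cand[!(cand$variant_id %in% drop_ids), , drop = FALSE]
  }
  structure(list(loci = loci, gw_p = gw_p, window_kb = window_kb,
                 signal_r2 = signal_r2, proxy_r2 = proxy_r2),
            class = "locus_set")
}

#' @export
print.locus_set <- function(x, ...) {
  cat(sprintf("<locus_set> %d loci (p < %g, +/-%g kb)\n",
              length(x$loci), x$gw_p, x$window_kb))
  invisible(x)
}

#' Conditional scan for secondary signals at a locus
#'
#' Refits every locus variant with the lead variant's dosage added to the
#' covariates. A candidate is declared a secondary signal when (1) its
#' original marginal p-value is below `suggestive_p`, (2)
#' `-log10(p_lead) / -log10(p_sec) < ratio`, and (3)
#' `-log10(p_sec) / -log10(p_cond) < ratio`. The default `rule = "all"` is
#' the conservative conjunction of the three conditions; `rule = "any"`
#' gives the literal disjunctive variant. Candidates nearly collinear with
#' the lead (`r^2 > 0.99`) are skipped.
#'
#' @param locus one element of a `locus_set`'s `loci` list.
#' @param geno dosage matrix (columns named by variant id).
#' @param phenotype,covars as in [association_scan].
#' @param results marginal scan results (source of original p-values).
#' @param suggestive_p original-p gate (default 1e-6).
#' @param ratio maximum -log10 fold difference (default 1.5).
#' @param rule `"all"` (conjunction, default) or `"any"` (disjunction).
#' @return data.frame of declared secondaries (`variant_id`, `p_orig`,
#'   `p_cond`), ordered by conditional p; zero rows when none qualify.
#' @export
conditional_secondary_scan <- function(locus, geno, phenotype, covars = NULL,
                                       results, suggestive_p = 1e-6,
                                       ratio = 1.5,
                                       rule = c("all", "any")) {
  rule <- match.arg(rule)
  lead_id <- locus$lead_id
  g_lead <- geno[, lead_id]
  cand_ids <- setdiff(intersect(locus$member_ids, colnames(geno)), lead_id)
  cand_ids <- intersect(cand_ids, results$variant_id)
  if (length(cand_ids) == 0L)
    return(data.frame(variant_id = character(0), p_orig = numeric(0),
                      p_cond = numeric(0)))
  r2 <- vapply(cand_ids, function(id)
    tryCatch(ld_r2(g_lead, geno[, id]), error = function(e) 1), numeric(1))
  cand_ids <- cand_ids[r2 <= 0.99]
  if (length(cand_ids) == 0L)
    return(data.frame(variant_id = character(0), p_orig = numeric(0),
                      p_cond = numeric(0)))
  cv <- if (is.null(covars)) data.frame(lead = g_lead)
        else cbind(as.data.frame(covars), lead = g_lead)
  cond <- suppressWarnings(
    association_scan(geno[, cand_ids, drop = FALSE], phenotype, cv))
  p_orig <- results$p[match(cond$variant_id, results$variant_id)]
  p_lead <- results$p[match(lead_id, results$variant_id)]
  l10 <- function(p) -log10(pmax(p, 1e-300))
  c1 <- p_orig < suggestive_p
  c2 <- l10(p_lead) / l10(p_orig) < ratio
  c3 <- l10(p_orig) / l10(cond$p) < ratio
  declared <- if (rule == "all") c1 & c2 & c3 else c1 | c2 | c3
  out <- data.frame(variant_id = cond$variant_id, p_orig = p_orig,
                    p_cond = cond$p, stringsAsFactors = FALSE)[declared, ,
                                                              drop = FALSE]
  out[order(out$p_cond), , drop = FALSE]
}
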