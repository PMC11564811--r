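# Lead-variant polygenic risk scores.

#' Build a PRS model
#'
#' A polygenic risk score model is the list of lead variants with their
#' effect alleles and GWAS effect-size weights; scoring sums effect-allele
#' dosages weighted by effect size.
#'
#' @param variant_id,EA,weight parallel vectors (ids unique, weights
#'   finite).
#' @param pc optional label of the shape PC the model predicts.
#' @return data.frame of class `prs_model`.
#' @export
prs_model <- function(variant_id, EA, weight, pc = NA) {
  if (anyDuplicated(variant_id)) stop("model variant ids must be unique")
  if (!all(is.finite(weight))) stop("weights must be finite")
  structure(data.frame(variant_id = variant_id, EA = EA, weight = weight,
                       stringsAsFactors = FALSE),
            pc = pc, class = c("prs_model", "data.frame"))
}

#' Score a cohort with a PRS model
#'
#' Raw score per subject: `sum_j weight_j * dosage_j`, with each dosage
#' counted on the model's effect allele (a variant stored on the opposite
#' allele contributes `2 - g`). Model variants absent from the cohort are
#' substituted from `proxies` when given (columns `variant_id`, `proxy_id`,
#' optional logical `flip` for allele-reversed proxies); otherwise scoring
#' errors and lists the missing ids. Scores are z-standardized on the
#' scoring cohort (mean/SD kept as attributes).
#'
#' @param model a [prs_model].
#' @param geno dosage matrix with columns named by variant id.
#' @param variants variant table for `geno` (id, EA, NEA).
#' @param proxies optional proxy substitution table.
#' @return numeric standardized score vector with attributes `raw`,
#'   `center`, `scale`.
#' @export
score_prs <- function(model, geno, variants, proxies = NULL) {
  stopifnot(inherits(model, "prs_model"))
  used_id <- model$variant_id
  if (!is.null(proxies)) {
    miss <- !(used_id %in% colnames(geno))
    sub <- match(used_id, proxies$variant_id)
    repl <- miss & !is.na(sub) & proxies$proxy_id[sub] %in% colnames(geno)
    used_id[repl] <- proxies$proxy_id[sub[repl]]
  }
  missing_ids <- setdiff(used_id, colnames(geno))
  if (length(missing_ids))
    stop(sprintf("model variants missing from genotypes (no proxy): %s",
                 paste(missing_ids, collapse = ", ")))
  vt <- variants[match(used_id, variants$variant_id), ]
  G <- geno[, used_id, drop = FALSE]
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2L]]
  }
  for (j in seq_along(used_id)) {
    same <- identical(vt$EA[j], model$EA[j]) ||
      (used_id[j] != model$variant_id[j])   # proxies counted as stored
    if (used_id[j] != model$variant_id[j] && !is.null(proxies)) {
      k <- match(model$variant_id[j], proxies$variant_id)
      if (!is.null(proxies$flip) && isTRUE(proxies$flip[k]))
        G[, j] <- 2 - G[, j]
    } else if (!same) {
      if (identical(vt$NEA[j], model$EA[j])) G[, j] <- 2 - G[, j]
      else stop(sprintf("allele mismatch for %s", used_id[j]))
    }
  }
  raw <- as.numeric(G %*% model$weight)
  s <- sd(raw)
  if (s == 0) {
    warning("degenerate PRS (zero variance); returning zeros")
    out <- rep(0, length(raw))
  } else out <- (raw - mean(raw)) / s
  attr(out, "raw") <- raw
  attr(out, "center") <- mean(raw)
  attr(out, "scale") <- s
  out
}

#' PRS-disease association
#'
#' Logistic regression of disease status on the standardized PRS plus
#' covariates; reports the odds ratio per SD of PRS with Wald 95% CI.
#'
#' @param scores standardized PRS vector (from [score_prs]).
#' @param outcome 0/1 vector (at least 10 cases).
#' @param covars optional covariate data.frame.
#' @param ... labels passed to [logistic_odds_ratio].
#' @return one-row association data.frame.
#' @export
prs_disease_association <- function(scores, outcome, covars = NULL, ...) {
  logistic_odds_ratio(as.numeric(scores), outcome, covars,
                      score_name = "prs", ...)
}

#' PRS transferability across cohorts
#'
#' For each named group, reports (a) the percentage of PC-score variance
#' the PRS explains incrementally over covariates (via
#' [pct_variance_explained]) and (b) the per-variant effect-allele
#' frequency with a flag for EAF below 1%, the regime in which a
#' European-derived score loses information in other ancestries.
#'
#' @param model a [prs_model].
#' @param cohorts named list; each element a list with `geno`, `variants`,
#'   `pc_scores` (numeric) and optional `covars`.
#' @param low_freq_threshold EAF flag threshold (default 0.01).
#' @return named list per group: `n`, `r2_pct`, `freq_table`
#'   (`variant_id`, `EA`, `EAF`, `low_freq`).
#' @export
prs_transferability <- function(model, cohorts, low_freq_threshold = 0.01) {
  stopifnot(inherits(model, "prs_model"), length(cohorts) >= 1L)
  lapply(cohorts, function(co) {
    n <- nrow(co$geno)
    if (n < 50L)
      warning(sprintf("group has only %d subjects; estimates unstable", n))
    sc <- score_prs(model, co$geno, co$variants)
    r2_pct <- pct_variance_explained(co$pc_scores,
                                     matrix(as.numeric(sc), ncol = 1L),
                                     co$covars)
    vt <- co$variants[match(model$variant_id, co$variants$variant_id), ]
    eaf <- vt$EAF
    flip <- !is.na(vt$EA) & vt$EA != model$EA & vt$NEA == model$EA
    eaf[flip] <- 1 - eaf[flip]
    freq <- data.frame(variant_id = model$variant_id, EA = model$EA,
                       EAF = eaf, low_freq = !is.na(eaf) &
                         eaf < low_freq_threshold,
                       stringsAsFactors = FALSE)
    list(n = n, r2_pct = r2_pct, freq_table = freq)
  })
}
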