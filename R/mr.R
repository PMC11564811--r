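# Two-sample Mendelian randomization: harmonization, filtering, estimators.

.palindromic <- function(ea, nea) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  !is.na(comp[ea]) & comp[ea] == nea
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome effects to the exposure's effect allele: rows whose
#' alleles already match are kept, rows with effect/non-effect alleles
#' reversed get their outcome beta negated and EAF complemented, and rows
#' whose allele sets neither match nor swap are dropped with a warning.
#' Strand-ambiguous palindromic variants (A/T, C/G) with exposure EAF in
#' `palindrome_window` are dropped. Exposure variants missing from the
#' outcome table can be replaced by their highest-`r^2` proxy present in
#' the outcome table when a genotype reference is supplied; the proxy's
#' outcome effect is sign-aligned by the dosage correlation. Instrument
#' strength `F = (beta_x / se_x)^2` is attached.
#'
#' @param exposure,outcome summary-statistic data.frames (columns
#'   `variant_id`, `chr`, `pos`, `EA`, `NEA`, `EAF`, `BETA`, `SE`, `P`).
#' @param ref_geno optional dosage matrix (columns named by variant id)
#'   used to find proxies for missing variants.
#' @param proxy_r2_min minimum proxy LD `r^2` (default 0.8).
#' @param palindrome_window exposure-EAF interval inside which palindromic
#'   variants are considered unresolvable (default `c(0.42, 0.58)`).
#' @return data.frame of class `mr_instruments`: `variant_id`, `chr`,
#'   `pos`, `EA`, `NEA`, `eaf`, `beta_exposure`, `se_exposure`,
#'   `p_exposure`, `beta_outcome`, `se_outcome`, `F`, `proxy_id`.
#' @export
harmonize_instruments <- function(exposure, outcome, ref_geno = NULL,
                                  proxy_r2_min = 0.8,
                                  palindrome_window = c(0.42, 0.58)) {
  out_ids <- outcome$variant_id
  rows <- list()
  for (i in seq_len(nrow(exposure))) {
    ex <- exposure[i, ]
    proxy_id <- NA_character_
    j <- match(ex$variant_id, out_ids)
    sign_flip <- 1
    if (is.na(j) && !is.null(ref_geno) &&
        ex$variant_id %in% colnames(ref_geno)) {
      cand <- intersect(out_ids, colnames(ref_geno))
      cand <- setdiff(cand, ex$variant_id)
      if (length(cand)) {
        g0 <- ref_geno[, ex$variant_id]
        rr <- vapply(cand, function(id)
          tryCatch(cor(g0, ref_geno[, id], use = "complete.obs"),
                   error = function(e) 0), numeric(1))
        best <- which.max(rr^2)
        if (rr[best]^2 >= proxy_r2_min) {
          proxy_id <- cand[best]
          j <- match(proxy_id, out_ids)
          sign_flip <- sign(rr[best])
        }
      }
    }
    if (is.na(j)) next
    oc <- outcome[j, ]
    if (is.na(proxy_id)) {
      if (oc$EA == ex$EA && oc$NEA == ex$NEA) {
        by <- oc$BETA
      } else if (oc$EA == ex$NEA && oc$NEA == ex$EA) {
        by <- -oc$BETA
      } else {
        warning(sprintf("incompatible alleles for %s; dropped",
                        ex$variant_id))
        next
      }
      if (.palindromic(ex$EA, ex$NEA) &&
          ex$EAF > palindrome_window[1] && ex$EAF < palindrome_window[2])
        next
    } else {
      by <- sign_flip * oc$BETA
    }
    rows[[length(rows) + 1L]] <- data.frame(
      variant_id = ex$variant_id, chr = ex$chr, pos = ex$pos,
      EA = ex$EA, NEA = ex$NEA, eaf = ex$EAF,
      beta_exposure = ex$BETA, se_exposure = ex$SE, p_exposure = ex$P,
      beta_outcome = by, se_outcome = oc$SE,
      F = (ex$BETA / ex$SE)^2, proxy_id = proxy_id,
      stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, rows)
         else data.frame(variant_id = character(0))
  structure(res, class = c("mr_instruments", "data.frame"))
}

#' Keep strong instruments
#'
#' Retains instruments with `F` strictly greater than `f_min` (default 10,
#' the conventional weak-instrument bound).
#'
#' @param instruments an `mr_instruments` data.frame.
#' @param f_min strength bound.
#' @return filtered `mr_instruments`; errors when nothing survives.
#' @export
strength_filter <- function(instruments, f_min = 10) {
  keep <- instruments$F > f_min
  if (!any(keep)) stop("no instruments with F above the bound")
  instruments[keep, , drop = FALSE]
}

#' LD-clump instruments against a genotype reference
#'
#' Greedy pruning by ascending exposure p-value: an instrument within
#' `window_kb` of an already-kept instrument on the same chromosome with
#' dosage `r^2 > r2_max` is dropped. Instruments absent from the reference
#' are dropped with a warning.
#'
#' @param instruments an `mr_instruments` data.frame.
#' @param geno_ref reference dosage matrix (columns named by variant id).
#' @param r2_max LD ceiling (default 0.001).
#' @param window_kb clumping window in kb (default 10000, i.e. 10 Mb).
#' @return clumped `mr_instruments`.
#' @export
ld_clump <- function(instruments, geno_ref, r2_max = 0.001,
                     window_kb = 10000) {
  present <- instruments$variant_id %in% colnames(geno_ref)
  if (any(!present)) {
    warning(sprintf("dropping %d instrument(s) absent from the reference",
                    sum(!present)))
    instruments <- instruments[present, , drop = FALSE]
  }
  ord <- order(instruments$p_exposure)
  inst <- instruments[ord, , drop = FALSE]
  win <- window_kb * 1000
  kept <- integer(0)
  for (i in seq_len(nrow(inst))) {
    ok <- TRUE
    for (k in kept) {
      if (inst$chr[i] == inst$chr[k] &&
          abs(inst$pos[i] - inst$pos[k]) <= win) {
        r2 <- tryCatch(ld_r2(geno_ref[, inst$variant_id[i]],
                             geno_ref[, inst$variant_id[k]]),
                       error = function(e) 1)
        if (r2 > r2_max) { ok <- FALSE; break }
      }
    }
    if (ok) kept <- c(kept, i)
  }
  inst[kept, , drop = FALSE]
}

.mr_estimate <- function(method, estimate, se, p, n, intercept = NA,
                         intercept_p = NA) {
  structure(list(method = method, estimate = estimate, se = se,
                 ci95 = c(estimate - 1.96 * se, estimate + 1.96 * se),
                 p = p, intercept = intercept, intercept_p = intercept_p,
                 n_instruments = n), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s: %.4f (95%% CI %.4f, %.4f), p = %.3g, k = %d\n",
              x$method, x$estimate, x$ci95[1], x$ci95[2], x$p,
              x$n_instruments))
  if (!is.na(x$intercept))
    cat(sprintf("  intercept %.4f (p = %.3g)\n", x$intercept, x$intercept_p))
  invisible(x)
}

#' Inverse-variance weighted MR estimate
#'
#' Fixed-effect IVW: `sum(bx by / sy^2) / sum(bx^2 / sy^2)` with SE
#' `sqrt(1 / sum(bx^2 / sy^2))`, inflated multiplicatively by
#' `sqrt(Q / (k - 1))` when Cochran's Q exceeds its degrees of freedom
#' (multiplicative random effects). A single instrument reduces to the
#' Wald ratio.
#'
#' @param instruments an `mr_instruments` data.frame (at least 1 row).
#' @return an `mr_estimate`.
#' @export
mr_ivw <- function(instruments) {
  k <- nrow(instruments)
  if (k < 1L) stop("need at least one instrument")
  bx <- instruments$beta_exposure
  by <- instruments$beta_outcome
  sy <- instruments$se_outcome
  if (k == 1L)
    return(.mr_estimate("IVW", by / bx, abs(sy / bx),
                        2 * pnorm(-abs(by / sy)), 1L))
  w <- 1 / sy^2
  est <- sum(w * bx * by) / sum(w * bx^2)
  se <- sqrt(1 / sum(w * bx^2))
  q <- sum(w * (by - est * bx)^2)
  phi <- q / (k - 1L)
  if (phi > 1) se <- se * sqrt(phi)
  .mr_estimate("IVW", est, se, 2 * pnorm(-abs(est / se)), k)
}

# Interpolated weighted median (weights normalised; cumulative weight
# centred at each order statistic).
.weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  cw <- cumsum(w) - w / 2
  if (cw[1] >= 0.5) return(x[1])
  if (cw[length(cw)] <= 0.5) return(x[length(x)])
  below <- max(which(cw < 0.5))
  x[below] + (x[below + 1] - x[below]) *
    (0.5 - cw[below]) / (cw[below + 1] - cw[below])
}

#' Weighted-median MR estimate
#'
#' Weighted median of per-instrument Wald ratios with inverse-variance
#' weights of the first-order delta-method ratio SEs; consistent when at
#' least half the weight comes from valid instruments. The SE is a
#' parametric bootstrap (instrument effects resampled at their stated SEs)
#' with a fixed internal seed; the caller's RNG state is untouched.
#'
#' @param instruments an `mr_instruments` data.frame (at least 3 rows).
#' @param n_boot bootstrap replicates (default 1000).
#' @param boot_seed bootstrap seed (default 42).
#' @return an `mr_estimate`.
#' @export
mr_weighted_median <- function(instruments, n_boot = 1000L, boot_seed = 42L) {
  k <- nrow(instruments)
  if (k < 3L) stop("need at least three instruments")
  bx <- instruments$beta_exposure
  by <- instruments$beta_outcome
  sx <- instruments$se_exposure
  sy <- instruments$se_outcome
  ratio <- by / bx
  se_ratio <- abs(sy / bx)
  est <- .weighted_median(ratio, 1 / se_ratio^2)
  boots <- with_local_seed(boot_seed, {
    vapply(seq_len(n_boot), function(b) {
      bxb <- rnorm(k, bx, sx)
      byb <- rnorm(k, by, sy)
      .weighted_median(byb / bxb, (bxb / sy)^2)
    }, numeric(1))
  })
  se <- sd(boots)
  .mr_estimate("weighted_median", est, se, 2 * pnorm(-abs(est / se)), k)
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of outcome effects on exposure effects
#' with an intercept, weights `1 / se_outcome^2`, after orienting exposure
#' effects positive (the standard orientation; outcome effects flip with
#' them). The slope is the causal estimate; the intercept estimates average
#' directional pleiotropy. SEs use the conventional residual-SD floor at 1
#' and a t reference with `k - 2` degrees of freedom.
#'
#' @param instruments an `mr_instruments` data.frame (at least 3 rows).
#' @return an `mr_estimate` with `intercept` and `intercept_p` filled.
#' @export
mr_egger <- function(instruments) {
  k <- nrow(instruments)
  if (k < 3L) stop("need at least three instruments")
  s <- ifelse(instruments$beta_exposure < 0, -1, 1)
  bx <- s * instruments$beta_exposure
  by <- s * instruments$beta_outcome
  sy <- instruments$se_outcome
  if (sd(bx) == 0) stop("no variation in exposure effects")
  fit <- lm(by ~ bx, weights = 1 / sy^2)
  sm <- suppressWarnings(summary(fit))  # exact fits trip summary.lm
  sigma <- sm$sigma
  adj <- max(1, sigma) / sigma
  slope <- coef(fit)[["bx"]]
  slope_se <- sm$coefficients["bx", "Std. Error"] * adj
  int <- coef(fit)[["(Intercept)"]]
  int_se <- sm$coefficients["(Intercept)", "Std. Error"] * adj
  .mr_estimate("egger", slope, slope_se,
               2 * pt(abs(slope / slope_se), k - 2, lower.tail = FALSE), k,
               intercept = int,
               intercept_p = 2 * pt(abs(int / int_se), k - 2,
                                    lower.tail = FALSE))
}

#' Bidirectional two-sample MR
#'
#' Runs the full pipeline (harmonization, F filter, optional LD clumping,
#' then IVW, weighted median and Egger) in both directions, swapping the
#' exposure and outcome roles.
#'
#' @param stats_a,stats_b summary-statistic tables for the two traits.
#' @param ref_geno optional genotype reference for proxies and clumping.
#' @param f_min instrument-strength bound (default 10).
#' @param clump apply [ld_clump] when a reference is given (default TRUE).
#' @param ... further arguments passed to [ld_clump].
#' @return data.frame: one row per direction x method with estimate, SE,
#'   CI, p, intercept columns and instrument count.
#' @export
mr_bidirectional <- function(stats_a, stats_b, ref_geno = NULL, f_min = 10,
                             clump = TRUE, ...) {
  run_dir <- function(exposure, outcome, label) {
    inst <- harmonize_instruments(exposure, outcome, ref_geno)
    inst <- strength_filter(inst, f_min)
    if (!is.null(ref_geno) && clump) inst <- ld_clump(inst, ref_geno, ...)
    ests <- list(mr_ivw(inst), mr_weighted_median(inst), mr_egger(inst))
    do.call(rbind, lapply(ests, function(e)
      data.frame(direction = label, method = e$method,
                 estimate = e$estimate, se = e$se,
                 ci_lo = e$ci95[1], ci_hi = e$ci95[2], p = e$p,
                 intercept = e$intercept, intercept_p = e$intercept_p,
                 n_instruments = e$n_instruments,
                 stringsAsFactors = FALSE)))
  }
  rbind(run_dir(stats_a, stats_b, "a_to_b"),
        run_dir(stats_b, stats_a, "b_to_a"))
}
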