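# Haseman-Elston heritability / genetic correlation and variance explained.

# Regression slope of y on x through the classic sums (with intercept).
.he_slope <- function(x, y) {
  n <- length(x)
  (sum(x * y) - sum(x) * sum(y) / n) / (sum(x^2) - sum(x)^2 / n)
}

#' Haseman-Elston heritability or genetic correlation
#'
#' Builds the genomic relationship matrix `G = Z Z' / m` from standardized
#' dosages and regresses off-diagonal phenotype cross-products on the
#' corresponding `G_ij`. The slope estimates the additive SNV heritability
#' `h2_g` of a standardized phenotype; with a second phenotype the
#' symmetrised cross-products `(y_a_i y_b_j + y_a_j y_b_i)/2` give the
#' genetic covariance, and the genetic correlation is
#' `r_g = gcov / sqrt(h2_a h2_b)`. Standard errors come from a
#' delete-one-block jackknife over subjects.
#'
#' @param geno subjects x variants dosage matrix (at least 10 variants).
#' @param pheno_a numeric phenotype vector (standardized internally).
#' @param pheno_b optional second phenotype; when given, the estimate is
#'   the genetic correlation.
#' @param n_blocks jackknife blocks (default 20).
#' @return A `heritability_estimate`: list with `estimate`, `se`, `type`
#'   (`"h2"` or `"rg"`), `method = "HE"`, and for the bivariate case the
#'   component estimates `h2_a`, `h2_b`, `gcov`.
#' @export
he_heritability <- function(geno, pheno_a, pheno_b = NULL, n_blocks = 20L) {
  geno <- as.matrix(geno)
  if (ncol(geno) < 10L) stop("need at least 10 variants")
  n <- nrow(geno)
  if (anyNA(geno)) {
    mu <- colMeans(geno, na.rm = TRUE)
    idx <- which(is.na(geno), arr.ind = TRUE)
    geno[idx] <- mu[idx[, 2L]]
  }
  sds <- apply(geno, 2L, sd)
  Z <- scale(geno[, sds > 0, drop = FALSE])
  G <- tcrossprod(Z) / ncol(Z)
  ya <- as.numeric(scale(pheno_a))
  bivariate <- !is.null(pheno_b)
  Pm <- if (bivariate) {
    yb <- as.numeric(scale(pheno_b))
    (tcrossprod(ya, yb) + tcrossprod(yb, ya)) / 2
  } else tcrossprod(ya)
  Pa <- tcrossprod(ya)
  Pb <- if (bivariate) tcrossprod(yb) else NULL

  est_fun <- function(keep) {
    ut <- upper.tri(G[keep, keep, drop = FALSE])
    g <- G[keep, keep][ut]
    if (!bivariate) return(.he_slope(g, Pa[keep, keep][ut]))
    h2a <- .he_slope(g, Pa[keep, keep][ut])
    h2b <- .he_slope(g, Pb[keep, keep][ut])
    gcov <- .he_slope(g, Pm[keep, keep][ut])
    if (h2a <= 0 || h2b <= 0) return(NA_real_)
    gcov / sqrt(h2a * h2b)
  }

  all_idx <- seq_len(n)
  full <- est_fun(all_idx)
  blocks <- split(all_idx, rep(seq_len(n_blocks), length.out = n))
  jk <- vapply(blocks, function(b) est_fun(setdiff(all_idx, b)), numeric(1))
  jk <- jk[is.finite(jk)]
  B <- length(jk)
  se <- if (B > 1) sqrt((B - 1) / B * sum((jk - mean(jk))^2)) else NA_real_

  out <- list(estimate = full, se = se,
              type = if (bivariate) "rg" else "h2", method = "HE",
              n_subjects = n, n_variants = ncol(Z))
  if (bivariate) {
    ut <- upper.tri(G)
    g <- G[ut]
    out$h2_a <- .he_slope(g, Pa[ut])
    out$h2_b <- .he_slope(g, Pb[ut])
    out$gcov <- .he_slope(g, Pm[ut])
  }
  structure(out, class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("<heritability_estimate> %s = %.4f (SE %.4f), HE regression\n",
              x$type, x$estimate, x$se))
  invisible(x)
}

#' Percent phenotype variance explained by significant variants
#'
#' Incremental R-squared: `100 * (R2 of covariates + dosages - R2 of
#' covariates alone)` from ordinary least squares fits.
#'
#' @param phenotype numeric vector.
#' @param sig_dosages matrix/data.frame of significant-variant dosages
#'   (at least one column).
#' @param covars optional covariate data.frame.
#' @return percentage.
#' @export
pct_variance_explained <- function(phenotype, sig_dosages, covars = NULL) {
  X <- as.matrix(sig_dosages)
  if (ncol(X) < 1L) stop("need at least one significant variant")
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2L]]
  }
  r2 <- function(mat) {
    fit <- lm.fit(cbind(1, mat), phenotype)
    1 - sum(fit$residuals^2) / sum((phenotype - mean(phenotype))^2)
  }
  base <- if (is.null(covars)) 0 else r2(as.matrix(as.data.frame(covars)))
  full <- r2(if (is.null(covars)) X
             else cbind(as.matrix(as.data.frame(covars)), X))
  100 * (full - base)
}
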