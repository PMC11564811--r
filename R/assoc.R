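# Observational analyses: correlations, stepwise covariates, odds ratios.

#' Two-sided Pearson correlation
#'
#' Sample correlation with the two-sided p-value from the t transform with
#' `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (at least 3), each with
#'   nonzero variance.
#' @return list with `r` and `p`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input")
  ct <- cor.test(x, y, alternative = "two.sided", method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

# Drop candidate columns that exactly duplicate an earlier one (ties broken
# by input order), so stepwise selection stays deterministic under forced
# collinearity.
.drop_duplicate_columns <- function(df) {
  keep <- !duplicated(lapply(df, function(col) as.numeric(col)))
  df[, keep, drop = FALSE]
}

#' Stepwise covariate selection for a binary outcome
#'
#' Bidirectional stepwise logistic selection by AIC starting from the full
#' model, deterministic given the candidate order. Exactly duplicated
#' candidates are reduced to their first occurrence before selection;
#' candidates whose inclusion breaks the fit (separation, non-convergence)
#' are dropped with a warning.
#'
#' @param outcome 0/1 vector.
#' @param candidates data.frame of candidate covariate columns.
#' @return character vector of selected candidate names.
#' @export
stepwise_covariates <- function(outcome, candidates) {
  candidates <- as.data.frame(candidates)
  if (ncol(candidates) < 1L) stop("need at least one candidate")
  candidates <- .drop_duplicate_columns(candidates)
  dat <- cbind(.y = outcome, candidates)
  repeat {
    fit <- withCallingHandlers(
      tryCatch(glm(.y ~ ., data = dat, family = binomial()),
               error = function(e) e),
      warning = function(w) invokeRestart("muffleWarning"))
    bad <- NULL
    if (inherits(fit, "error")) {
      bad <- names(candidates)[ncol(candidates)]
    } else if (!fit$converged || any(is.na(coef(fit)))) {
      nac <- names(coef(fit))[is.na(coef(fit))]
      bad <- if (length(nac)) intersect(names(candidates), nac)
             else names(candidates)[ncol(candidates)]
    }
    if (is.null(bad) || length(bad) == 0L) break
    warning(sprintf("dropping candidate(s) %s: unstable logistic fit",
                    paste(bad, collapse = ", ")))
    candidates <- candidates[, setdiff(names(candidates), bad), drop = FALSE]
    if (ncol(candidates) == 0L) return(character(0))
    dat <- cbind(.y = outcome, candidates)
  }
  sel <- suppressWarnings(
    step(fit, scope = list(lower = .y ~ 1), direction = "both", trace = 0))
  setdiff(all.vars(stats::formula(sel))[-1L], ".y")
}

#' Logistic odds ratio per SD of a score
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via [stats::glm], convergence tolerance 1e-8) of a binary outcome
#' on the internally standardized score plus covariates. Reports the odds
#' ratio per SD with a Wald 95% confidence interval on the log-odds scale.
#'
#' @param score numeric vector (standardized internally; OR is per SD).
#' @param outcome 0/1 vector with at least 10 cases.
#' @param covars optional data.frame of adjustment covariates.
#' @param score_name label used in the output.
#' @param outcome_name label used in the output.
#' @return one-row data.frame: `score`, `outcome`, `odds_ratio`, `ci_lo`,
#'   `ci_hi`, `p_value`, `n_cases`, `covariates_used`.
#' @export
logistic_odds_ratio <- function(score, outcome, covars = NULL,
                                score_name = "score",
                                outcome_name = "outcome") {
  if (sum(outcome == 1) < 10L) stop("need at least 10 cases")
  s <- as.numeric(scale(score))
  dat <- data.frame(.y = outcome, .s = s)
  if (!is.null(covars)) dat <- cbind(dat, as.data.frame(covars))
  fit <- glm(.y ~ ., data = dat, family = binomial(),
             control = list(epsilon = 1e-8, maxit = 50))
  probs <- fitted(fit)
  if (any(probs > 1 - 1e-10) || any(probs < 1e-10)) {
    cf <- coef(fit)[-1L]
    worst <- names(cf)[which.max(abs(cf))]
    stop(sprintf("perfect separation detected (offending column: %s)",
                 worst))
  }
  b <- coef(fit)[".s"]
  se <- sqrt(diag(vcov(fit))[".s"])
  zst <- b / se
  data.frame(score = score_name, outcome = outcome_name,
             odds_ratio = exp(b),
             ci_lo = exp(b - 1.96 * se), ci_hi = exp(b + 1.96 * se),
             p_value = 2 * pnorm(-abs(zst)),
             n_cases = sum(outcome == 1),
             covariates_used = paste(setdiff(names(dat), c(".y", ".s")),
                                     collapse = ","),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise alpha.
#' @param n_tests number of tests (at least 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (n_tests < 1) stop("`n_tests` must be at least 1")
  alpha / n_tests
}
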