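# Synthetic covariates and binary cardiometabolic outcomes.

# Standardized-covariate log-odds contributions used by the outcome model;
# modest, fixed, documented here rather than configurable.
.covariate_log_odds <- c(age = 0.20, sex = 0.25, bmi = 0.15, sbp = 0.10,
                         heart_rate = 0.05, height = 0)

#' Simulate covariates and binary outcomes for a shape cohort
#'
#' Covariates mimic a middle-aged imaging cohort: age ~ N(62, 7.5^2) years,
#' sex ~ Bernoulli(0.48) (1 = male), sex-specific height (men N(176, 7^2),
#' women N(163, 6^2) cm), BMI ~ N(26.5, 4^2) kg/m^2, systolic blood pressure
#' N(137, 17^2) mmHg plus 15 mmHg in the 20% flagged as taking
#' blood-pressure medication (the reported `sbp` column already carries the
#' adjustment; `bp_medication` records the flag), and heart rate
#' N(61, 9^2) bpm.
#'
#' Each binary outcome is drawn from a logistic model whose linear predictor
#' sums the configured per-SD log odds ratios on the standardized latent
#' shape scores plus small fixed standardized-covariate terms; the intercept
#' is solved numerically so the expected prevalence matches the configured
#' target.
#'
#' @param cfg a [sim_config] (uses `outcome_log_odds`,
#'   `outcome_prevalence`, `seed`).
#' @param truth `truth_record` from [sample_shape_population].
#' @return A data.frame (one row per subject): `subject_id`, covariate
#'   columns, `bp_medication`, and one 0/1 column per configured outcome.
#'   Attribute `intercepts` stores the solved outcome intercepts.
#' @export
sample_covariates_outcomes <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "truth_record"))
  set.seed(cfg$seed + 303L)
  z <- truth$true_latent_scores
  n <- nrow(z)

  sex <- rbinom(n, 1, 0.48)
  age <- rnorm(n, 62, 7.5)
  height <- ifelse(sex == 1, rnorm(n, 176, 7), rnorm(n, 163, 6))
  bmi <- rnorm(n, 26.5, 4)
  bp_med <- rbinom(n, 1, 0.2)
  sbp <- rnorm(n, 137, 17) + 15 * bp_med
  hr <- rnorm(n, 61, 9)

  out <- data.frame(subject_id = truth$subject_ids, age = age, sex = sex,
                    height = height, bmi = bmi, sbp = sbp, heart_rate = hr,
                    bp_medication = bp_med, stringsAsFactors = FALSE)

  if (!is.null(cfg$outcome_log_odds)) {
    covs <- scale(cbind(age = age, sex = sex, bmi = bmi, sbp = sbp,
                        heart_rate = hr, height = height))
    eta_cov <- as.numeric(covs %*% .covariate_log_odds[colnames(covs)])
    zs <- scale(z)
    intercepts <- numeric(0)
    for (nm in names(cfg$outcome_log_odds)) {
      target <- cfg$outcome_prevalence[[nm]]
      if (!is.finite(target) || target <= 0 || target >= 1)
        stop(sprintf("unattainable target prevalence for outcome '%s'", nm))
      eta <- eta_cov + as.numeric(zs %*% cfg$outcome_log_odds[[nm]])
      b0 <- uniroot(function(b) mean(plogis(b + eta)) - target,
                    c(-30, 30), tol = 1e-10)$root
      prev <- mean(plogis(b0 + eta))
      if (abs(prev - target) / target > 0.2)
        stop(sprintf("unattainable target prevalence for outcome '%s'", nm))
      out[[nm]] <- rbinom(n, 1, plogis(b0 + eta))
      intercepts[nm] <- b0
    }
    attr(out, "intercepts") <- intercepts
  }
  out
}
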