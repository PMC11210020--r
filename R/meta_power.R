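# Random-effects meta-analysis across outcome cohorts, instrument-strength
# diagnostics, and normal-approximation power calculations.

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Pools cohort-level estimates (e.g. the IVW estimate per liver-steatosis
#' cohort) with between-cohort variance tau^2 from the DerSimonian-Laird
#' moment estimator: fixed weights `w_i = 1/se_i^2`, `Q = sum w_i (b_i -
#' b_FE)^2`, `tau2 = max(0, (Q - (m-1)) / (sum w - sum w^2 / sum w))`, then
#' inverse-variance pooling with weights `1/(se_i^2 + tau2)`. A single
#' cohort passes through unchanged.
#'
#' @param beta cohort effect estimates.
#' @param se cohort standard errors.
#' @param labels cohort labels (default `cohort1..m`).
#' @return A `meta_estimate`: pooled `beta`, `se`, `ci_low`, `ci_high`,
#'   `pval`, `tau2`, `q_meta`, `i2_meta` (%), and the input `cohorts` table.
#' @export
meta_random <- function(beta, se, labels = NULL) {
  stopifnot(length(beta) == length(se), all(se > 0))
  m <- length(beta)
  labels <- labels %||% paste0("cohort", seq_len(m))
  cohorts <- data.frame(label = labels, beta = beta, se = se,
                        stringsAsFactors = FALSE)
  if (m == 1L) {
    message("meta_random: single cohort, passing estimate through")
    return(structure(list(beta = beta, se = se,
                          ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
                          pval = pval_wald(beta, se), tau2 = 0, q_meta = 0,
                          i2_meta = 0, cohorts = cohorts),
                     class = "meta_estimate"))
  }
  w <- 1 / se^2
  b_fe <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - b_fe)^2)
  tau2 <- max(0, (q - (m - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (se^2 + tau2)
  pooled <- sum(wr * beta) / sum(wr)
  se_pooled <- 1 / sqrt(sum(wr))
  i2 <- if (q > 0) max(0, (q - (m - 1)) / q) * 100 else 0
  structure(list(beta = pooled, se = se_pooled,
                 ci_low = pooled - Z95 * se_pooled,
                 ci_high = pooled + Z95 * se_pooled,
                 pval = pval_wald(pooled, se_pooled),
                 tau2 = tau2, q_meta = q, i2_meta = i2, cohorts = cohorts),
            class = "meta_estimate")
}

#' @export
print.meta_estimate <- function(x, ...) {
  cat(sprintf("<meta_estimate> pooled beta=%.6g se=%.6g 95%%CI [%.6g, %.6g] p=%.3g\n",
              x$beta, x$se, x$ci_low, x$ci_high, x$pval))
  cat(sprintf("  %d cohorts, tau2=%.4g I2=%.1f%%\n", nrow(x$cohorts), x$tau2,
              x$i2_meta))
  invisible(x)
}

#' Instrument strength: variance explained and approximate F-statistic
#'
#' For a standardized (SD-unit) trait each variant explains
#' `r2_j = 2 eaf_j (1-eaf_j) beta_j^2`; when EAF is missing the
#' sample-size-based fallback `beta^2 / (beta^2 + n se^2)` is used (and
#' flagged). The overall F-statistic is
#' `R2 (n - k - 1) / ((1 - R2) k)`; F > 10 is the conventional bar for
#' "weak-instrument bias unlikely".
#'
#' @param table a `gwas_table` of selected instruments, with `eaf` and `n`.
#' @param n GWAS sample size; defaults to the largest `n` in the table.
#' @return An `instrument_strength`: `r2_total`, `f_stat`, `n`, `k`,
#'   `per_snp_r2`, `used_fallback`, `weak_instrument_unlikely`.
#' @export
instrument_strength <- function(table, n = NULL) {
  stopifnot(inherits(table, "gwas_table"))
  d <- table$data
  k <- nrow(d)
  n <- n %||% suppressWarnings(max(d$n, na.rm = TRUE))
  if (!is.finite(n) || n <= k + 1)
    stopf("need a sample size n > k + 1 to compute the F-statistic")
  have_eaf <- !is.na(d$eaf)
  r2 <- numeric(k)
  r2[have_eaf] <- 2 * d$eaf[have_eaf] * (1 - d$eaf[have_eaf]) * d$beta[have_eaf]^2
  if (any(!have_eaf)) {
    message(sprintf("instrument_strength: %d variant(s) missing EAF; using beta^2/(beta^2 + n se^2) fallback",
                    sum(!have_eaf)))
    i <- !have_eaf
    r2[i] <- d$beta[i]^2 / (d$beta[i]^2 + n * d$se[i]^2)
  }
  r2_total <- sum(r2)
  if (r2_total >= 1) stopf("total R^2 >= 1; check trait standardization")
  f <- r2_total * (n - k - 1) / ((1 - r2_total) * k)
  structure(list(r2_total = r2_total, f_stat = f, n = n, k = k,
                 per_snp_r2 = r2, used_fallback = any(!have_eaf),
                 weak_instrument_unlikely = f > 10),
            class = "instrument_strength")
}

#' @export
print.instrument_strength <- function(x, ...) {
  cat(sprintf("<instrument_strength> k=%d n=%d R2=%.3g%% F=%.1f (%s)\n",
              x$k, x$n, 100 * x$r2_total, x$f_stat,
              if (x$weak_instrument_unlikely) "weak-instrument bias unlikely, F > 10"
              else "weak instruments possible, F <= 10"))
  invisible(x)
}

#' Statistical power of a two-sample MR analysis
#'
#' Normal approximation to the power of the two-sided Wald test at level
#' `alpha`: for a continuous outcome the non-centrality is
#' `|b| sqrt(n r2)`; for a binary outcome (log-odds effects)
#' `|log OR| sqrt(n r2 cf (1-cf))` with case fraction `cf`. Power is
#' `Phi(ncp - z_{1-alpha/2})` (the negligible far-tail rejection mass is
#' dropped, so a zero effect returns `alpha/2`).
#'
#' @param n outcome GWAS sample size.
#' @param r2 variance of the exposure explained by the instruments.
#' @param effect effect size to detect: beta (continuous) or log odds ratio
#'   (binary).
#' @param case_fraction case fraction for a binary outcome.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param alpha two-sided significance level (default 0.05).
#' @return power in `[0, 1]`.
#' @export
mr_power <- function(n, r2, effect, case_fraction = NULL,
                     outcome_type = c("continuous", "binary"), alpha = 0.05) {
  outcome_type <- match.arg(outcome_type)
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0,1)")
  if (r2 <= 0 || r2 >= 1) stopf("r2 must be in (0,1)")
  if (n <= 0) stopf("n must be positive")
  ncp <- if (outcome_type == "binary") {
    if (is.null(case_fraction) || case_fraction <= 0 || case_fraction >= 1)
      stopf("binary outcome requires case_fraction in (0,1)")
    abs(effect) * sqrt(n * r2 * case_fraction * (1 - case_fraction))
  } else abs(effect) * sqrt(n * r2)
  stats::pnorm(ncp - stats::qnorm(1 - alpha / 2))
}

#' Smallest detectable effect at a target power
#'
#' Inverse of [mr_power()]: the effect (beta, or log OR for a binary
#' outcome) detectable with probability `target_power` at level `alpha`.
#'
#' @inheritParams mr_power
#' @param target_power desired power (default 0.80).
#' @return the detectable effect size (log OR for binary outcomes; exponentiate
#'   for the odds-ratio scale).
#' @export
mr_detectable_effect <- function(n, r2, case_fraction = NULL,
                                 outcome_type = c("continuous", "binary"),
                                 alpha = 0.05, target_power = 0.80) {
  outcome_type <- match.arg(outcome_type)
  if (target_power <= 0 || target_power >= 1) stopf("target_power must be in (0,1)")
  denom <- if (outcome_type == "binary") {
    if (is.null(case_fraction) || case_fraction <= 0 || case_fraction >= 1)
      stopf("binary outcome requires case_fraction in (0,1)")
    sqrt(n * r2 * case_fraction * (1 - case_fraction))
  } else sqrt(n * r2)
  (stats::qnorm(1 - alpha / 2) + stats::qnorm(target_power)) / denom
}
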