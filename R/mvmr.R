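# Multivariable MR, the two-step mediation decomposition, and the
# per-doubling scale conversion for liability exposures.

#' Multivariable MR (conditional causal effects)
#'
#' Weighted through-origin multiple regression of the outcome betas on K
#' exposure-beta columns with weights 1/sey^2: each coefficient is the
#' effect of that exposure conditional on the others, which is how a
#' mediator is adjusted for in the mediation decomposition. Standard errors
#' come from the weighted normal-equations covariance with the
#' multiplicative random-effects inflation `max(1, sqrt(Q/(L-K)))`.
#'
#' @param set a `harmonized_set` whose `bx`/`sex` are L x K matrices
#'   (from `harmonize(list(exposure, mediator), outcome)`). K = 1 reduces
#'   exactly to [ivw_mre()].
#' @return An `mvmr_result`: `$estimates` (list of `mr_estimate`, one per
#'   exposure, named), `$n_snps`, `$q_stat`, `$i2` for the joint fit.
#' @export
mvmr <- function(set) {
  stopifnot(inherits(set, "harmonized_set"))
  X <- bx_matrix(set)
  K <- ncol(X); L <- nrow(X)
  if (L < K + 1L) stopf("MVMR needs at least K+1 = %d instruments, got %d", K + 1L, L)
  w <- 1 / set$sey^2
  qrX <- qr(sqrt(w) * X)
  if (qrX$rank < K) {
    bad <- set$exposure_names[-qrX$pivot[seq_len(qrX$rank)]]
    stopf("exposure beta matrix is rank deficient (collinear: %s)",
          paste(bad, collapse = ", "))
  }
  xtwx <- crossprod(X, w * X)
  coef <- drop(solve(xtwx, crossprod(X, w * set$by)))
  q <- sum(w * (set$by - drop(X %*% coef))^2)
  df <- L - K
  scale <- max(1, sqrt(q / df))
  ses <- sqrt(diag(solve(xtwx))) * scale
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  ests <- lapply(seq_len(K), function(k)
    new_mr_estimate(if (K == 1L) "ivw_mre" else "mvmr", coef[[k]], ses[[k]], L, q, i2))
  names(ests) <- set$exposure_names
  structure(list(estimates = ests, n_snps = L, q_stat = q, i2 = i2),
            class = "mvmr_result")
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("<mvmr_result> %d exposures, %d SNPs, Q=%.4g I2=%.1f%%\n",
              length(x$estimates), x$n_snps, x$q_stat, x$i2))
  for (nm in names(x$estimates)) {
    e <- x$estimates[[nm]]
    cat(sprintf("  %-20s beta=%.6g se=%.6g p=%.3g\n", nm, e$beta, e$se, e$pval))
  }
  invisible(x)
}

#' Mediation decomposition by the product of coefficients
#'
#' Two-step MR mediation: the indirect effect of the exposure on the outcome
#' through the mediator is `a * b`, where `a` is the exposure-to-mediator
#' effect (step 1, univariable MR) and `b` the mediator-to-outcome effect
#' adjusted for the exposure (step 2, from MVMR). Its standard error is the
#' first-order delta-method form `sqrt(a^2 se_b^2 + b^2 se_a^2)` (the two
#' samples are treated as independent; supply `cov_ab` to add a covariance
#' term, or `second_order = TRUE` for the exact-product extra term
#' `se_a^2 se_b^2`). The proportion mediated is `indirect / total` with
#' delta-method variance combining both uncertainties; `log_scale = TRUE`
#' instead builds the CI on log(indirect/total) (requires a positive ratio).
#'
#' @param step1 `mr_estimate` of exposure -> mediator.
#' @param step2 `mr_estimate` of mediator -> outcome (exposure-adjusted).
#' @param total `mr_estimate` of exposure -> outcome (univariable).
#' @param direct optional `mr_estimate` of exposure -> outcome adjusted for
#'   the mediator, carried through for reporting.
#' @param cov_ab covariance between the step-1 and step-2 estimates
#'   (default 0: non-overlapping samples).
#' @param second_order add the second-order product-variance term.
#' @param log_scale build the proportion CI on the log scale.
#' @return A `mediation_result` with `total`, `direct`, `step1`, `step2`,
#'   `indirect` (beta, se, ci, pval) and `proportion_mediated` (value, ci).
#' @export
mediate <- function(step1, step2, total, direct = NULL, cov_ab = 0,
                    second_order = FALSE, log_scale = FALSE) {
  stopifnot(inherits(step1, "mr_estimate"), inherits(step2, "mr_estimate"),
            inherits(total, "mr_estimate"))
  if (total$beta == 0) stopf("total effect is zero: proportion mediated undefined")
  a <- step1$beta; sa <- step1$se
  b <- step2$beta; sb <- step2$se
  ind <- a * b
  var_ind <- a^2 * sb^2 + b^2 * sa^2 + 2 * a * b * cov_ab
  if (second_order) var_ind <- var_ind + sa^2 * sb^2
  se_ind <- sqrt(var_ind)
  prop <- ind / total$beta
  se_prop <- sqrt((se_ind / total$beta)^2 + (ind * total$se / total$beta^2)^2)
  if (log_scale) {
    if (prop <= 0) stopf("log-scale proportion CI requires a positive proportion")
    se_log <- se_prop / prop
    ci <- prop * exp(c(-1, 1) * Z95 * se_log)
  } else {
    ci <- prop + c(-1, 1) * Z95 * se_prop
  }
  structure(list(
    total = total, direct = direct, step1 = step1, step2 = step2,
    indirect = list(beta = ind, se = se_ind,
                    ci_low = ind - Z95 * se_ind, ci_high = ind + Z95 * se_ind,
                    pval = pval_wald(ind, se_ind)),
    proportion_mediated = list(value = prop, se = se_prop,
                               ci_low = ci[[1L]], ci_high = ci[[2L]])),
    class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> total=%.4g  indirect=%.4g (se %.4g)\n",
              x$total$beta, x$indirect$beta, x$indirect$se))
  p <- x$proportion_mediated
  cat(sprintf("  proportion mediated: %.1f%% (95%% CI %.1f%%, %.1f%%)\n",
              100 * p$value, 100 * p$ci_low, 100 * p$ci_high))
  invisible(x)
}

#' Rescale a liability-scale effect to per doubling of prevalence
#'
#' Effects of genetic liability to a binary exposure (per log-odds of
#' liability) are multiplied by ln 2 = 0.693 so they read as "per doubling
#' in the prevalence" of the exposure; the SE and CI transform with it.
#'
#' @param beta an effect estimate, or an `mr_estimate` (then `se` is ignored
#'   and a rescaled `mr_estimate` is returned).
#' @param se standard error accompanying a numeric `beta`.
#' @return `c(beta, se) * log(2)`, or the rescaled `mr_estimate`.
#' @export
per_doubling <- function(beta, se = NULL) {
  ln2 <- log(2)
  if (inherits(beta, "mr_estimate")) {
    out <- new_mr_estimate(beta$method, beta$beta * ln2, beta$se * ln2,
                           beta$n_snps, beta$q_stat, beta$i2)
    return(out)
  }
  if (is.null(se)) beta * ln2 else c(beta = beta * ln2, se = se * ln2)
}
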