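# Univariable two-sample MR estimators and heterogeneity diagnostics.

new_mr_estimate <- function(method, beta, se, n_snps, q_stat = NA_real_,
                            i2 = NA_real_) {
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
                 pval = pval_wald(beta, se), n_snps = n_snps,
                 q_stat = q_stat, i2 = i2), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate:%s> beta=%.6g se=%.6g 95%%CI [%.6g, %.6g] p=%.3g n_snps=%d",
              x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pval, x$n_snps))
  if (is.finite(x$q_stat)) cat(sprintf(" Q=%.4g I2=%.1f%%", x$q_stat, x$i2))
  cat("\n")
  invisible(x)
}

#' Wald ratio for a single instrument
#'
#' Per-variant causal estimate: outcome beta divided by exposure beta, with
#' the first-order standard error sey/|bx| (the uncertainty in the exposure
#' association is ignored; set `second_order = TRUE` to add it).
#'
#' @param bx,sex exposure beta and SE for one variant.
#' @param by,sey outcome beta and SE for the same variant, same effect allele.
#' @param second_order include the second-order term
#'   `sqrt(sey^2/bx^2 + by^2*sex^2/bx^4)` instead of the first-order SE.
#' @return An `mr_estimate` with `n_snps = 1`; heterogeneity fields are NA.
#' @export
wald_ratio <- function(bx, by, sey, sex = NA_real_, second_order = FALSE) {
  if (bx == 0) stopf("degenerate instrument: exposure beta is zero")
  beta <- by / bx
  se <- if (second_order) sqrt(sey^2 / bx^2 + by^2 * sex^2 / bx^4) else sey / abs(bx)
  new_mr_estimate("wald", beta, se, 1L)
}

#' Inverse-variance-weighted estimate with multiplicative random effects
#'
#' The main MR estimator: a weighted through-origin regression of outcome on
#' exposure betas with weights 1/sey^2. The fixed-effect SE is inflated by
#' the residual overdispersion factor `max(1, sqrt(Q/(L-1)))`
#' (multiplicative random effects; underdispersion never shrinks the SE).
#' With one instrument this falls back to the Wald ratio.
#'
#' @param set a `harmonized_set` with a single exposure.
#' @return An `mr_estimate` with Cochran's Q and I^2 populated.
#' @export
ivw_mre <- function(set) {
  stopifnot(inherits(set, "harmonized_set"))
  bx <- set$bx; by <- set$by; sey <- set$sey
  if (is.matrix(bx)) stopf("ivw_mre expects a single exposure; use mvmr()")
  L <- length(bx)
  if (L == 1L) {
    message("ivw_mre: single instrument, falling back to Wald ratio")
    return(wald_ratio(bx, by, sey))
  }
  w <- 1 / sey^2
  sxx <- sum(w * bx^2)
  if (sxx == 0) stopf("degenerate set: all exposure betas are zero")
  beta <- sum(w * bx * by) / sxx
  se0 <- 1 / sqrt(sxx)
  q <- sum(w * (by - beta * bx)^2)
  scale <- max(1, sqrt(q / (L - 1)))
  i2 <- if (q > 0) max(0, (q - (L - 1)) / q) * 100 else 0
  new_mr_estimate("ivw_mre", beta, se0 * scale, L, q, i2)
}

#' Cochran's Q and I-squared for a fitted causal effect
#'
#' @param set a `harmonized_set` (single exposure).
#' @param beta the fitted causal effect to compute residual heterogeneity
#'   around.
#' @return list with `q`, `df = L - 1`, and `i2` (percentage in `[0, 100]`).
#' @export
cochran_q <- function(set, beta) {
  stopifnot(inherits(set, "harmonized_set"))
  L <- n_snps(set)
  if (L < 2L) stopf("heterogeneity requires at least 2 instruments")
  q <- sum((set$by - beta * set$bx)^2 / set$sey^2)
  list(q = q, df = L - 1L, i2 = if (q > 0) max(0, (q - (L - 1L)) / q) * 100 else 0)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome on exposure betas *with* an
#' intercept, weights 1/sey^2, after orienting every instrument to a
#' non-negative exposure beta. The intercept estimates the average
#' directional pleiotropic effect (its p-value is the standard test for
#' overall horizontal pleiotropy); the slope is the causal estimate under
#' the InSIDE assumption. Both SEs carry the multiplicative
#' random-effects inflation `max(1, sqrt(Q/(L-2)))`. The I^2_GX statistic
#' (weighted heterogeneity of the exposure betas relative to their
#' measurement error) quantifies regression-dilution ("NOME") bias of the
#' slope; values near 1 indicate negligible dilution.
#'
#' @param set a `harmonized_set` with a single exposure.
#' @return An `egger_result`: `$slope` (`mr_estimate`), `$intercept`
#'   (value, se, pval), `$i2_gx` in `[0, 1]`.
#' @export
egger <- function(set) {
  stopifnot(inherits(set, "harmonized_set"))
  bx <- set$bx; by <- set$by; sey <- set$sey; sex <- set$sex
  if (is.matrix(bx)) stopf("egger expects a single exposure")
  L <- length(bx)
  if (L < 3L) stopf("MR-Egger requires at least 3 instruments")
  flip <- bx < 0
  bx[flip] <- -bx[flip]; by[flip] <- -by[flip]
  w <- 1 / sey^2
  X <- cbind(1, bx)
  xtwx <- crossprod(X, w * X)
  if (abs(det(xtwx)) < .Machine$double.eps * sum(w)^2 ||
      isTRUE(all.equal(stats::var(bx), 0)))
    stopf("insufficient variation in exposure betas: Egger design is collinear")
  coef <- solve(xtwx, crossprod(X, w * by))
  resid <- by - X %*% coef
  q <- sum(w * resid^2)
  scale <- max(1, sqrt(q / (L - 2)))
  covm <- solve(xtwx) * scale^2
  ses <- sqrt(diag(covm))
  slope <- new_mr_estimate("egger_slope", coef[[2L]], ses[[2L]], L, q,
                           if (q > 0) max(0, (q - (L - 2)) / q) * 100 else 0)
  wx <- 1 / sex^2
  bbar <- sum(wx * bx) / sum(wx)
  qgx <- sum(wx * (bx - bbar)^2)
  i2_gx <- if (qgx > 0) max(0, (qgx - (L - 1)) / qgx) else 0
  structure(list(
    slope = slope,
    intercept = list(value = coef[[1L]], se = ses[[1L]],
                     pval = pval_wald(coef[[1L]], ses[[1L]])),
    i2_gx = i2_gx), class = "egger_result")
}

#' @export
print.egger_result <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  intercept=%.6g se=%.6g p=%.3g  I2_GX=%.3f\n",
              x$intercept$value, x$intercept$se, x$intercept$pval, x$i2_gx))
  invisible(x)
}

# Point estimator: interpolated weighted median of per-SNP ratios.
weighted_median_point <- function(bx, by, sey) {
  r <- by / bx
  w <- bx^2 / sey^2
  o <- order(r)
  r <- r[o]; w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  stats::approx(s, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted-median estimator
#'
#' Consistent when instruments carrying at least half the total weight are
#' valid. Per-SNP Wald ratios are weighted by bx^2/sey^2 (inverse variance
#' of the ratio, first order); the estimate interpolates the ratio whose
#' cumulative standardized weight crosses one half. The SE is the standard
#' deviation of the estimator over `n_boot` parametric-bootstrap replicates
#' (per-SNP betas resampled from their sampling normals).
#'
#' @param set a `harmonized_set` with a single exposure, L >= 3.
#' @param n_boot bootstrap replicates for the SE (default 1000); `0` skips
#'   the bootstrap and returns an estimate with `NA` uncertainty.
#' @param seed RNG seed for the bootstrap (restores the caller's RNG state).
#' @return An `mr_estimate`.
#' @export
weighted_median <- function(set, n_boot = 1000L, seed = NULL) {
  stopifnot(inherits(set, "harmonized_set"))
  bx <- set$bx; by <- set$by; sey <- set$sey; sex <- set$sex
  if (is.matrix(bx)) stopf("weighted_median expects a single exposure")
  L <- length(bx)
  if (L < 3L) stopf("weighted median requires at least 3 instruments")
  est <- weighted_median_point(bx, by, sey)
  if (n_boot == 0L) return(new_mr_estimate("weighted_median", est, NA_real_, L))
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      weighted_median_point(stats::rnorm(L, bx, sex), stats::rnorm(L, by, sey), sey)
    }, numeric(1L))
  })
  new_mr_estimate("weighted_median", est, stats::sd(boot), L)
}

#' Per-class subset estimates
#'
#' Runs the IVW estimator within each instrument class (e.g. HbA1c variants
#' split into glycemic vs erythrocytic clusters); classes with a single
#' variant fall back to the Wald ratio.
#'
#' @param set a `harmonized_set` with a single exposure.
#' @param classes character vector of per-SNP labels, same length and order
#'   as `set$variant_id` ("unknown" is an ordinary label).
#' @return Named list of `mr_estimate`, one per label; single-SNP entries
#'   carry method `"wald"`.
#' @export
subset_estimates <- function(set, classes) {
  stopifnot(inherits(set, "harmonized_set"),
            length(classes) == n_snps(set))
  out <- list()
  for (lab in unique(classes)) {
    idx <- which(classes == lab)
    sub <- subset_set(set, idx)
    out[[lab]] <- if (length(idx) >= 2L) ivw_mre(sub)
      else wald_ratio(sub$bx, sub$by, sub$sey)
  }
  out
}

# Row-subset of a harmonized set.
subset_set <- function(set, idx) {
  s <- set
  for (f in c("variant_id", "ea", "oa", "eaf", "by", "sey")) s[[f]] <- s[[f]][idx]
  if (is.matrix(set$bx)) {
    s$bx <- set$bx[idx, , drop = FALSE]; s$sex <- set$sex[idx, , drop = FALSE]
  } else {
    s$bx <- set$bx[idx]; s$sex <- set$sex[idx]
  }
  s
}

# Build a harmonized_set directly from aligned vectors (internal and for
# power users / simulations); bx may be a matrix for multiple exposures.
#' Assemble a harmonized set from aligned vectors
#'
#' Low-level constructor for callers that already hold allele-aligned
#' per-variant effects (e.g. simulation output or published instrument
#' tables): no allele processing is performed.
#'
#' @param bx,sex exposure beta(s) and SE(s); matrices (L x K) for K exposures.
#' @param by,sey outcome beta and SE vectors.
#' @param variant_id optional IDs (generated if omitted).
#' @param eaf optional effect-allele frequencies.
#' @param exposure_names,outcome_name trait labels.
#' @return A `harmonized_set`.
#' @export
harmonized_set <- function(bx, sex, by, sey, variant_id = NULL, eaf = NULL,
                           exposure_names = NULL, outcome_name = "outcome") {
  L <- length(by)
  bxm <- if (is.matrix(bx)) bx else matrix(bx, ncol = 1L)
  sexm <- if (is.matrix(sex)) sex else matrix(sex, ncol = 1L)
  stopifnot(nrow(bxm) == L, length(sey) == L, all(dim(bxm) == dim(sexm)))
  K <- ncol(bxm)
  variant_id <- variant_id %||% sprintf("snp%05d", seq_len(L))
  exposure_names <- exposure_names %||%
    if (K == 1L) "exposure" else paste0("exposure_", seq_len(K))
  structure(list(
    exposure_names = exposure_names, exposure_units = rep("SD", K),
    outcome_name = outcome_name, outcome_unit = "SD",
    variant_id = variant_id, ea = rep("A", L), oa = rep("G", L),
    eaf = eaf %||% rep(NA_real_, L),
    bx = if (K == 1L) drop(bxm) else bxm,
    sex = if (K == 1L) drop(sexm) else sexm,
    by = by, sey = sey,
    exclusions = data.frame(variant_id = character(), reason = character(),
                            stringsAsFactors = FALSE)), class = "harmonized_set")
}
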