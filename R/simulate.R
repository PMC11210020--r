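# Synthetic GWAS summary statistics under a known structural model:
# exposure -> mediator -> outcome (log-odds), with optional horizontal
# pleiotropy and seeded outliers, so every pipeline stage has ground truth.

#' Simulation configuration
#'
#' Describes the generative model for synthetic summary statistics. Per-SNP
#' true exposure effects are gamma_j ~ N(0, gamma_sd); the mediator receives
#' kappa_j = a * gamma_j + delta_j (delta_j mediator-specific for a fraction
#' of variants, so the exposure and mediator effect columns are not
#' collinear in MVMR); the outcome, on the log-odds scale, receives
#' Gamma_j = theta_direct * gamma_j + b * kappa_j + alpha_j with alpha_j the
#' horizontal-pleiotropy offset. Observed betas add sampling noise with
#' per-variant standard error `1/sqrt(2 eaf (1-eaf) n_trait)`.
#'
#' Defaults mirror the fasting-insulin -> ferritin -> liver-steatosis chain
#' at published-GWAS scale: L = 150 instruments, exposure / mediator /
#' outcome sample sizes of 158,550 / 246,139 / 885,701, direct effect
#' 1.113, a = 0.375, b = 0.223, so the true total effect is 1.197 and the
#' true proportion mediated a*b / (theta_direct + a*b) ~ 7%.
#'
#' @param L instrument count (>= 4).
#' @param n_exp,n_med,n_out GWAS sample sizes (n_out may be a vector, one
#'   per outcome cohort; recycled over `n_cohorts`).
#' @param eaf_range allele-frequency sampling interval.
#' @param gamma_sd SD of true per-SNP exposure effects.
#' @param theta_direct direct exposure -> outcome effect (log-odds per unit).
#' @param a exposure -> mediator effect.
#' @param b mediator -> outcome effect (log-odds per mediator unit).
#' @param med_specific_fraction fraction of variants with an extra
#'   mediator-specific effect delta_j.
#' @param med_delta_sd SD of delta_j.
#' @param pleiotropy list: `mode` one of "none", "balanced", "directional",
#'   "inside_violation"; `mean`, `sd`, `fraction_affected`.
#' @param outliers list: `count`, `offset_multiplier` (applied post hoc by
#'   [inject_outliers()] when count > 0).
#' @param n_cohorts number of independent outcome cohorts.
#' @param palindromic_fraction fraction of variants assigned A/T or C/G
#'   allele pairs.
#' @param all_significant re-draw tiny gamma_j so every instrument passes
#'   genome-wide significance in the exposure GWAS (default TRUE; the
#'   margin keeps observed p-values below 5e-8 with high probability).
#' @param observation_noise set `FALSE` to emit the true effects without
#'   sampling noise (standard errors are still reported), so estimator
#'   identities can be checked exactly.
#' @param seed RNG seed; the whole simulation is reproducible from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(L = 150L, n_exp = 158550, n_med = 246139,
                       n_out = 885701, eaf_range = c(0.05, 0.95),
                       gamma_sd = 0.03, theta_direct = 1.113, a = 0.375,
                       b = 0.223, med_specific_fraction = 0.5,
                       med_delta_sd = 0.03,
                       pleiotropy = list(mode = "none", mean = 0, sd = 0,
                                         fraction_affected = 0),
                       outliers = list(count = 0L, offset_multiplier = 0),
                       n_cohorts = 1L, palindromic_fraction = 0.2,
                       all_significant = TRUE, observation_noise = TRUE,
                       seed = 1L) {
  if (L < 4L) stopf("L must be at least 4")
  if (gamma_sd < 0 || med_delta_sd < 0) stopf("effect SDs must be >= 0")
  if (any(c(n_exp, n_med, n_out) <= 0)) stopf("sample sizes must be positive")
  stopifnot(length(eaf_range) == 2L, eaf_range[[1L]] > 0,
            eaf_range[[2L]] < 1, eaf_range[[1L]] < eaf_range[[2L]])
  pleiotropy <- utils::modifyList(
    list(mode = "none", mean = 0, sd = 0, fraction_affected = 0), pleiotropy)
  if (!pleiotropy$mode %in% c("none", "balanced", "directional", "inside_violation"))
    stopf("unknown pleiotropy mode '%s'", pleiotropy$mode)
  if (pleiotropy$fraction_affected < 0 || pleiotropy$fraction_affected > 1)
    stopf("fraction_affected must be in [0,1]")
  outliers <- utils::modifyList(list(count = 0L, offset_multiplier = 0), outliers)
  if (palindromic_fraction < 0 || palindromic_fraction > 1)
    stopf("palindromic_fraction must be in [0,1]")
  structure(list(L = as.integer(L), n_exp = n_exp, n_med = n_med,
                 n_out = rep_len(n_out, n_cohorts), eaf_range = eaf_range,
                 gamma_sd = gamma_sd, theta_direct = theta_direct, a = a,
                 b = b, med_specific_fraction = med_specific_fraction,
                 med_delta_sd = med_delta_sd, pleiotropy = pleiotropy,
                 outliers = outliers, n_cohorts = as.integer(n_cohorts),
                 palindromic_fraction = palindromic_fraction,
                 all_significant = all_significant,
                 observation_noise = observation_noise, seed = seed),
            class = "sim_config")
}

# Allele pairs: non-palindromic draws avoid complement pairs.
NONPAL_PAIRS <- rbind(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                      c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
PAL_PAIRS <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Simulate GWAS summary statistics with known truth
#'
#' Draws one exposure table, one mediator table, and `n_cohorts` outcome
#' tables under the structural model of [sim_config()], plus a truth record
#' holding every per-SNP true effect and the implied causal quantities
#' (total effect `theta_direct + a*b`, true proportion mediated). All
#' tables share variant IDs, alleles, and allele frequencies, so
#' harmonization is exact; observed noise is independent across traits and
#' cohorts.
#'
#' @param config a `sim_config`.
#' @return list with `exposure` (`gwas_table`), `mediator` (`gwas_table`),
#'   `outcomes` (list of `gwas_table`), `truth` (list: `gamma`, `delta`,
#'   `kappa`, `alpha_pleio`, `Gamma`, `theta_total`,
#'   `proportion_mediated_true`, `eaf`, `se_*`, `outlier_ids`).
#' @export
simulate_gwas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  with_seed(cf$seed, {
    L <- cf$L
    variant_id <- sprintf("rs%07d", seq_len(L) + 1000000L)
    eaf <- stats::runif(L, cf$eaf_range[[1L]], cf$eaf_range[[2L]])
    pal <- stats::runif(L) < cf$palindromic_fraction
    al <- matrix("", L, 2L)
    al[pal, ] <- PAL_PAIRS[sample.int(nrow(PAL_PAIRS), sum(pal), TRUE), , drop = FALSE]
    al[!pal, ] <- NONPAL_PAIRS[sample.int(nrow(NONPAL_PAIRS), sum(!pal), TRUE), , drop = FALSE]

    se_exp <- 1 / sqrt(2 * eaf * (1 - eaf) * cf$n_exp)
    se_med <- 1 / sqrt(2 * eaf * (1 - eaf) * cf$n_med)

    gamma <- stats::rnorm(L, 0, cf$gamma_sd)
    if (cf$all_significant && cf$gamma_sd > 0) {
      # require the *observed* beta to clear genome-wide significance whp
      zmin <- stats::qnorm(1 - 2.5e-8) + 2
      for (i in 1:100) {
        weak <- abs(gamma) < zmin * se_exp
        if (!any(weak)) break
        gamma[weak] <- stats::rnorm(sum(weak), 0, cf$gamma_sd)
        if (i == 100L)
          gamma[weak] <- sign(gamma[weak] + (gamma[weak] == 0)) * zmin * se_exp[weak] * 1.05
      }
    }
    med_specific <- stats::runif(L) < cf$med_specific_fraction
    delta <- ifelse(med_specific, stats::rnorm(L, 0, cf$med_delta_sd), 0)
    kappa <- cf$a * gamma + delta

    # Pleiotropic offsets are defined in the exposure-increasing-allele
    # frame (sign(gamma) coupling): a "directional" offset must survive the
    # estimators' orientation step, otherwise sign-symmetric instruments
    # would average it away.
    pl <- cf$pleiotropy
    alpha <- numeric(L)
    if (pl$mode != "none" && pl$fraction_affected > 0) {
      hit <- stats::runif(L) < pl$fraction_affected
      alpha[hit] <- switch(pl$mode,
        balanced = stats::rnorm(sum(hit), 0, pl$sd),
        directional = sign(gamma[hit]) * stats::rnorm(sum(hit), pl$mean, pl$sd),
        inside_violation = sign(gamma[hit]) * pl$mean +
          pl$sd * gamma[hit] / max(cf$gamma_sd, 1e-12))
    }
    Gamma <- cf$theta_direct * gamma + cf$b * kappa + alpha

    make_table <- function(true_beta, se, name, unit, n) {
      beta <- if (cf$observation_noise) stats::rnorm(L, true_beta, se) else true_beta
      gwas_table(data.frame(
        variant_id = variant_id, effect_allele = al[, 1L],
        other_allele = al[, 2L], eaf = eaf, beta = beta, se = se,
        pval = pval_wald(beta, se), n = n, stringsAsFactors = FALSE),
        trait_name = name, trait_unit = unit, reconstruct_missing_se = FALSE)
    }
    exposure <- make_table(gamma, se_exp, "sim_exposure", "SD", cf$n_exp)
    mediator <- make_table(kappa, se_med, "sim_mediator", "SD", cf$n_med)
    outcomes <- lapply(seq_len(cf$n_cohorts), function(ci) {
      se_out <- 1 / sqrt(2 * eaf * (1 - eaf) * cf$n_out[[ci]])
      make_table(Gamma, se_out, sprintf("sim_outcome_cohort%d", ci),
                 "log-odds", cf$n_out[[ci]])
    })

    theta_total <- cf$theta_direct + cf$a * cf$b
    truth <- list(gamma = gamma, delta = delta, kappa = kappa,
                  alpha_pleio = alpha, Gamma = Gamma,
                  theta_total = theta_total,
                  proportion_mediated_true = cf$a * cf$b / theta_total,
                  eaf = eaf, variant_id = variant_id,
                  se_exp = se_exp, se_med = se_med,
                  outlier_ids = character())
    sim <- list(exposure = exposure, mediator = mediator, outcomes = outcomes,
                truth = truth, config = cf)
    if (cf$outliers$count > 0L)
      sim <- inject_outliers(sim, cf$outliers$count,
                             cf$outliers$offset_multiplier,
                             seed = NULL)
    sim
  })
}

#' Inject pleiotropic outliers into simulated outcome tables
#'
#' Adds `offset_multiplier * sey_j` to the outcome beta of `count` randomly
#' chosen variants (the same variants in every cohort), recording them in
#' the truth record. Refuses to corrupt half or more of the instruments,
#' since every outlier-robust method here assumes a valid majority.
#'
#' @param sim output of [simulate_gwas()].
#' @param count number of variants to perturb (< L/2).
#' @param offset_multiplier offset in units of the variant's outcome SE.
#' @param seed optional seed (NULL continues the current RNG stream).
#' @return the modified simulation list with `truth$outlier_ids` filled.
#' @export
inject_outliers <- function(sim, count, offset_multiplier, seed = NULL) {
  stopifnot(is.list(sim), !is.null(sim$outcomes))
  L <- nrow(sim$outcomes[[1L]]$data)
  if (count == 0L) return(sim)
  if (count >= L / 2)
    stopf("refusing to corrupt %d of %d instruments (majority-valid assumption broken)",
          count, L)
  with_seed(seed, {
    idx <- sample.int(L, count)
    for (ci in seq_along(sim$outcomes)) {
      d <- sim$outcomes[[ci]]$data
      d$beta[idx] <- d$beta[idx] + offset_multiplier * d$se[idx]
      d$pval[idx] <- pval_wald(d$beta[idx], d$se[idx])
      sim$outcomes[[ci]]$data <- d
    }
    sim$truth$outlier_ids <- sort(sim$outcomes[[1L]]$data$variant_id[idx])
    sim
  })
}

#' Write a simulation to disk as plain TSV plus a truth JSON
#'
#' @param sim output of [simulate_gwas()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(tab, name)
    utils::write.table(tab$data, file.path(dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  wr(sim$exposure, "exposure")
  wr(sim$mediator, "mediator")
  for (ci in seq_along(sim$outcomes)) wr(sim$outcomes[[ci]], paste0("outcome_cohort", ci))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
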