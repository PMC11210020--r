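# Orchestration of the full two-step analysis: instrument selection ->
# harmonization per outcome cohort -> univariable MR and sensitivity suite
# -> random-effects meta-analysis -> MVMR -> mediation -> report tables.

LIABILITY_UNITS <- c("log-odds", "logodds", "log odds", "liability")

# One tidy row per estimate; the single formatting point of the report.
estimate_row <- function(exposure, outcome, cohort, est, unit = "",
                         intercept = NA_real_, intercept_p = NA_real_,
                         i2_gx = NA_real_) {
  data.frame(exposure = exposure, outcome = outcome, cohort = cohort,
             method = est$method, n_snps = est$n_snps, beta = est$beta,
             se = est$se, ci_low = est$ci_low, ci_high = est$ci_high,
             pval = est$pval, q_stat = est$q_stat %||% NA_real_,
             i2 = est$i2 %||% NA_real_, intercept = intercept,
             intercept_p = intercept_p, i2_gx = i2_gx, unit = unit,
             stringsAsFactors = FALSE)
}

meta_to_estimate <- function(me, method) {
  new_mr_estimate(method, me$beta, me$se, nrow(me$cohorts), me$q_meta,
                  me$i2_meta)
}

resolve_table <- function(entry, default_unit = "SD") {
  if (inherits(entry, "gwas_table")) return(entry)
  if (is.character(entry)) return(read_sumstats(entry, trait_unit = default_unit))
  if (is.list(entry)) {
    if (inherits(entry$table, "gwas_table")) return(entry$table)
    return(read_sumstats(entry$path, trait_name = entry$name %||% basename(entry$path),
                         trait_unit = entry$unit %||% default_unit))
  }
  stopf("cannot interpret trait entry of class %s", class(entry)[[1L]])
}

#' Run the full two-step MR analysis
#'
#' Executes, for every exposure-outcome pair: genome-wide-significance
#' instrument selection, blocklist exclusion, per-cohort harmonization, the
#' IVW (multiplicative random effects) main analysis, the requested
#' sensitivity estimators (MR-Egger, weighted median, MR-PRESSO),
#' leave-one-out influence scans, and DerSimonian-Laird meta-analysis of
#' the cohort-level IVW (and outlier-corrected) estimates. Effects of
#' liability-unit exposures are rescaled to per doubling of prevalence.
#' Each (exposure, mediator, outcome) triple named in the config is then
#' decomposed by two-step mediation: step 1 univariable exposure->mediator
#' IVW, step 2 the MVMR mediator effect adjusted for the exposure, product
#' of coefficients with delta-method SE. A failing pair is reported in
#' `$failures` without aborting the others.
#'
#' @param config a named list (or path to a JSON file with the same shape):
#'   `exposures`, `mediators`, `outcomes` are named lists whose elements are
#'   `gwas_table` objects, file paths, or `list(path=, unit=)`; outcome
#'   elements may be named lists of cohort tables. `mediation` is a list of
#'   `c(exposure, mediator, outcome)` name triples. Optional scalars:
#'   `p_threshold` (5e-8), `r2_threshold` (0.001), `eaf_window`
#'   (c(0.42, 0.58)), `methods` (`c("ivw","egger","wm","presso")`),
#'   `blocklist`, `n_boot` (1000), `n_sim` (1000), `seed`, `out_dir`.
#' @return An `mr_analysis_report`: `$estimates` (tidy data.frame including
#'   cohort-level and `cohort == "meta"` rows), `$instruments`,
#'   `$mediation`, `$presso`, `$leave_one_out`, `$failures`, `$config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = FALSE)
  cfg <- utils::modifyList(
    list(p_threshold = 5e-8, r2_threshold = 0.001, eaf_window = c(0.42, 0.58),
         methods = c("ivw", "egger", "wm", "presso"),
         blocklist = DEFAULT_BLOCKLIST, n_boot = 1000L, n_sim = 1000L,
         seed = 1L, out_dir = NULL),
    config)
  if (is.null(cfg$exposures) || is.null(cfg$outcomes))
    stopf("config must name at least one exposure and one outcome")
  eaf_window <- as.numeric(cfg$eaf_window)

  exposures <- lapply(cfg$exposures, resolve_table)
  mediators <- lapply(cfg$mediators %||% list(), resolve_table)
  # every outcome is a named list of cohort tables; promote single tables
  outcomes <- lapply(cfg$outcomes, function(o) {
    if (inherits(o, "gwas_table") || is.character(o) ||
        (is.list(o) && (!is.null(o$path) || !is.null(o$table))))
      list(pooled = resolve_table(o, "log-odds"))
    else lapply(o, resolve_table, default_unit = "log-odds")
  })

  failures <- list()
  note_failure <- function(where, e)
    failures[[length(failures) + 1L]] <<- list(stage = where,
                                               message = conditionMessage(e))

  # instrument selection per exposure/mediator trait
  select_for <- function(tab) {
    sel <- suppressMessages(select_instruments(tab, cfg$p_threshold))
    exclude_blocklist(sel, cfg$blocklist)
  }
  instruments <- lapply(c(exposures, mediators), function(t)
    tryCatch(select_for(t), error = function(e) e))

  inst_rows <- list()
  for (nm in names(instruments)) {
    it <- instruments[[nm]]
    if (inherits(it, "error")) { note_failure(paste0("instruments:", nm), it); next }
    st <- tryCatch(instrument_strength(it), error = function(e) NULL)
    inst_rows[[nm]] <- data.frame(
      trait = nm, n_snps = nrow(it$data),
      r2_total = if (is.null(st)) NA_real_ else st$r2_total,
      f_stat = if (is.null(st)) NA_real_ else st$f_stat,
      weak_instrument_unlikely = if (is.null(st)) NA else st$weak_instrument_unlikely,
      stringsAsFactors = FALSE)
  }

  rows <- list(); presso_out <- list(); loo_out <- list()
  liability <- function(nm) {
    tab <- c(exposures, mediators)[[nm]]
    tolower(tab$trait_unit) %in% LIABILITY_UNITS
  }
  scale_if_liability <- function(est, exp_nm)
    if (liability(exp_nm)) per_doubling(est) else est
  unit_label <- function(exp_nm) if (liability(exp_nm)) "per-doubling" else
    c(exposures, mediators)[[exp_nm]]$trait_unit

  analyse_pair <- function(exp_nm, out_nm, cohorts, inst) {
    per_cohort_ivw <- list(); per_cohort_corr <- list()
    for (co_nm in names(cohorts)) {
      set <- harmonize(inst, cohorts[[co_nm]], eaf_window)
      L <- n_snps(set)
      ivw <- suppressMessages(ivw_mre(set))
      per_cohort_ivw[[co_nm]] <- ivw
      rows[[length(rows) + 1L]] <<- estimate_row(
        exp_nm, out_nm, co_nm, scale_if_liability(ivw, exp_nm), unit_label(exp_nm))
      if ("egger" %in% cfg$methods && L >= 3L) {
        eg <- egger(set)
        rows[[length(rows) + 1L]] <<- estimate_row(
          exp_nm, out_nm, co_nm, scale_if_liability(eg$slope, exp_nm),
          unit_label(exp_nm), eg$intercept$value, eg$intercept$pval, eg$i2_gx)
      }
      if ("wm" %in% cfg$methods && L >= 3L) {
        wm <- weighted_median(set, n_boot = cfg$n_boot, seed = cfg$seed)
        rows[[length(rows) + 1L]] <<- estimate_row(
          exp_nm, out_nm, co_nm, scale_if_liability(wm, exp_nm), unit_label(exp_nm))
      }
      if ("presso" %in% cfg$methods && L >= 4L) {
        pr <- suppressMessages(presso(set, n_sim = cfg$n_sim, seed = cfg$seed))
        presso_out[[paste(exp_nm, out_nm, co_nm, sep = "|")]] <<- pr
        corr <- pr$corrected
        corr$method <- "presso_corrected"
        per_cohort_corr[[co_nm]] <- corr
        rows[[length(rows) + 1L]] <<- estimate_row(
          exp_nm, out_nm, co_nm, scale_if_liability(corr, exp_nm), unit_label(exp_nm))
      }
      if (L >= 3L)
        loo_out[[paste(exp_nm, out_nm, co_nm, sep = "|")]] <<- leave_one_out(set)
    }
    # meta-analysis of cohort-level estimates
    metas <- list(ivw_mre = per_cohort_ivw)
    if (length(per_cohort_corr) == length(cohorts) && length(cohorts) > 1L)
      metas$presso_corrected <- per_cohort_corr
    out <- list()
    for (meth in names(metas)) {
      ests <- metas[[meth]]
      me <- suppressMessages(meta_random(
        vapply(ests, `[[`, numeric(1L), "beta"),
        vapply(ests, `[[`, numeric(1L), "se"), names(ests)))
      pooled <- meta_to_estimate(me, paste0("meta_", meth))
      pooled$n_snps <- ests[[1L]]$n_snps
      rows[[length(rows) + 1L]] <<- estimate_row(
        exp_nm, out_nm, "meta", scale_if_liability(pooled, exp_nm), unit_label(exp_nm))
      out[[meth]] <- pooled
    }
    out$ivw_per_cohort <- per_cohort_ivw
    out
  }

  pair_meta <- list()
  for (exp_nm in names(exposures)) {
    inst <- instruments[[exp_nm]]
    if (inherits(inst, "error")) next
    for (out_nm in names(outcomes)) {
      res <- tryCatch(analyse_pair(exp_nm, out_nm, outcomes[[out_nm]], inst),
                      error = function(e) e)
      if (inherits(res, "error")) note_failure(paste(exp_nm, out_nm, sep = "->"), res)
      else pair_meta[[paste(exp_nm, out_nm, sep = "|")]] <- res
    }
  }

  # exposure -> mediator pairs needed by mediation step 1
  mediation_results <- list()
  for (triple in (cfg$mediation %||% list())) {
    triple <- unlist(triple)
    key <- paste(triple, collapse = "|")
    res <- tryCatch({
      exp_nm <- triple[[1L]]; med_nm <- triple[[2L]]; out_nm <- triple[[3L]]
      inst_e <- instruments[[exp_nm]]; inst_m <- instruments[[med_nm]]
      if (inherits(inst_e, "error")) stop(inst_e)
      if (inherits(inst_m, "error")) stop(inst_m)
      # step 1: exposure -> mediator, univariable IVW on exposure instruments
      set1 <- harmonize(inst_e, mediators[[med_nm]], eaf_window)
      step1 <- suppressMessages(ivw_mre(set1))
      rows[[length(rows) + 1L]] <- estimate_row(
        exp_nm, med_nm, "pooled", scale_if_liability(step1, exp_nm), unit_label(exp_nm))
      # MVMR instrument set: union of both traits' instruments, restricted
      # to variants available in both full tables
      union_ids <- sort(union(inst_e$data$variant_id, inst_m$data$variant_id))
      sub_table <- function(full, ids) {
        d <- full$data[full$data$variant_id %in% ids, , drop = FALSE]
        new_gwas_table(d, full$trait_name, full$trait_unit)
      }
      exp_sub <- sub_table(exposures[[exp_nm]], union_ids)
      med_sub <- sub_table(mediators[[med_nm]], union_ids)
      cohorts <- outcomes[[out_nm]]
      directs <- list(); step2s <- list()
      for (co_nm in names(cohorts)) {
        set2 <- harmonize(list(exp_sub, med_sub), cohorts[[co_nm]], eaf_window)
        mv <- mvmr(set2)
        directs[[co_nm]] <- mv$estimates[[exposures[[exp_nm]]$trait_name]]
        step2s[[co_nm]] <- mv$estimates[[mediators[[med_nm]]$trait_name]]
      }
      pool <- function(ests, meth) {
        if (length(ests) == 1L) { e <- ests[[1L]]; e$method <- meth; return(e) }
        me <- meta_random(vapply(ests, `[[`, numeric(1L), "beta"),
                          vapply(ests, `[[`, numeric(1L), "se"), names(ests))
        pooled <- meta_to_estimate(me, meth)
        pooled$n_snps <- ests[[1L]]$n_snps
        pooled
      }
      direct <- pool(directs, "mvmr_direct")
      step2 <- pool(step2s, "mvmr_step2")
      total <- pair_meta[[paste(exp_nm, out_nm, sep = "|")]]$ivw_mre
      if (is.null(total)) stopf("no univariable estimate for %s -> %s", exp_nm, out_nm)
      total$method <- "ivw_total"
      med <- mediate(step1, step2, total, direct = direct)
      rows[[length(rows) + 1L]] <- estimate_row(exp_nm, out_nm, "meta",
                                                scale_if_liability(direct, exp_nm),
                                                unit_label(exp_nm))
      med
    }, error = function(e) e)
    if (inherits(res, "error")) note_failure(paste0("mediation:", key), res)
    else mediation_results[[key]] <- res
  }

  estimates <- if (length(rows)) do.call(rbind, rows) else
    data.frame(exposure = character())
  report <- structure(list(
    estimates = estimates,
    instruments = if (length(inst_rows)) do.call(rbind, inst_rows) else NULL,
    mediation = mediation_results, presso = presso_out,
    leave_one_out = loo_out, failures = failures, config = cfg),
    class = "mr_analysis_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.mr_analysis_report <- function(x, ...) {
  cat(sprintf("<mr_analysis_report> %d estimate rows, %d mediation triple(s), %d failure(s)\n",
              nrow(x$estimates), length(x$mediation), length(x$failures)))
  invisible(x)
}

#' Write an analysis report to TSV/JSON files
#'
#' Emits `estimates.tsv`, `instruments.tsv`, `mediation.json`,
#' `presso.json`, and `leave_one_out.tsv` under `dir`. Numbers are written
#' at 6 significant digits; row order is the (deterministic) report order,
#' so regeneration from the same inputs and seeds is byte-identical.
#'
#' @param report an `mr_analysis_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(d) {
    num <- vapply(d, is.numeric, logical(1L))
    d[num] <- lapply(d[num], signif, digits = 6L)
    d
  }
  utils::write.table(fmt(report$estimates), file.path(dir, "estimates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$instruments))
    utils::write.table(fmt(report$instruments), file.path(dir, "instruments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  med <- lapply(report$mediation, function(m) list(
    total = unclass(m$total)[c("beta", "se", "ci_low", "ci_high", "pval", "n_snps")],
    direct = if (!is.null(m$direct))
      unclass(m$direct)[c("beta", "se", "ci_low", "ci_high", "pval")],
    step1 = unclass(m$step1)[c("beta", "se", "pval", "n_snps")],
    step2 = unclass(m$step2)[c("beta", "se", "pval")],
    indirect = m$indirect, proportion_mediated = m$proportion_mediated))
  jsonlite::write_json(med, file.path(dir, "mediation.json"),
                       auto_unbox = TRUE, digits = NA)
  pr <- lapply(report$presso, function(p) list(
    rss_obs = p$rss_obs, global_p = p$global_p, outliers = I(p$outliers),
    distortion_p = p$distortion_p, n_sim = p$n_sim,
    corrected_beta = p$corrected$beta, corrected_se = p$corrected$se))
  jsonlite::write_json(pr, file.path(dir, "presso.json"),
                       auto_unbox = TRUE, digits = NA)
  if (length(report$leave_one_out)) {
    loo <- do.call(rbind, lapply(names(report$leave_one_out), function(k) {
      d <- report$leave_one_out[[k]]
      cbind(data.frame(pair = k, stringsAsFactors = FALSE), d)
    }))
    utils::write.table(fmt(loo), file.path(dir, "leave_one_out.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Leave-one-out influence scan
#'
#' Re-fits the IVW estimate with each variant removed in turn; the variant
#' whose removal moves the estimate the most (largest |delta beta| from the
#' full-set fit) is flagged as the maximum-influence variant.
#'
#' @param set a `harmonized_set` with a single exposure, L >= 3.
#' @return data.frame with one row per removed variant (`variant_id`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `pval`, `delta_beta`, `max_influence`).
#' @export
leave_one_out <- function(set) {
  stopifnot(inherits(set, "harmonized_set"))
  if (is.matrix(set$bx)) stopf("leave_one_out expects a single exposure")
  L <- n_snps(set)
  if (L < 3L) stopf("leave-one-out requires at least 3 instruments")
  full <- suppressMessages(ivw_mre(set))
  out <- lapply(seq_len(L), function(j) {
    e <- suppressMessages(ivw_mre(subset_set(set, setdiff(seq_len(L), j))))
    data.frame(variant_id = set$variant_id[[j]], beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, pval = e$pval,
               delta_beta = e$beta - full$beta, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$max_influence <- abs(out$delta_beta) == max(abs(out$delta_beta))
  out
}
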