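# Reading, validation, instrument selection, and allele harmonization of
# GWAS summary statistics.

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

# Default header dialects understood by read_sumstats(). First match wins.
DEFAULT_COLUMN_MAP <- list(
  variant_id    = c("variant_id", "SNP", "snp", "rsid", "RSID", "ID", "MarkerName"),
  effect_allele = c("effect_allele", "EA", "A1", "ALT", "Allele1", "ea"),
  other_allele  = c("other_allele", "OA", "A2", "NEA", "REF", "Allele2", "oa"),
  eaf           = c("eaf", "EAF", "FRQ", "af", "A1FREQ", "Freq1", "effect_allele_frequency"),
  beta          = c("beta", "BETA", "b", "Effect", "effect"),
  se            = c("se", "SE", "StdErr", "standard_error"),
  pval          = c("pval", "P", "p", "pvalue", "P-value", "Pval", "p_value"),
  n             = c("n", "N", "samplesize", "sample_size"),
  chrom         = c("chrom", "CHR", "chr", "chromosome"),
  pos           = c("pos", "BP", "POS", "position", "base_pair_location")
)

new_gwas_table <- function(data, trait_name, trait_unit, log = NULL) {
  stopifnot(is.data.frame(data))
  if (!nzchar(trait_unit)) stopf("trait_unit must be a non-empty label")
  if (anyDuplicated(data$variant_id))
    stopf("duplicate variant_id in table for trait '%s'", trait_name)
  structure(
    list(trait_name = trait_name, trait_unit = trait_unit,
         data = data,
         log = log %||% data.frame(variant_id = character(), reason = character(),
                                   stringsAsFactors = FALSE)),
    class = "gwas_table")
}

#' Construct a GWAS summary-statistics table
#'
#' Bundles per-variant association summary statistics (effect/other allele,
#' effect-allele frequency, beta, standard error, p-value, sample size) for a
#' single trait, the raw material of every downstream MR step. Rows failing
#' validation are dropped and recorded in the exclusion log.
#'
#' @param data data.frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, and at least one of `se`, `pval`; optional
#'   `eaf`, `n`, `chrom`, `pos`.
#' @param trait_name trait label, e.g. `"fasting_insulin"`.
#' @param trait_unit unit of `beta`, e.g. `"SD"`, `"log pmol/l"`, `"log-odds"`.
#' @param reconstruct_missing_se fill missing standard errors from beta and
#'   p-value via [reconstruct_se()] (default `TRUE`).
#' @return A `gwas_table` object: `$trait_name`, `$trait_unit`, `$data`
#'   (validated rows), `$log` (dropped rows with reasons).
#' @export
gwas_table <- function(data, trait_name, trait_unit = "SD",
                       reconstruct_missing_se = TRUE) {
  req <- c("variant_id", "effect_allele", "other_allele", "beta")
  miss <- setdiff(req, names(data))
  if (length(miss)) stopf("missing mandatory column(s): %s", paste(miss, collapse = ", "))
  if (!any(c("se", "pval") %in% names(data)))
    stopf("missing mandatory column: one of se, pval")
  for (col in c("eaf", "se", "pval", "n")) if (is.null(data[[col]])) data[[col]] <- NA_real_
  data$variant_id <- as.character(data$variant_id)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))

  drop_reason <- rep(NA_character_, nrow(data))
  flag <- function(bad, why) drop_reason[bad & is.na(drop_reason)] <<- why
  flag(!data$effect_allele %in% BASES | !data$other_allele %in% BASES,
       "invalid-allele")
  flag(data$effect_allele == data$other_allele, "identical-alleles")
  flag(!is.finite(data$beta), "missing-beta")
  flag(!is.na(data$eaf) & (data$eaf < 0 | data$eaf > 1), "eaf-out-of-range")
  flag(!is.na(data$se) & data$se <= 0, "nonpositive-se")
  # GWAS tables routinely print underflowed p = 0; floor rather than drop
  data$pval[!is.na(data$pval) & data$pval == 0] <- .Machine$double.xmin
  flag(!is.na(data$pval) & (data$pval < 0 | data$pval > 1), "pval-out-of-range")
  flag(is.na(data$se) & is.na(data$pval), "no-se-or-pval")
  dup <- duplicated(data$variant_id)
  flag(dup, "duplicate-variant")

  if (reconstruct_missing_se) {
    needs <- is.na(drop_reason) & is.na(data$se)
    if (any(needs)) {
      bad0 <- needs & (data$beta == 0 | data$pval >= 1)
      drop_reason[bad0] <- "se-unrecoverable"
      needs <- needs & !bad0
      data$se[needs] <- reconstruct_se(data$beta[needs], data$pval[needs])
    }
  }
  # fill missing p-values from beta/se for filtering steps
  nap <- is.na(drop_reason) & is.na(data$pval) & !is.na(data$se)
  data$pval[nap] <- pval_wald(data$beta[nap], data$se[nap])

  keep <- is.na(drop_reason)
  log <- data.frame(variant_id = data$variant_id[!keep],
                    reason = drop_reason[!keep], stringsAsFactors = FALSE)
  data <- data[keep, , drop = FALSE]
  if (nrow(data) == 0L) stopf("no valid rows remain for trait '%s'", trait_name)
  rownames(data) <- NULL
  new_gwas_table(data, trait_name, trait_unit, log)
}

#' Read a delimited summary-statistics file
#'
#' Reads a tab- or comma-delimited GWAS summary-statistics table, mapping
#' common header dialects (SNP/rsid, A1/EA, BETA/b, SE, P/pval, EAF/FRQ, N)
#' onto the canonical column names, then validates rows as [gwas_table()].
#'
#' @param path file path; delimiter inferred from the header line.
#' @param column_map named list mapping canonical names to candidate headers;
#'   merged over the shipped defaults.
#' @inheritParams gwas_table
#' @return A `gwas_table`.
#' @export
read_sumstats <- function(path, trait_name = basename(path), trait_unit = "SD",
                          column_map = list(), reconstruct_missing_se = TRUE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  map <- utils::modifyList(DEFAULT_COLUMN_MAP, column_map)
  out <- list()
  for (canon in names(map)) {
    hit <- intersect(map[[canon]], names(raw))
    if (length(hit)) out[[canon]] <- raw[[hit[[1L]]]]
  }
  for (req in c("variant_id", "effect_allele", "other_allele", "beta"))
    if (is.null(out[[req]]))
      stopf("could not locate a '%s' column in %s (headers: %s)",
            req, path, paste(names(raw), collapse = ", "))
  gwas_table(as.data.frame(out, stringsAsFactors = FALSE), trait_name,
             trait_unit, reconstruct_missing_se)
}

#' Reconstruct a standard error from beta and p-value
#'
#' When a GWAS reports effects and p-values but no standard errors, the SE is
#' recovered as |beta| / z, with z the two-sided standard-normal quantile at
#' the reported p-value. Tiny p-values are handled on the log scale, so no
#' quantile overflow can occur.
#'
#' @param beta effect estimate(s), non-zero.
#' @param pval two-sided p-value(s) in (0, 1).
#' @return positive standard error(s), same length as `beta`.
#' @export
reconstruct_se <- function(beta, pval) {
  if (any(pval <= 0 | pval >= 1)) stopf("pval must lie strictly in (0,1)")
  if (any(beta == 0)) stopf("cannot reconstruct se when beta == 0")
  z <- stats::qnorm(log(pval) - log(2), lower.tail = FALSE, log.p = TRUE)
  abs(beta) / z
}

#' Select genome-wide-significant, mutually independent instruments
#'
#' Keeps variants with p below `p_threshold` (default genome-wide
#' significance, 5e-8) and, when a correlation matrix is supplied, greedily
#' clumps them: candidates are visited in ascending p-value (ties broken by
#' variant_id) and retained only if their squared correlation with every
#' already-retained variant stays below `r2_threshold`.
#'
#' @param table a `gwas_table`.
#' @param p_threshold significance threshold (default `5e-8`).
#' @param ld optional symmetric correlation (r) matrix with unit diagonal,
#'   dimnames covering all candidate variants. Entries are correlations;
#'   they are squared before comparison with `r2_threshold`.
#' @param r2_threshold LD pruning threshold on r^2 (default `0.001`).
#' @return A `gwas_table` of retained instruments; removals appended to the log.
#' @export
select_instruments <- function(table, p_threshold = 5e-8, ld = NULL,
                               r2_threshold = 0.001) {
  stopifnot(inherits(table, "gwas_table"))
  if (p_threshold <= 0 || p_threshold >= 1) stopf("p_threshold must be in (0,1)")
  d <- table$data
  sig <- !is.na(d$pval) & d$pval < p_threshold
  log <- data.frame(variant_id = d$variant_id[!sig],
                    reason = rep("pval-above-threshold", sum(!sig)),
                    stringsAsFactors = FALSE)
  d <- d[sig, , drop = FALSE]
  if (nrow(d) == 0L) stopf("no variant passes p < %g", p_threshold)
  if (is.null(ld)) {
    message("select_instruments: no LD matrix supplied; input treated as pre-pruned")
  } else {
    missing_ld <- setdiff(d$variant_id, rownames(ld))
    if (length(missing_ld))
      stopf("LD matrix does not cover candidate variant(s): %s",
            paste(missing_ld, collapse = ", "))
    ord <- order(d$pval, d$variant_id)
    d <- d[ord, , drop = FALSE]
    kept <- character()
    clumped <- character()
    for (v in d$variant_id) {
      if (length(kept) == 0L || all(ld[v, kept]^2 < r2_threshold)) kept <- c(kept, v)
      else clumped <- c(clumped, v)
    }
    if (length(clumped))
      log <- rbind(log, data.frame(variant_id = clumped, reason = "ld-clumped",
                                   stringsAsFactors = FALSE))
    d <- d[d$variant_id %in% kept, , drop = FALSE]
  }
  d <- d[order(d$variant_id), , drop = FALSE]
  rownames(d) <- NULL
  new_gwas_table(d, table$trait_name, table$trait_unit, rbind(table$log, log))
}

#' Variants excluded by default: the two HFE hemochromatosis missense
#' variants, removed so iron-instrument effects are not dominated by
#' hereditary hemochromatosis.
#' @export
DEFAULT_BLOCKLIST <- c("rs1800562", "rs1799945")

#' Remove blocklisted variants and regions
#'
#' Drops named variants (by default the HFE hemochromatosis variants
#' rs1800562 and rs1799945) and, when the table carries coordinates, any
#' variant inside a blocked region (closed 1-based intervals), e.g. the ABO
#' locus. Removals are logged.
#'
#' @param table a `gwas_table`.
#' @param blocked_ids character vector of variant IDs to remove.
#' @param blocked_regions optional list of `c(chrom, start, end)` triples.
#' @return A `gwas_table` (possibly empty `$data` is an error upstream, but an
#'   empty result here is allowed and logged).
#' @export
exclude_blocklist <- function(table, blocked_ids = DEFAULT_BLOCKLIST,
                              blocked_regions = NULL) {
  stopifnot(inherits(table, "gwas_table"))
  d <- table$data
  bad <- d$variant_id %in% blocked_ids
  reason <- ifelse(bad, "blocklisted-variant", NA_character_)
  if (!is.null(blocked_regions)) {
    if (is.null(d$chrom) || is.null(d$pos) || all(is.na(d$pos)))
      stopf("region blocking requested but table lacks chrom/pos coordinates")
    for (reg in blocked_regions) {
      inreg <- !is.na(d$pos) & as.character(d$chrom) == as.character(reg[[1L]]) &
        d$pos >= as.numeric(reg[[2L]]) & d$pos <= as.numeric(reg[[3L]])
      reason[inreg & is.na(reason)] <- "blocklisted-region"
      bad <- bad | inreg
    }
  }
  log <- data.frame(variant_id = d$variant_id[bad], reason = reason[bad],
                    stringsAsFactors = FALSE)
  d <- d[!bad, , drop = FALSE]
  if (nrow(d) == 0L) message("exclude_blocklist: all variants removed")
  rownames(d) <- NULL
  new_gwas_table(d, table$trait_name, table$trait_unit, rbind(table$log, log))
}

# Align one outcome-side record to the exposure orientation.
# Returns "keep", "flip", or a drop reason.
align_alleles <- function(ea_x, oa_x, eaf_x, ea_y, oa_y, eaf_y, eaf_window) {
  palindromic <- identical(COMPLEMENT[[ea_x]], oa_x)
  if (palindromic) {
    same <- (ea_y == ea_x && oa_y == oa_x) || (ea_y == oa_x && oa_y == ea_x)
    if (!same) return("allele-mismatch")
    if (is.na(eaf_x) || is.na(eaf_y)) return("palindromic-missing-eaf")
    if (eaf_x > eaf_window[[1L]] && eaf_x < eaf_window[[2L]])
      return("palindromic-intermediate-EAF")
    if (abs(eaf_x - eaf_y) <= abs(eaf_x - (1 - eaf_y))) "keep" else "flip"
  } else {
    if (ea_y == ea_x && oa_y == oa_x) return("keep")
    if (ea_y == oa_x && oa_y == ea_x) return("flip")
    cey <- COMPLEMENT[[ea_y]]; coy <- COMPLEMENT[[oa_y]]
    if (cey == ea_x && coy == oa_x) return("keep")
    if (cey == oa_x && coy == ea_x) return("flip")
    "allele-mismatch"
  }
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome (and any additional exposure) effects to the first
#' exposure's effect allele at every shared variant. Swapped allele labels
#' flip the sign of the outcome beta and replace its EAF by 1-EAF; strand
#' complements (A<->T, C<->G) are resolved before comparison; palindromic
#' variants are oriented by effect-allele-frequency agreement and discarded
#' when the exposure EAF lies strictly inside the ambiguity window (default
#' 42-58%); irreconcilable allele pairs are discarded. Every discard is
#' logged with its reason, and the retained variants are ordered by
#' ascending variant_id.
#'
#' @param exposure a `gwas_table`, or a list of them for multivariable MR
#'   (everything is aligned to the first; variant sets are intersected).
#' @param outcome a `gwas_table`.
#' @param eaf_window `(low, high)` strict ambiguity window for palindromic
#'   variants, default `c(0.42, 0.58)`.
#' @return A `harmonized_set`: vectors `variant_id`, `ea`, `oa`, `eaf`,
#'   `bx`, `sex` (matrices with one column per exposure when several), `by`,
#'   `sey`, plus `exclusions` (variant_id, reason) and trait names/units.
#' @export
harmonize <- function(exposure, outcome, eaf_window = c(0.42, 0.58)) {
  exposures <- if (inherits(exposure, "gwas_table")) list(exposure) else exposure
  stopifnot(length(exposures) >= 1L, inherits(outcome, "gwas_table"))
  for (e in exposures) stopifnot(inherits(e, "gwas_table"))
  stopifnot(length(eaf_window) == 2L, eaf_window[[1L]] < eaf_window[[2L]])

  ref <- exposures[[1L]]$data
  shared <- ref$variant_id
  for (tab in c(exposures[-1L], list(outcome)))
    shared <- intersect(shared, tab$data$variant_id)
  if (length(shared) == 0L) stopf("no variant shared between exposure and outcome tables")
  shared <- sort(shared)

  ref <- ref[match(shared, ref$variant_id), , drop = FALSE]
  K <- length(exposures)
  L0 <- length(shared)
  bx <- sex <- matrix(NA_real_, L0, K)
  bx[, 1L] <- ref$beta; sex[, 1L] <- ref$se
  excl <- list()
  ok <- rep(TRUE, L0)

  align_table <- function(tab, flip_also_eaf = TRUE) {
    td <- tab$data[match(shared, tab$data$variant_id), , drop = FALSE]
    action <- character(L0)
    for (i in seq_len(L0)) {
      action[[i]] <- align_alleles(ref$effect_allele[[i]], ref$other_allele[[i]],
                                   ref$eaf[[i]], td$effect_allele[[i]],
                                   td$other_allele[[i]], td$eaf[[i]], eaf_window)
    }
    fl <- action == "flip"
    td$beta[fl] <- -td$beta[fl]
    if (flip_also_eaf) td$eaf[fl] <- 1 - td$eaf[fl]
    list(data = td, dropped = !(action %in% c("keep", "flip")), reason = action)
  }

  for (k in seq_len(K)[-1L]) {
    al <- align_table(exposures[[k]])
    bx[, k] <- al$data$beta; sex[, k] <- al$data$se
    drop_k <- al$dropped & ok
    if (any(drop_k))
      excl[[length(excl) + 1L]] <- data.frame(variant_id = shared[drop_k],
                                              reason = al$reason[drop_k],
                                              stringsAsFactors = FALSE)
    ok <- ok & !al$dropped
  }
  alo <- align_table(outcome)
  drop_o <- alo$dropped & ok
  if (any(drop_o))
    excl[[length(excl) + 1L]] <- data.frame(variant_id = shared[drop_o],
                                            reason = alo$reason[drop_o],
                                            stringsAsFactors = FALSE)
  ok <- ok & !alo$dropped

  if (!any(ok)) stopf("harmonization retained zero variants")
  exclusions <- if (length(excl)) do.call(rbind, excl)
    else data.frame(variant_id = character(), reason = character(),
                    stringsAsFactors = FALSE)

  bx <- bx[ok, , drop = FALSE]; sex <- sex[ok, , drop = FALSE]
  structure(list(
    exposure_names = vapply(exposures, function(e) e$trait_name, character(1L)),
    exposure_units = vapply(exposures, function(e) e$trait_unit, character(1L)),
    outcome_name = outcome$trait_name,
    outcome_unit = outcome$trait_unit,
    variant_id = shared[ok],
    ea = ref$effect_allele[ok], oa = ref$other_allele[ok],
    eaf = ref$eaf[ok],
    bx = if (K == 1L) drop(bx) else bx,
    sex = if (K == 1L) drop(sex) else sex,
    by = alo$data$beta[ok], sey = alo$data$se[ok],
    exclusions = exclusions), class = "harmonized_set")
}

# Number of instruments in a harmonized set.
n_snps <- function(set) length(set$variant_id)

# Exposure-beta matrix view (L x K) regardless of K.
bx_matrix <- function(set) {
  if (is.matrix(set$bx)) set$bx else matrix(set$bx, ncol = 1L)
}

#' Write a harmonized set (and its exclusion log) to TSV
#'
#' @param set a `harmonized_set`.
#' @param path output TSV path; the exclusion log goes to
#'   `<path minus extension>.exclusions.tsv`.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(set, path) {
  stopifnot(inherits(set, "harmonized_set"))
  bx <- bx_matrix(set); sex <- if (is.matrix(set$sex)) set$sex else matrix(set$sex, ncol = 1L)
  d <- data.frame(variant_id = set$variant_id, ea = set$ea, oa = set$oa,
                  eaf = set$eaf, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(bx))) {
    sfx <- if (ncol(bx) == 1L) "" else paste0("_", k)
    d[[paste0("bx", sfx)]] <- bx[, k]
    d[[paste0("sex", sfx)]] <- sex[, k]
  }
  d$by <- set$by; d$sey <- set$sey
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expath <- paste0(sub("\\.[^.]*$", "", path), ".exclusions.tsv")
  utils::write.table(set$exclusions, expath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a harmonized set written by [write_harmonized()]
#' @param path TSV path.
#' @param exposure_name,outcome_name trait labels for the restored object.
#' @return A `harmonized_set`.
#' @export
read_harmonized <- function(path, exposure_name = "exposure",
                            outcome_name = "outcome") {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  bxcols <- grep("^bx", names(d), value = TRUE)
  sexcols <- grep("^sex", names(d), value = TRUE)
  K <- length(bxcols)
  structure(list(
    exposure_names = if (K == 1L) exposure_name else paste0(exposure_name, "_", seq_len(K)),
    exposure_units = rep("SD", K),
    outcome_name = outcome_name, outcome_unit = "SD",
    variant_id = d$variant_id, ea = d$ea, oa = d$oa, eaf = d$eaf,
    bx = if (K == 1L) d[[bxcols]] else as.matrix(d[bxcols]),
    sex = if (K == 1L) d[[sexcols]] else as.matrix(d[sexcols]),
    by = d$by, sey = d$sey,
    exclusions = data.frame(variant_id = character(), reason = character(),
                            stringsAsFactors = FALSE)), class = "harmonized_set")
}

#' @export
print.gwas_table <- function(x, ...) {
  cat(sprintf("<gwas_table> %s (%s): %d variants, %d dropped\n",
              x$trait_name, x$trait_unit, nrow(x$data), nrow(x$log)))
  invisible(x)
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s: %d variants (%d excluded)\n",
              paste(x$exposure_names, collapse = " + "), x$outcome_name,
              n_snps(x), nrow(x$exclusions)))
  invisible(x)
}
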