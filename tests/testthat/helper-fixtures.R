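# Fixtures built in code: small harmonized sets and sumstats tables.

# Harmonized set drawn around a true causal slope theta, optionally with
# per-variant pleiotropic offsets added to the outcome betas.
make_set <- function(L = 10, theta = 0.3, seed = 1, sex = 0.01, sey = 0.05,
                     alpha = 0, noise = TRUE) {
  set.seed(seed)
  bx <- rnorm(L, 0, 0.2)
  bx[abs(bx) < 0.02] <- 0.05
  sexv <- rep_len(sex, L)
  seyv <- rep_len(sey, L)
  by <- theta * bx + rep_len(alpha, L) + if (noise) rnorm(L, 0, seyv) else 0
  harmonized_set(bx, sexv, by, seyv)
}

# data.frame of valid summary-stat rows with deterministic alleles.
make_sumstats_df <- function(L = 5, seed = 1, beta_sd = 0.1) {
  set.seed(seed)
  data.frame(
    variant_id = sprintf("rs%03d", seq_len(L)),
    effect_allele = rep_len(c("A", "C", "G", "T", "A"), L),
    other_allele = rep_len(c("G", "T", "A", "C", "C"), L),
    eaf = round(runif(L, 0.1, 0.9), 3),
    beta = round(rnorm(L, 0, beta_sd), 4),
    se = round(runif(L, 0.01, 0.05), 4),
    pval = round(runif(L, 1e-12, 0.5), 15),
    n = 10000L, stringsAsFactors = FALSE)
}

write_tsv <- function(d, path = tempfile(fileext = ".tsv")) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Independent weighted-least-squares oracle (R's own QR path via lm.wfit),
# kept separate from the package's normal-equations solve.
wls_oracle <- function(X, y, w) {
  fit <- stats::lm.wfit(X, y, w)
  XtWX <- crossprod(X, w * X)
  list(coef = fit$coefficients,
       cov_unit = solve(XtWX),
       rss = sum(w * fit$residuals^2))
}
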