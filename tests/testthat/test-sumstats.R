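test_that("read_sumstats round-trips a valid table and maps header dialects", {
  d <- make_sumstats_df(3)
  tab <- read_sumstats(write_tsv(d), trait_name = "t", trait_unit = "SD")
  expect_s3_class(tab, "gwas_table")
  expect_equal(nrow(tab$data), 3L)
  expect_equal(tab$data$beta, d$beta)
  expect_equal(nrow(tab$log), 0L)

  # common GWAS header dialect
  d2 <- d
  names(d2) <- c("SNP", "A1", "A2", "FRQ", "BETA", "SE", "P", "N")
  tab2 <- read_sumstats(write_tsv(d2), trait_name = "t")
  expect_equal(tab2$data$se, d$se)

  d3 <- d[, c("variant_id", "beta", "se")]
  expect_error(read_sumstats(write_tsv(d3)), "effect_allele")
})

test_that("invalid rows are dropped and logged with reasons", {
  d <- make_sumstats_df(6)
  d$other_allele[2] <- d$effect_allele[2]      # identical alleles
  d$eaf[3] <- 1.2                              # eaf out of range
  d$se[4] <- -1                                # nonpositive se
  d$effect_allele[5] <- "N"                    # invalid allele
  tab <- gwas_table(d, "t")
  expect_equal(nrow(tab$data), 2L)
  expect_setequal(tab$log$reason,
                  c("identical-alleles", "eaf-out-of-range", "nonpositive-se",
                    "invalid-allele"))
  # all dropped -> empty-input error
  d_bad <- d[2:5, ]
  expect_error(gwas_table(d_bad, "t"), "no valid rows")
})

test_that("missing se is reconstructed from beta and pval on read", {
  d <- make_sumstats_df(4)
  d$se[2] <- NA
  tab <- gwas_table(d, "t")
  expect_equal(tab$data$se[2], reconstruct_se(d$beta[2], d$pval[2]))
  # beta == 0 with missing se is unrecoverable
  d$beta[3] <- 0; d$se[3] <- NA
  tab2 <- gwas_table(d, "t")
  expect_true("se-unrecoverable" %in% tab2$log$reason)
})

test_that("reconstruct_se matches the normal-quantile oracle", {
  # z = 1 at two-sided p = 0.3173105
  expect_equal(reconstruct_se(1.0, 2 * pnorm(-1)), 1.0, tolerance = 1e-10)
  expect_equal(reconstruct_se(0.10, 0.05), 0.10 / qnorm(0.975),
               tolerance = 1e-10)
  # sign of beta is ignored
  expect_equal(reconstruct_se(-0.2, 0.05), 0.2 / qnorm(0.975),
               tolerance = 1e-10)
  expect_error(reconstruct_se(0, 0.05), "beta")
  expect_error(reconstruct_se(0.1, 1), "pval")
  # log-scale quantile: no overflow at extreme p
  se <- reconstruct_se(0.05, 1e-300)
  expect_true(is.finite(se) && se > 0)
})

test_that("reconstruct_se round-trips p-values to 1e-10 relative error", {
  set.seed(7)
  beta <- rnorm(50, 0, 0.3); beta[beta == 0] <- 0.1
  pval <- 10^runif(50, -200, -0.05)
  se <- reconstruct_se(beta, pval)
  p_back <- 2 * pnorm(-abs(beta / se))
  expect_equal(p_back, pval, tolerance = 1e-10)
})

test_that("select_instruments applies the p threshold and greedy clumping", {
  d <- make_sumstats_df(5)
  d$pval <- c(1e-9, 1e-7, 1e-12, 0.01, 4e-8)
  tab <- gwas_table(d, "t")
  kept <- suppressMessages(select_instruments(tab))
  expect_equal(nrow(kept$data), 3L)
  expect_setequal(kept$data$variant_id, d$variant_id[c(1, 3, 5)])

  # two correlated significant SNPs: only the smaller-p one survives
  d2 <- make_sumstats_df(2)
  d2$pval <- c(1e-9, 1e-12)
  ld <- matrix(c(1, sqrt(0.5), sqrt(0.5), 1), 2,
               dimnames = list(d2$variant_id, d2$variant_id))
  kept2 <- select_instruments(gwas_table(d2, "t"), ld = ld)
  expect_equal(kept2$data$variant_id, "rs002")
  expect_true("ld-clumped" %in% kept2$log$reason)

  # LD matrix must cover all candidates
  expect_error(select_instruments(gwas_table(d2, "t"), ld = ld[1, 1, drop = FALSE]),
               "LD matrix")
})

test_that("greedy clumping agrees with the brute-force pairwise oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    L <- 10
    d <- make_sumstats_df(L, seed = seed)
    d$pval <- 10^runif(L, -15, -8)
    A <- matrix(rnorm(L * L, 0, 0.3), L)
    R <- cov2cor(crossprod(A) + diag(L))
    dimnames(R) <- list(d$variant_id, d$variant_id)
    r2t <- 0.1
    kept <- select_instruments(gwas_table(d, "t"), ld = R, r2_threshold = r2t)
    ids <- kept$data$variant_id
    # oracle: re-run the greedy scan independently and check all kept pairs
    ord <- d$variant_id[order(d$pval, d$variant_id)]
    oracle <- character()
    for (v in ord)
      if (all(R[v, oracle]^2 < r2t)) oracle <- c(oracle, v)
    expect_setequal(ids, oracle)
    if (length(ids) >= 2L) {
      pairs <- combn(ids, 2)
      expect_true(all(R[cbind(pairs[1, ], pairs[2, ])]^2 < r2t))
    }
  }
})

test_that("select_instruments is invariant to input row order", {
  d <- make_sumstats_df(8, seed = 3)
  d$pval <- 10^seq(-15, -8.5, length.out = 8)
  R <- diag(8); R[1, 2] <- R[2, 1] <- 0.9
  dimnames(R) <- list(d$variant_id, d$variant_id)
  a <- select_instruments(gwas_table(d, "t"), ld = R, r2_threshold = 0.01)
  b <- select_instruments(gwas_table(d[sample(8), ], "t"), ld = R,
                          r2_threshold = 0.01)
  expect_equal(a$data$variant_id, b$data$variant_id)
})

test_that("exclude_blocklist removes HFE variants and blocked regions", {
  d <- make_sumstats_df(5)
  d$variant_id[2] <- "rs1800562"
  tab <- gwas_table(d, "t")
  out <- exclude_blocklist(tab)
  expect_false("rs1800562" %in% out$data$variant_id)
  expect_true("blocklisted-variant" %in% out$log$reason)
  # empty blocklist is the identity
  expect_equal(exclude_blocklist(tab, blocked_ids = character())$data, tab$data)
  # region blocking with coordinates
  d$chrom <- "9"; d$pos <- c(100, 200, 300, 400, 500)
  out2 <- exclude_blocklist(gwas_table(d, "t"), blocked_ids = character(),
                            blocked_regions = list(c("9", 150, 350)))
  expect_equal(nrow(out2$data), 3L)
})

test_that("harmonize aligns swapped, complementary, and palindromic alleles", {
  ex <- gwas_table(data.frame(
    variant_id = c("rs1", "rs2", "rs3", "rs4", "rs5"),
    effect_allele = c("A", "A", "A", "A", "A"),
    other_allele  = c("G", "G", "T", "T", "G"),
    eaf = c(0.3, 0.3, 0.50, 0.10, 0.3),
    beta = 0.1, se = 0.01, pval = 1e-10, n = 1e5), "exp")
  out <- gwas_table(data.frame(
    variant_id = c("rs1", "rs2", "rs3", "rs4", "rs5"),
    effect_allele = c("G", "T", "A", "A", "A"),
    other_allele  = c("A", "C", "T", "T", "C"),
    eaf = c(0.7, 0.3, 0.50, 0.88, 0.3),
    beta = 0.05, se = 0.01, pval = 1e-6, n = 1e5), "out")
  set <- harmonize(ex, out)
  # rs1: swapped labels -> outcome beta sign flips
  expect_equal(set$by[set$variant_id == "rs1"], -0.05)
  # rs2: strand complement (T/C == A/G) -> kept as-is
  expect_equal(set$by[set$variant_id == "rs2"], 0.05)
  # rs3: palindromic with intermediate exposure EAF -> discarded
  expect_false("rs3" %in% set$variant_id)
  expect_equal(set$exclusions$reason[set$exclusions$variant_id == "rs3"],
               "palindromic-intermediate-EAF")
  # rs4: palindromic, EAFs concordant only under flip -> sign flipped
  expect_true(abs(0.10 - (1 - 0.88)) < abs(0.10 - 0.88))  # oracle
  expect_equal(set$by[set$variant_id == "rs4"], -0.05)
  # rs5: irreconcilable allele pair -> discarded
  expect_equal(set$exclusions$reason[set$exclusions$variant_id == "rs5"],
               "allele-mismatch")
  # deterministic ascending order
  expect_equal(set$variant_id, sort(set$variant_id))
})

test_that("palindromic variant with EAF exactly at the window edge is retained", {
  ex <- gwas_table(data.frame(
    variant_id = "rs1", effect_allele = "A", other_allele = "T",
    eaf = 0.42, beta = 0.1, se = 0.01, pval = 1e-10, n = 1e5), "exp")
  out <- gwas_table(data.frame(
    variant_id = "rs1", effect_allele = "A", other_allele = "T",
    eaf = 0.42, beta = 0.05, se = 0.01, pval = 1e-6, n = 1e5), "out")
  expect_equal(n_snps(harmonize(ex, out)), 1L)
})

test_that("palindromic variant with missing exposure EAF is discarded", {
  ex <- gwas_table(data.frame(
    variant_id = c("rs1", "rs2"), effect_allele = "A", other_allele = c("T", "G"),
    eaf = NA_real_, beta = 0.1, se = 0.01, pval = 1e-10, n = 1e5), "exp")
  out <- gwas_table(data.frame(
    variant_id = c("rs1", "rs2"), effect_allele = "A", other_allele = c("T", "G"),
    eaf = 0.2, beta = 0.05, se = 0.01, pval = 1e-6, n = 1e5), "out")
  set <- harmonize(ex, out)
  expect_equal(set$variant_id, "rs2")
  expect_equal(set$exclusions$reason, "palindromic-missing-eaf")
})

test_that("harmonization is idempotent and orientation-invariant", {
  sim <- simulate_gwas(sim_config(L = 30, seed = 11))
  ex <- sim$exposure; out <- sim$outcomes[[1]]
  set1 <- harmonize(ex, out)
  # re-express the harmonized set as tables and harmonize again
  as_table <- function(set, side) {
    beta <- if (side == "x") set$bx else set$by
    se <- if (side == "x") set$sex else set$sey
    gwas_table(data.frame(variant_id = set$variant_id, effect_allele = set$ea,
                          other_allele = set$oa, eaf = set$eaf, beta = beta,
                          se = se, pval = pmax(2 * pnorm(-abs(beta / se)), 1e-300),
                          n = 1e5), paste0("re_", side))
  }
  set2 <- harmonize(as_table(set1, "x"), as_table(set1, "y"))
  expect_equal(set2$bx, set1$bx)
  expect_equal(set2$by, set1$by)
  expect_equal(set2$variant_id, set1$variant_id)

  # flipping both allele labels and both beta signs changes nothing
  flip_table <- function(tab) {
    d <- tab$data
    tmp <- d$effect_allele; d$effect_allele <- d$other_allele; d$other_allele <- tmp
    d$beta <- -d$beta; d$eaf <- 1 - d$eaf
    gwas_table(d, tab$trait_name, tab$trait_unit)
  }
  set3 <- harmonize(flip_table(ex), flip_table(out))
  expect_equal(sign(set3$bx) * set3$by, sign(set1$bx) * set1$by)
  expect_equal(abs(set3$bx), abs(set1$bx))
})

test_that("multi-exposure harmonization intersects and aligns to the first exposure", {
  sim <- simulate_gwas(sim_config(L = 25, seed = 5))
  med_small <- sim$mediator
  med_small$data <- med_small$data[1:20, ]
  set <- harmonize(list(sim$exposure, med_small), sim$outcomes[[1]])
  expect_true(is.matrix(set$bx))
  expect_equal(ncol(set$bx), 2L)
  expect_true(all(set$variant_id %in% med_small$data$variant_id))
})

test_that("harmonized sets serialize to TSV and back", {
  set <- make_set(L = 6, seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_harmonized(set, path)
  expect_true(file.exists(sub("\\.tsv$", ".exclusions.tsv", path)))
  back <- read_harmonized(path)
  expect_equal(back$bx, set$bx)
  expect_equal(back$sey, set$sey)
})
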