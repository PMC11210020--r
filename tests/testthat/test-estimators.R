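test_that("wald_ratio arithmetic and degenerate guards", {
  e <- wald_ratio(bx = 0.5, by = 0.1, sey = 0.05)
  expect_equal(e$beta, 0.2)
  expect_equal(e$se, 0.1)
  expect_equal(e$n_snps, 1L)
  expect_true(is.na(e$q_stat))
  e0 <- wald_ratio(bx = 0.5, by = 0, sey = 0.05)
  expect_equal(e0$beta, 0)
  expect_error(wald_ratio(0, 0.1, 0.05), "degenerate")
})

test_that("wald_ratio first-order SE matches a Monte-Carlo oracle", {
  set.seed(99)
  bx <- 0.4; by <- 0.12; sey <- 0.03
  draws <- rnorm(1e5, by, sey) / bx
  e <- wald_ratio(bx, by, sey)
  expect_equal(e$se, sd(draws), tolerance = 0.02)
})

test_that("ivw_mre: exact proportional data gives Q = 0 and the SE floor", {
  set <- make_set(L = 8, theta = 0.3, seed = 4, noise = FALSE)
  e <- ivw_mre(set)
  expect_equal(e$beta, 0.3, tolerance = 1e-12)
  expect_equal(e$q_stat, 0, tolerance = 1e-16)
  expect_equal(e$i2, 0)
  # floor at 1 engaged: se equals the fixed-effect SE
  expect_equal(e$se, 1 / sqrt(sum(set$bx^2 / set$sey^2)), tolerance = 1e-12)
})

test_that("ivw_mre equals the weighted-least-squares matrix oracle", {
  set <- harmonized_set(bx = c(0.1, 0.2, 0.3), sex = rep(0.01, 3),
                        by = c(0.03, 0.05, 0.10), sey = c(0.01, 0.01, 0.02))
  w <- 1 / set$sey^2
  or <- wls_oracle(matrix(set$bx), set$by, w)
  e <- ivw_mre(set)
  expect_equal(e$beta, unname(or$coef), tolerance = 1e-12)
  scale <- max(1, sqrt(or$rss / 2))
  expect_equal(e$se, sqrt(or$cov_unit[1, 1]) * scale, tolerance = 1e-12)
})

test_that("ivw_mre falls back to the Wald ratio at L = 1", {
  set <- harmonized_set(0.5, 0.01, 0.1, 0.05)
  expect_message(e <- ivw_mre(set), "Wald")
  expect_equal(e$beta, 0.2)
})

test_that("cochran_q equals term-by-term summation", {
  set <- make_set(L = 5, theta = 0.25, seed = 6)
  beta <- 0.2
  manual <- sum((set$by - beta * set$bx)^2 / set$sey^2)
  cq <- cochran_q(set, beta)
  expect_equal(cq$q, manual, tolerance = 1e-12)
  expect_equal(cq$df, 4L)
  expect_equal(cq$i2, max(0, (manual - 4) / manual) * 100)
})

test_that("egger recovers exact affine data and matches the WLS oracle", {
  set <- make_set(L = 10, theta = 0.2, seed = 8, alpha = 0.05, noise = FALSE)
  set$bx <- abs(set$bx)  # keep orientation trivial for the exact check
  set$by <- 0.05 + 0.2 * set$bx
  r <- egger(set)
  expect_equal(r$intercept$value, 0.05, tolerance = 1e-10)
  expect_equal(r$slope$beta, 0.2, tolerance = 1e-10)

  set2 <- make_set(L = 12, theta = 0.3, seed = 9, alpha = 0.02)
  bx <- abs(set2$bx); by <- sign(set2$bx) * set2$by
  w <- 1 / set2$sey^2
  or <- wls_oracle(cbind(1, bx), by, w)
  r2 <- egger(set2)
  expect_equal(r2$slope$beta, unname(or$coef[2]), tolerance = 1e-12)
  scale <- max(1, sqrt(or$rss / (12 - 2)))
  expect_equal(r2$slope$se, sqrt(or$cov_unit[2, 2]) * scale, tolerance = 1e-12)
  expect_equal(r2$intercept$se, sqrt(or$cov_unit[1, 1]) * scale, tolerance = 1e-12)

  # I2_GX against direct summation
  wx <- 1 / set2$sex^2
  bbar <- sum(wx * bx) / sum(wx)
  qgx <- sum(wx * (bx - bbar)^2)
  expect_equal(r2$i2_gx, max(0, (qgx - 11) / qgx), tolerance = 1e-12)
})

test_that("egger rejects degenerate designs", {
  set <- harmonized_set(rep(0.2, 5), rep(0.01, 5), rnorm(5), rep(0.05, 5))
  expect_error(egger(set), "collinear|variation")
  expect_error(egger(make_set(L = 2)), "at least 3")
})

test_that("weighted_median interpolation matches hand computation", {
  # identical ratios: estimate equals the common ratio
  set <- harmonized_set(bx = c(0.1, 0.2, 0.4), sex = rep(0.01, 3),
                        by = 0.4 * c(0.1, 0.2, 0.4), sey = rep(0.02, 3))
  expect_equal(weighted_median(set, n_boot = 0)$beta, 0.4, tolerance = 1e-12)

  # equal weights, ratios (0.1, 0.2, 0.9): cumulative standardized weights
  # (1/6, 1/2, 5/6) put the interpolated median exactly at 0.2
  bx <- c(0.1, 0.1, 0.1)
  sey <- rep(0.02, 3)
  by <- c(0.1, 0.2, 0.9) * bx
  set2 <- harmonized_set(bx, rep(0.01, 3), by, sey)
  expect_equal(weighted_median(set2, n_boot = 0)$beta, 0.2, tolerance = 1e-12)
  expect_error(weighted_median(make_set(L = 2)), "at least 3")
})

test_that("weighted_median bootstrap SE is seeded and reproducible", {
  set <- make_set(L = 15, theta = 0.25, seed = 10)
  a <- weighted_median(set, n_boot = 200, seed = 42)
  b <- weighted_median(set, n_boot = 200, seed = 42)
  expect_identical(a$se, b$se)
  expect_true(a$se > 0)
})

test_that("weighted_median lies between the extreme per-SNP ratios", {
  for (seed in 1:10) {
    set <- make_set(L = 9, theta = 0.2, seed = seed)
    r <- set$by / set$bx
    est <- weighted_median(set, n_boot = 0)$beta
    expect_gte(est, min(r))
    expect_lte(est, max(r))
  }
})

test_that("subset_estimates stratifies and falls back for singleton classes", {
  set <- make_set(L = 7, theta = 0.3, seed = 12)
  all_one <- subset_estimates(set, rep("all", 7))
  expect_equal(all_one$all$beta, ivw_mre(set)$beta)
  mixed <- subset_estimates(set, c(rep("a", 6), "b"))
  expect_equal(mixed$b$method, "wald")
  expect_equal(mixed$b$beta, set$by[7] / set$bx[7])
  expect_equal(mixed$a$n_snps, 6L)
})

test_that("two classes with different true effects are each recovered", {
  set.seed(33)
  L <- 60
  bx <- rnorm(L, 0, 0.2); bx[abs(bx) < 0.05] <- 0.1
  cls <- rep(c("pos", "neg"), each = L / 2)
  theta <- ifelse(cls == "pos", 0.1, -0.3)
  sey <- rep(0.01, L)
  by <- theta * bx + rnorm(L, 0, sey)
  set <- harmonized_set(bx, rep(0.005, L), by, sey)
  res <- subset_estimates(set, cls)
  expect_equal(res$pos$beta, 0.1, tolerance = 0.05)
  expect_equal(res$neg$beta, -0.3, tolerance = 0.05)
})

test_that("estimators are scale-equivariant and orientation-invariant", {
  set <- make_set(L = 12, theta = 0.3, seed = 14)
  c_scale <- 3.7
  scaled <- set; scaled$by <- set$by * c_scale; scaled$sey <- set$sey * c_scale
  for (f in list(ivw_mre, function(s) egger(s)$slope,
                 function(s) weighted_median(s, n_boot = 0))) {
    expect_equal(f(scaled)$beta, f(set)$beta * c_scale, tolerance = 1e-10)
  }
  expect_equal(ivw_mre(scaled)$se, ivw_mre(set)$se * c_scale, tolerance = 1e-10)

  for (seed in 1:5) {
    set.seed(seed)
    flip <- runif(12) < 0.5
    flipped <- set
    flipped$bx[flip] <- -set$bx[flip]
    flipped$by[flip] <- -set$by[flip]
    expect_equal(ivw_mre(flipped)$beta, ivw_mre(set)$beta, tolerance = 1e-12)
    expect_equal(egger(flipped)$slope$beta, egger(set)$slope$beta,
                 tolerance = 1e-12)
    expect_equal(weighted_median(flipped, n_boot = 0)$beta,
                 weighted_median(set, n_boot = 0)$beta, tolerance = 1e-12)
  }
})

test_that("homogeneous data reduces the MRE estimate to fixed-effect IVW", {
  set <- make_set(L = 10, theta = 0.3, seed = 16, noise = FALSE)
  e <- ivw_mre(set)
  w <- 1 / set$sey^2
  expect_equal(e$beta, sum(w * set$bx * set$by) / sum(w * set$bx^2),
               tolerance = 1e-12)
  expect_equal(e$se, 1 / sqrt(sum(w * set$bx^2)), tolerance = 1e-12)
})
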