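test_that("upper-quartile size factors follow the declared quantile rule", {
  # the rule itself: 75th percentile of {1,3,5,7} by p*(n+1) interpolation
  expect_equal(rc_quantile(c(1, 3, 5, 7), 0.75), 6.5)
  expect_equal(rc_quantile(c(0, 0, 1, 3, 5, 7)[c(0, 0, 1, 3, 5, 7) > 0], 0.75),
               6.5)
  m <- cbind(a = c(0, 0, 1, 3, 5, 7), b = 2 * c(0, 0, 1, 3, 5, 7))
  uq <- upper_quartile_normalize(m)
  expect_equal(unname(uq$size_factors["b"] / uq$size_factors["a"]), 2)
  expect_equal(exp(mean(log(uq$size_factors))), 1)
  expect_equal(uq$normalized[, "a"], uq$normalized[, "b"],
               ignore_attr = TRUE)
  m2 <- cbind(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(unname(upper_quartile_normalize(m2)$size_factors),
               c(1, 1))
  expect_error(upper_quartile_normalize(cbind(c(0, 0), c(1, 2))),
               "all-zero")
})

test_that("RPKM follows its definition and scaling laws", {
  expect_equal(rpkm(1000, 2000, 1e7), 50)
  expect_equal(rpkm(0, 1234, 5e6), 0)
  expect_equal(rpkm(100, 500, 2e6), rpkm(100, 500, 1e6) / 2)
  expect_error(rpkm(10, 0, 1e6), "length")
})

test_that("TE is a flagged ratio, invariant to global library rescaling", {
  expect_equal(translation_efficiency(50, 25), 2)
  expect_equal(translation_efficiency(0, 25), 0)
  expect_true(is.na(translation_efficiency(10, 0)))
  rpf <- c(10, 20, 30); rna <- c(5, 10, 15)
  expect_equal(translation_efficiency(rpf * 3.7, rna * 3.7),
               translation_efficiency(rpf, rna))
})

test_that("te_range matches closed forms", {
  expect_equal(te_range(rep(2.5, 100)), 1)
  expect_equal(te_range(c(rep(1, 50), 8), central_mass = 1), 8)
  set.seed(4)
  te <- 2^stats::runif(2e4)  # log2-TE uniform on [0, 1]
  expect_lt(abs(log2(te_range(te)) - 0.95), 0.02)
  expect_error(te_range(rep(1, 10)), "40")
})

test_that("range permutation test is calibrated and deterministic", {
  te <- 2^stats::rnorm(60, sd = 0.5)
  same <- range_permutation_test(te, te, n_perm = 200, seed = 1)
  expect_gt(same$p_value, 0.5)
  r1 <- range_permutation_test(te, te * 2, n_perm = 200, seed = 3)
  r2 <- range_permutation_test(te, te * 2, n_perm = 200, seed = 3)
  expect_identical(r1, r2)
  # type-I error under a common distribution
  set.seed(5)
  hits <- 0
  for (k in 1:200) {
    a <- 2^stats::rnorm(50, sd = 0.7)
    b <- 2^stats::rnorm(50, sd = 0.7)
    p <- range_permutation_test(a, b, n_perm = 1000,
                                seed = sample.int(1e6, 1))$p_value
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.02)
  expect_lte(hits / 200, 0.09)
})

test_that("TE-length regression recovers exact and null relationships", {
  x <- seq(2, 4, length.out = 50)
  fit <- suppressWarnings(te_length_regression(-x, x))  # exact fit warns
  expect_equal(fit$slope, -1)
  expect_equal(fit$r_squared, 1)
  expect_error(te_length_regression(c(1, 2), c(1, 2)), "at least 3")
  expect_error(te_length_regression(rnorm(10), rep(2, 10)), "variance")
  set.seed(6)
  fit0 <- te_length_regression(rnorm(5000), runif(5000, 2, 4))
  expect_lt(fit0$r_squared, 0.01)
})

test_that("location shift recovers injected multiplicative shifts exactly", {
  ref <- 2^stats::rnorm(500, sd = 1)
  same <- location_shift(ref, ref)
  expect_equal(same$delta_log2, 0)
  expect_gt(same$p_value, 0.9)
  sh <- location_shift(ref * 2^(-0.525), ref)
  expect_equal(sh$delta_log2, -0.525)
  # -0.525 log2 units is a >30% TE reduction
  expect_equal(sh$percent_change, 100 * (2^(-0.525) - 1))
  expect_lt(sh$percent_change, -30)
  sh2 <- location_shift(ref * 2^(-0.105), ref)
  expect_equal(round(-sh2$percent_change), 7)
})

test_that("sample PCA separates groups and orders variance fractions", {
  set.seed(7)
  base <- matrix(2^rnorm(200 * 8, 6), 200, 8)
  ident <- pca_samples(base[, c(1, 1, 1, 1)], top_n = 200)
  expect_lt(max(abs(ident$coordinates)), 1e-8)
  grp <- base
  grp[, 5:8] <- grp[, 5:8] * 8
  res <- suppressWarnings(pca_samples(grp, top_n = 4000))
  pc1 <- res$coordinates[, 1]
  expect_true(all(pc1[1:4] < 0) || all(pc1[1:4] > 0))
  expect_true(sign(mean(pc1[1:4])) != sign(mean(pc1[5:8])))
  expect_true(all(diff(res$var_explained) <= 1e-12))
  expect_lte(sum(res$var_explained), 1 + 1e-12)
})

test_that("daily biosynthesis ratios integrate the cycle correctly", {
  zt <- seq(0, 22, 2)
  m <- rbind(ref = rep(4, 12), up = rep(6, 12),
             wave = 4 + 2 * cos(2 * pi * zt / 24))
  r <- daily_biosynthesis_ratio(m, zt, "ref")
  expect_equal(unname(r["ref"]), 1)
  expect_equal(unname(r["up"]), 1.5)
  # trapezoid mean of a full cosine cycle equals the mesor
  expect_equal(unname(r["wave"]), 1)
  expect_error(daily_biosynthesis_ratio(m, zt, "absent"), "absent")
})
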