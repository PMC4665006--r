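test_that("harmonic fit recovers noiseless amplitude and phase exactly", {
  zt <- rep(seq(0, 22, 2), 2)
  for (phase in seq(0, 22, 2)) {
    y <- 2^(5 + (log2(2) / 2) * cos(2 * pi * (zt - phase) / 24))
    fit <- harmonic_fit(y, zt, pseudocount = 0)
    expect_lt(abs(fit$amp_fold - 2), 1e-9)
    dphi <- min(abs(fit$phase_h - phase), 24 - abs(fit$phase_h - phase))
    expect_lt(dphi, 1e-6)
    expect_lt(fit$pvalue, 1e-6)
  }
})

test_that("constant series give unit amplitude and p = 1", {
  fit <- harmonic_fit(rep(32, 12), seq(0, 22, 2))
  expect_equal(fit$amp_fold, 1)
  expect_equal(fit$pvalue, 1)
  expect_error(harmonic_fit(1:4, c(0, 2, 4, 6)), "at least 6")
  expect_error(harmonic_fit(1:6, c(0, 1, 2, 3, 4, 5)), "half the period")
})

test_that("harmonic model methods are mutually consistent", {
  set.seed(12)
  zt <- rep(seq(0, 22, 2), 2)
  y <- 2^(4 + 0.6 * cos(2 * pi * (zt - 7) / 24) + rnorm(24, 0, 0.1))
  fit <- harmonic_fit(y, zt)
  expect_s3_class(fit, "harmonic_fit")
  expect_named(coef(fit), c("mesor", "cos", "sin"))
  expect_equal(fitted(fit) + residuals(fit), log2(y + 1))
  expect_equal(predict(fit, fit$phase_h),
               fit$mesor_log2 + log2(fit$amp_fold) / 2)
  expect_output(print(fit), "fold-amplitude")
})

test_that("harmonic p-values are uniform under the null", {
  set.seed(13)
  zt <- rep(seq(0, 22, 2), 2)
  p <- replicate(1000,
    harmonic_fit(rnorm(24), zt, log2_transform = FALSE)$pvalue)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("rhythm detection honours amplitude-cutoff semantics and FDR", {
  zt <- rep(seq(0, 22, 2), 2)
  # a noiseless amplitude-1.2 gene: tiny p but below the amplitude cutoff
  y <- 2^(6 + (log2(1.2) / 2) * cos(2 * pi * zt / 24))
  m <- matrix(rep(y, 5), 5, 24, byrow = TRUE,
              dimnames = list(paste0("g", 1:5), NULL))
  det <- detect_rhythmic(m, zt, pseudocount = 0)
  expect_true(all(det$pvalue < 1e-6))
  expect_false(any(det$rhythmic))
  # all-null table: BH leaves essentially nothing flagged
  set.seed(14)
  m0 <- matrix(2^rnorm(500 * 24, 6, 0.3), 500, 24,
               dimnames = list(paste0("g", 1:500), NULL))
  det0 <- detect_rhythmic(m0, zt)
  expect_lte(sum(det0$rhythmic), 2)
})

test_that("rhythm detection recovers amp-3 genes among flat genes", {
  set.seed(15)
  zt <- rep(seq(0, 22, 2), 2)
  n <- 200
  truth <- rep(c(FALSE, TRUE), each = n / 2)
  phases <- runif(n, 0, 24)
  m <- t(vapply(seq_len(n), function(g) {
    amp_term <- if (truth[g])
      (log2(3) / 2) * cos(2 * pi * (zt - phases[g]) / 24) else 0
    2^(7 + amp_term + rnorm(24, 0, 0.25))
  }, numeric(24)))
  rownames(m) <- paste0("g", seq_len(n))
  det <- detect_rhythmic(m, zt)
  sens <- mean(det$rhythmic[truth])
  fdr <- sum(det$rhythmic & !truth) / max(1, sum(det$rhythmic))
  expect_gte(sens, 0.95)
  expect_lte(fdr, 0.05)
})

test_that("gene classification satisfies the inclusion-exclusion identities", {
  genes <- paste0("g", 1:10829)
  rna <- setNames(rep(FALSE, 10829), genes)
  rpf <- rna
  rna[1:1870] <- TRUE                    # mRNA rhythmic
  rpf[1:1192] <- TRUE                    # overlap
  rpf[1871:(1870 + 682)] <- TRUE         # footprint-only rhythmic
  cls <- classify_genes(rna, rpf)
  cc <- cls$counts
  expect_equal(unname(cc["rpf_rhythmic"]), 1874)
  expect_equal(unname(cc["rpf_only"]), 682)
  expect_equal(unname(cc["rna_only"]), 678)
  expect_equal(unname(cc["rna_only"]), unname(cc["rna_rhythmic"] - cc["both"]))
  expect_equal(unname(cc["rpf_only"]), unname(cc["rpf_rhythmic"] - cc["both"]))
  expect_equal(sum(cc[c("both", "rna_only", "rpf_only", "neither")]),
               unname(cc["n"]))
  # equal and disjoint sets
  eq <- classify_genes(rna, rna)
  expect_equal(unname(eq$counts["both"]), 1870)
  expect_equal(unname(eq$counts["rna_only"]), 0)
  dis <- classify_genes(rna, setNames(c(rep(FALSE, 1870), rep(TRUE, 10),
                                        rep(FALSE, 10829 - 1880)), genes))
  expect_equal(unname(dis$counts["both"]), 0)
  expect_error(classify_genes(rna[1:10], rpf[11:20]), "universe")
})

test_that("differential TE is calibrated under the null", {
  study <- simulate_study_counts(400, seed = 16,
                                 config = rhythm_config(frac_rna = 0,
                                                        frac_te = 0),
                                 depth = 4e5)
  dte <- differential_te(study$counts[, study$rpf_cols],
                         study$counts[, study$rna_paired], study$zt_rpf)
  expect_lte(sum(dte$qvalue < 0.05, na.rm = TRUE), 2)
  frac05 <- mean(dte$pvalue < 0.05, na.rm = TRUE)
  expect_gt(frac05, 0.01)
  expect_lt(frac05, 0.10)
})

test_that("high-confidence set recovers TE-rhythmic, mRNA-flat genes", {
  study <- simulate_study_counts(1000, seed = 21)
  fitsR <- detect_rhythmic(study$rpkm_rpf, study$zt_rpf)
  fitsN <- detect_rhythmic(study$rpkm_rna, study$zt_rna)
  cls <- classify_genes(fitsN, fitsR)
  dte <- differential_te(study$counts[, study$rpf_cols],
                         study$counts[, study$rna_paired], study$zt_rpf)
  hc <- high_confidence_set(cls, dte)
  g <- study$truth$genes
  te_only <- g$transcript_id[g$te_rhythmic & !g$rna_rhythmic]
  expect_gte(sum(hc %in% te_only), 45)
  expect_lte(sum(!(hc %in% te_only)), 3)
  # genes rhythmic in both assays are excluded no matter the diff-TE q
  dte_all <- dte
  dte_all$qvalue <- 0
  hc_all <- high_confidence_set(cls, dte_all)
  both_genes <- cls$assignments$gene_id[cls$assignments$category == "both"]
  expect_length(intersect(hc_all, both_genes), 0)
  # empty significant set -> empty high-confidence set
  dte_none <- dte
  dte_none$qvalue <- 1
  expect_length(high_confidence_set(cls, dte_none), 0)
})

test_that("Rayleigh statistic and p-value behave at the extremes", {
  r1 <- rayleigh_test(rep(7.25, 20))
  expect_equal(r1$statistic, 1)
  expect_lt(r1$p_value, 1e-6)
  r0 <- rayleigh_test(seq(0, 23, length.out = 24))
  expect_lt(r0$statistic, 1e-10)
  expect_gt(r0$p_value, 0.99)
  expect_error(rayleigh_test(5), "at least 2")
})

test_that("Rayleigh agrees with a Monte-Carlo oracle", {
  # statistic: von Mises kappa = 1 concentration
  set.seed(17)
  obs_R <- rayleigh_test(rvonmises(100, mu = pi, kappa = 1) * 24 / (2 * pi))
  mc_R <- replicate(400, {
    th <- rvonmises(100, mu = pi, kappa = 1)
    sqrt(sum(cos(th))^2 + sum(sin(th))^2) / 100
  })
  expect_lt(abs(obs_R$statistic - mean(mc_R)), 3 * sd(mc_R))
  # p-value: uniform null, factor-2 agreement for p in [1e-3, 0.5]
  n <- 50
  null_R <- replicate(1e5, {
    th <- runif(n, 0, 2 * pi)
    sqrt(sum(cos(th))^2 + sum(sin(th))^2) / n
  })
  for (ptar in c(0.4, 0.05, 0.005)) {
    Rq <- quantile(null_R, 1 - ptar, names = FALSE)
    p_mc <- mean(null_R >= Rq)
    p_formula <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (n * Rq)^2)) - (1 + 2 * n))
    expect_lt(abs(log(p_formula / p_mc)), log(2))
  }
})

test_that("Watson-Wheeler matches its definition and a permutation oracle", {
  set.seed(18)
  # statistic equals the brute-force computation on random instances
  for (k in 1:100) {
    a <- runif(sample(10:25, 1), 0, 24)
    b <- runif(sample(10:25, 1), 0, 24)
    expect_equal(watson_wheeler(a, b)$statistic,
                 oracle_watson_wheeler_W(a, b))
  }
  # identical multisets: W near zero, p near 1
  a <- runif(30, 0, 24)
  same <- watson_wheeler(a, sample(a))
  expect_lt(same$statistic, 0.5)
  expect_gt(same$p_value, 0.7)
  # two tight clusters 12 h apart
  clus <- watson_wheeler(rnorm(50, 6, 0.5) %% 24, rnorm(50, 18, 0.5) %% 24)
  expect_lt(clus$p_value, 1e-6)
  # chi-squared p tracks the permutation p in the moderate regime (where
  # the permutation null can resolve the p-value)
  a2 <- rvonmises(40, mu = 0, kappa = 0.6) * 24 / (2 * pi)
  b2 <- rvonmises(40, mu = 0.7, kappa = 0.6) * 24 / (2 * pi)
  ww <- watson_wheeler(a2, b2)
  pp <- oracle_ww_perm_p(a2, b2, n_perm = 3000)
  expect_lt(abs(log(ww$p_value / pp)), log(2))
  # degenerate: all angles identical
  deg <- suppressWarnings(watson_wheeler(rep(3, 12), rep(3, 15)))
  expect_equal(deg$p_value, 1)
})

test_that("phase histograms bin the cycle and conserve counts", {
  h <- phase_histogram(rep(12, 9))
  expect_equal(unname(h[13]), 9L)
  expect_equal(sum(h), 9L)
  set.seed(19)
  ph <- runif(200, 0, 24)
  expect_equal(sum(phase_histogram(ph)), 200L)
  expect_equal(unname(phase_histogram(23.99)[24]), 1L)
  expect_error(phase_histogram(24), "lie in")
  expect_error(phase_histogram(-0.1), "lie in")
})
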