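test_that("zero depth yields an empty alignment table; seeds give determinism", {
  tx <- generate_transcriptome(10, seed = 4)
  truth <- generate_ground_truth(tx, seed = 5)
  a0 <- simulate_sample(tx, truth, zt = 0, assay = "RPF", depth = 0, seed = 1)
  expect_equal(nrow(a0), 0)
  a1 <- simulate_sample(tx, truth, zt = 4, assay = "RPF", depth = 5000, seed = 1)
  a2 <- simulate_sample(tx, truth, zt = 4, assay = "RPF", depth = 5000, seed = 1)
  expect_identical(a1, a2)
  expect_true(all(a1$pos5 >= 0))
  st <- transcript_structure(tx)
  txlen <- st$tx_len[match(a1$transcript_id, st$transcript_id)]
  expect_true(all(a1$pos5 + a1$length <= txlen))
})

test_that("full frame bias with no leakage puts every A-site in CDS frame 0", {
  tx <- generate_transcriptome(10, seed = 6,
                               config = generator_config(uorf_fraction = 0))
  truth <- generate_ground_truth(tx, rhythm_config(frame_bias = 1,
                                                   pause_fraction = 0),
                                 seed = 7)
  aln <- simulate_sample(tx, truth, zt = 0, assay = "RPF", depth = 2e4,
                         seed = 8, utr5_leak = 0)
  st <- transcript_structure(tx)
  aa <- assign_asite(aln, st)$asites
  u5 <- st$utr5_len[match(aa$transcript_id, st$transcript_id)]
  expect_true(all((aa$pos - u5) %% 3 == 0))
})

test_that("equal-rate genes at vanishing dispersion match the Poisson limit", {
  cfg <- generator_config(utr5_sdlog = 0, cds_codons_sdlog = 0,
                          utr3_sdlog = 0, uorf_fraction = 0)
  tx <- generate_transcriptome(10, seed = 9, config = cfg)
  truth <- generate_ground_truth(tx, rhythm_config(frac_rna = 0, frac_te = 0,
                                                   dispersion = 0,
                                                   pause_fraction = 0),
                                 seed = 10)
  truth$genes$rna_baseline <- 1
  truth$genes$te_baseline <- 1
  aln <- simulate_sample(tx, truth, zt = 0, assay = "RNA", depth = 1e5,
                         seed = 11)
  counts <- table(factor(aln$transcript_id,
                         levels = transcript_structure(tx)$transcript_id))
  expect_true(all(abs(counts - 1e4) <= 3 * sqrt(1e4)))
})

test_that("per-gene counts match the negative binomial mean/variance", {
  tx <- generate_transcriptome(2000, seed = 12)
  truth <- generate_ground_truth(tx, rhythm_config(frac_rna = 0, frac_te = 0,
                                                   dispersion = 0.05),
                                 seed = 13)
  sheet <- sample_sheet(replicates = 1:2, assays = "RPF")
  cm <- simulate_counts(tx, truth, sheet, depth = 1e6, seed = 14)
  mu_hat <- rowMeans(cm)
  v_hat <- apply(cm, 1, var)
  keep <- mu_hat > 100  # variance ratio is noisy for tiny counts
  ratio <- v_hat[keep] / (mu_hat[keep] + 0.05 * mu_hat[keep]^2)
  # with 24 observations per gene, the per-gene ratio is noisy, but the
  # average over ~2000 genes is tight
  expect_gt(mean(ratio), 0.9)
  expect_lt(mean(ratio), 1.1)
})

test_that("RNA reads show no frame preference", {
  tx <- generate_transcriptome(50, seed = 15)
  truth <- generate_ground_truth(tx, seed = 16)
  aln <- simulate_sample(tx, truth, zt = 6, assay = "RNA", depth = 1e5,
                         seed = 17)
  st <- transcript_structure(tx)
  aa <- assign_asite(filter_by_length(aln, 21, 60), st,
                     offsets = rna_offset_table())$asites
  u5 <- st$utr5_len[match(aa$transcript_id, st$transcript_id)]
  cds <- st$cds_len[match(aa$transcript_id, st$transcript_id)]
  in_cds <- aa$pos >= u5 & aa$pos < u5 + cds
  fd <- frame_distribution(aa$pos[in_cds] - u5[in_cds])
  tol <- 3 * sqrt((1 / 3) * (2 / 3) / fd$n)
  expect_true(all(abs(fd$f - 1 / 3) < tol))
})

test_that("simulated 5'UTR read share recovers the configured leakage", {
  tx <- generate_transcriptome(200, seed = 18)
  truth <- generate_ground_truth(tx, seed = 19)
  aln <- simulate_sample(tx, truth, zt = 2, assay = "RPF", depth = 2e5,
                         seed = 20, utr5_leak = 0.06)
  st <- transcript_structure(tx)
  rc <- count_by_region(assign_asite(filter_by_length(aln, 26, 35),
                                     st)$asites, st)
  share <- sum(rc$utr5) / sum(rc$utr5 + rc$cds + rc$utr3)
  expect_lt(abs(share - 0.06), 0.01)
})

test_that("count-level and alignment-level simulators agree on expectations", {
  tx <- generate_transcriptome(100, seed = 21)
  truth <- generate_ground_truth(tx, rhythm_config(frac_rna = 0, frac_te = 0,
                                                   dispersion = 0),
                                 seed = 22)
  sheet <- data.frame(sample_id = "RPF_ZT00_r1", zt = 0, replicate = 1,
                      assay = "RPF", stringsAsFactors = FALSE)
  cm <- simulate_counts(tx, truth, sheet, depth = 2e5, seed = 23)
  aln <- simulate_sample(tx, truth, zt = 0, assay = "RPF", depth = 2e5,
                         seed = 24)
  st <- transcript_structure(tx)
  rc <- count_by_region(assign_asite(filter_by_length(aln, 26, 35),
                                     st)$asites, st)
  # same expected CDS counts: correlation near 1 and no global bias
  expect_gt(cor(cm[, 1], rc$cds), 0.99)
  expect_lt(abs(sum(rc$cds) / sum(cm[, 1]) - 1), 0.05)
})
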