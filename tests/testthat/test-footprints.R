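test_that("length filtering keeps the inclusive bounds and preserves order", {
  aln <- data.frame(transcript_id = "t1", pos5 = 0:3,
                    length = c(25L, 26L, 35L, 36L))
  kept <- filter_by_length(aln, 26, 35)
  expect_equal(kept$length, c(26L, 35L))
  expect_equal(kept$pos5, c(1L, 2L))
  expect_equal(nrow(filter_by_length(aln[0, ], 26, 35)), 0)
  expect_equal(filter_by_length(aln, 0, Inf), aln)
  expect_error(filter_by_length(aln, 30, 20))
})

test_that("A-site assignment applies the offset table and drops what it must", {
  st <- tiny_structure()
  off <- default_offset_table()
  aln <- data.frame(transcript_id = "t1",
                    pos5 = c(100L, 0L, 5L, 440L),
                    length = c(30L, 29L, 25L, 30L))
  res <- assign_asite(aln, st, off)
  # offset[30] = 15 -> 100 + 15 = 115
  expect_equal(res$asites$pos[1], 115L)
  # length 25 absent from the table -> dropped and counted
  expect_equal(unname(res$dropped["no_offset"]), 1L)
  # pos5 440 + 15 = 455 >= 450 -> out of bounds
  expect_equal(unname(res$dropped["out_of_bounds"]), 1L)
  expect_equal(nrow(res$asites), 2)
})

test_that("region counting is exhaustive, exclusive and half-open", {
  st <- tiny_structure()
  rc <- count_by_region(data.frame(transcript_id = "t1",
                                   pos = c(50L, 150L, 420L)), st)
  expect_equal(unlist(rc[1, c("utr5", "cds", "utr3")]),
               c(utr5 = 1L, cds = 1L, utr3 = 1L))
  # boundary: position == utr5_len is the first CDS base
  rc2 <- count_by_region(data.frame(transcript_id = "t1", pos = 100L), st)
  expect_equal(rc2$cds, 1L)
  expect_equal(rc2$utr5, 0L)
  # conservation over random positions
  set.seed(1)
  pos <- sample.int(450, 500, replace = TRUE) - 1L
  rc3 <- count_by_region(data.frame(transcript_id = "t1", pos = pos), st)
  expect_equal(rc3$utr5 + rc3$cds + rc3$utr3, 500L)
})

test_that("region enrichment compares observed shares to length shares", {
  lens <- c(utr5 = 100, cds = 300, utr3 = 100)
  expect_equal(region_enrichment(c(utr5 = 10, cds = 30, utr3 = 10), lens),
               c(utr5 = 1, cds = 1, utr3 = 1))
  r <- region_enrichment(c(utr5 = 0, cds = 100, utr3 = 0),
                         c(utr5 = 150, cds = 300, utr3 = 150))
  expect_equal(unname(r["cds"]), 2)
  expect_error(region_enrichment(c(utr5 = 0, cds = 0, utr3 = 0), lens),
               "no reads")
})

test_that("frame distributions behave at the extremes and under uniformity", {
  fd <- frame_distribution(c(0L, 3L, 9L), anchor = 0L)
  expect_equal(fd$f, c(1, 0, 0))
  expect_equal(frame_distribution(5L, anchor = 0L)$f, c(0, 0, 1))
  fd0 <- frame_distribution(integer(0))
  expect_true(fd0$undefined)
  set.seed(2)
  pos <- sample.int(3e4, 2e4, replace = TRUE)
  fdu <- frame_distribution(pos, anchor = 0L)
  tol <- 3 * sqrt((1 / 3) * (2 / 3) / fdu$n)
  expect_true(all(abs(fdu$f - 1 / 3) < tol))
  expect_equal(sum(fdu$f), 1)
})

test_that("metagene profiles separate periodic footprints from flat RNA", {
  tx <- generate_transcriptome(60, seed = 30)
  truth <- generate_ground_truth(tx, rhythm_config(frame_bias = 1,
                                                   pause_fraction = 0),
                                 seed = 31)
  st <- transcript_structure(tx)
  rpf <- simulate_sample(tx, truth, zt = 0, assay = "RPF", depth = 1e5,
                         seed = 32, utr5_leak = 0)
  mp <- metagene_profile(rpf, st)
  expect_length(mp$start, 200)
  # frame_bias = 1: density strictly confined to every third nucleotide
  off_frame <- seq_along(mp$start)[-seq(1, 200, by = 3)]
  expect_true(all(mp$start[off_frame] == 0))
  expect_gt(periodicity_score(mp$start), 0.9)
  rna <- simulate_sample(tx, truth, zt = 0, assay = "RNA", depth = 1e5,
                         seed = 33)
  mr <- metagene_profile(filter_by_length(rna, 21, 60), st,
                         offsets = rna_offset_table())
  expect_lt(periodicity_score(mr$start), 0.2)
  expect_error(metagene_profile(rpf, st, min_cds = 1e6), "no transcripts")
})

test_that("periodicity score is exact at the extremes and monotone in frame bias", {
  expect_equal(periodicity_score(rep(c(1, 0, 0), 40)), 1)
  expect_equal(periodicity_score(rep(2, 30)), 0)
  expect_error(periodicity_score(rep(0, 30)), "all-zero")
  expect_error(periodicity_score(c(1, 2)), "length")

  scores <- vapply(c(0.5, 0.9), function(fb) {
    tx <- generate_transcriptome(100, seed = 34)
    truth <- generate_ground_truth(tx, rhythm_config(frame_bias = fb,
                                                     pause_fraction = 0),
                                   seed = 35)
    aln <- simulate_sample(tx, truth, zt = 0, assay = "RPF", depth = 1e5,
                           seed = 36)
    periodicity_score(metagene_profile(aln,
                                       transcript_structure(tx))$start)
  }, 0)
  expect_gt(scores[2], scores[1])
})
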