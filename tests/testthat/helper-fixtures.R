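# Shared fixtures and independent oracles, built in code.

# Hand-built single-transcript structure table: 100 nt 5'UTR, 300 nt CDS,
# 50 nt 3'UTR.
tiny_structure <- function() {
  data.frame(transcript_id = "t1", gene_id = "g1",
             utr5_len = 100L, cds_len = 300L, utr3_len = 50L,
             tx_len = 450L, stringsAsFactors = FALSE)
}

# Random 5'UTR with an embedded in-frame AUG..stop uORF of n_codons codons
# (start + body + stop), at 0-based offset `at`. Body codons avoid the base
# A entirely, so no spurious start (ATG) or stop (TAA/TAG/TGA) can arise in
# any frame; the placed uORF is the only ORF in the sequence.
utr_with_uorf <- function(len, at, n_codons) {
  afree <- as.vector(outer(outer(c("C", "G", "T"), c("C", "G", "T"),
                                 paste0), c("C", "G", "T"), paste0))
  chars <- rep("C", len)  # C background: cannot form ATG or stops
  body <- if (n_codons > 2)
    unlist(strsplit(sample(afree, n_codons - 2, replace = TRUE), ""))
  else character(0)
  uorf <- c("A", "T", "G", body, "T", "A", "A")
  chars[(at + 1):(at + 3 * n_codons)] <- uorf
  paste(chars, collapse = "")
}

# von Mises sampler (Best & Fisher rejection), for circular-statistics
# oracles; angles in radians.
rvonmises <- function(n, mu = 0, kappa = 1) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- (sign(u[3] - 0.5) * acos(f) + mu) %% (2 * pi)
      i <- i + 1
    }
  }
  out
}

# Independent trimean oracle: Tukey hinges computed from first principles
# (hinge depth (floor((n+1)/2) + 1) / 2 on the sorted sample).
oracle_trimean <- function(x) {
  x <- sort(x)
  n <- length(x)
  d <- (floor((n + 1) / 2) + 1) / 2
  h1 <- (x[floor(d)] + x[ceiling(d)]) / 2
  h2 <- (x[n + 1 - floor(d)] + x[n + 1 - ceiling(d)]) / 2
  (h1 + 2 * stats::median(x) + h2) / 4
}

# Brute-force pause-site oracle: explicit scan against fold * trimean.
oracle_pause_scan <- function(counts, fold) {
  tm <- oracle_trimean(counts)
  hits <- data.frame(codon_index = integer(0), score = numeric(0))
  for (i in seq_along(counts)) {
    if (counts[i] >= fold * tm)
      hits <- rbind(hits, data.frame(codon_index = i - 1L,
                                     score = counts[i] / tm))
  }
  hits[order(-hits$score), , drop = FALSE]
}

# Independent Watson-Wheeler statistic: literal transcription of the
# rank-score definition, scalar loops throughout.
oracle_watson_wheeler_W <- function(a, b, period = 24) {
  x <- c(a, b) %% period
  N <- length(x)
  r <- rank(x, ties.method = "average")
  W <- 0
  for (grp in list(seq_along(a), length(a) + seq_along(b))) {
    C <- 0; S <- 0
    for (i in grp) {
      C <- C + cos(2 * pi * r[i] / N)
      S <- S + sin(2 * pi * r[i] / N)
    }
    W <- W + (C^2 + S^2) / length(grp)
  }
  2 * W
}

# Permutation null for the Watson-Wheeler statistic.
oracle_ww_perm_p <- function(a, b, n_perm = 2000) {
  obs <- oracle_watson_wheeler_W(a, b)
  pool <- c(a, b)
  hits <- 0
  for (k in seq_len(n_perm)) {
    idx <- sample.int(length(pool), length(a))
    if (oracle_watson_wheeler_W(pool[idx], pool[-idx]) >= obs)
      hits <- hits + 1
  }
  (1 + hits) / (1 + n_perm)
}

# Count matrices and fits for a standard count-level synthetic study.
simulate_study_counts <- function(n_genes, seed, config = rhythm_config(),
                                  depth = 1e6) {
  tx <- generate_transcriptome(n_genes, seed = seed)
  truth <- generate_ground_truth(tx, config, seed = seed + 1L)
  sheet <- sample_sheet()
  cm <- simulate_counts(tx, truth, sheet, depth = depth, seed = seed + 2L)
  st <- transcript_structure(tx)
  is_rpf <- sheet$assay == "RPF"
  rpkm_of <- function(cols) {
    uq <- upper_quartile_normalize(cm[, cols, drop = FALSE])
    sweep(sweep(uq$normalized, 1, st$cds_len / 1e3, "/"),
          2, colSums(uq$normalized) / 1e6, "/")
  }
  key_rpf <- paste(sheet$zt[is_rpf], sheet$replicate[is_rpf])
  key_rna <- paste(sheet$zt[!is_rpf], sheet$replicate[!is_rpf])
  list(tx = tx, truth = truth, sheet = sheet, st = st, counts = cm,
       rpf_cols = sheet$sample_id[is_rpf],
       rna_cols = sheet$sample_id[!is_rpf],
       rna_paired = sheet$sample_id[!is_rpf][match(key_rpf, key_rna)],
       zt_rpf = sheet$zt[is_rpf],
       zt_rna = sheet$zt[!is_rpf],
       rpkm_rpf = rpkm_of(sheet$sample_id[is_rpf]),
       rpkm_rna = rpkm_of(sheet$sample_id[!is_rpf]))
}
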