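#' Default footprint length distribution
#'
#' Categorical over 26-35 nt with modes at 29 and 30 nt (probability 0.35
#' each), emulating the insert-size profile of ribosome-protected fragments.
#'
#' @return Data frame with columns `length` and `prob` (summing to 1).
#' @export
rpf_length_distribution <- function() {
  data.frame(length = 26:35,
             prob = c(0.02, 0.04, 0.10, 0.35, 0.35, 0.08, 0.03, 0.015,
                      0.01, 0.005))
}

#' Sample sheet for the full circadian design
#'
#' @param timepoints ZT hours (default 0, 2, ..., 22).
#' @param replicates replicate indices (default 1:2).
#' @param assays assays (default RPF and RNA).
#' @return Data frame `sample_id`, `zt`, `replicate`, `assay`.
#' @export
sample_sheet <- function(timepoints = seq(0, 22, by = 2), replicates = 1:2,
                         assays = c("RPF", "RNA")) {
  sheet <- expand.grid(zt = timepoints, replicate = replicates,
                       assay = assays, stringsAsFactors = FALSE)
  sheet <- sheet[order(sheet$assay, sheet$replicate, sheet$zt), ]
  sheet$sample_id <- sprintf("%s_ZT%02d_r%d", sheet$assay, sheet$zt,
                             sheet$replicate)
  rownames(sheet) <- NULL
  sheet[, c("sample_id", "zt", "replicate", "assay")]
}

.draw_counts <- function(mu, dispersion) {
  n <- length(mu)
  if (dispersion > 0) stats::rnbinom(n, size = 1 / dispersion, mu = mu)
  else stats::rpois(n, mu)
}

#' Simulate one library as transcript-coordinate alignments
#'
#' Per-gene read totals are negative binomial around the expected rates of
#' the ground truth. Footprint (RPF) reads place their A-site in CDS frame 0
#' with probability `frame_bias`, uniformly over codons except pause-site
#' codons (weighted by their multiplier); a fraction `utr5_leak` of RPF reads
#' falls in the 5'UTR, concentrated on uORFs (in-frame when the uORF is
#' translated). Read 5' ends are back-computed from the A-site via the
#' offset table, and lengths follow [rpf_length_distribution()]. RNA reads
#' are uniform over the transcript with lengths uniform in
#' `rna_length_range`. Reads that would fall outside the transcript are
#' dropped.
#'
#' @param transcripts a `"transcript_set"`.
#' @param truth a `"ground_truth"`.
#' @param zt ZT hour of the sample.
#' @param assay `"RPF"` or `"RNA"`.
#' @param depth total reads to draw (expected; >= 0).
#' @param seed integer seed, or `NULL` to continue the current RNG stream.
#' @param utr5_leak fraction of RPF reads landing in the 5'UTR.
#' @param uorf_concentration of the leaked reads, the fraction directed at
#'   annotated uORFs (proportionally to loading; translated uORFs weighted 4x
#'   relative to untranslated ones).
#' @param rpf_lengths data frame `length`/`prob` for footprint lengths.
#' @param rna_length_range inclusive length band for RNA reads.
#' @param offsets A-site offset table used to back-compute read 5' ends.
#' @return Data frame of alignments: `transcript_id`, `pos5` (0-based),
#'   `length`.
#' @export
simulate_sample <- function(transcripts, truth, zt, assay, depth, seed = NULL,
                            utr5_leak = 0.06, uorf_concentration = 0.8,
                            rpf_lengths = rpf_length_distribution(),
                            rna_length_range = c(21, 60),
                            offsets = default_offset_table()) {
  stopifnot(depth >= 0, assay %in% c("RPF", "RNA"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  empty <- data.frame(transcript_id = character(0), pos5 = integer(0),
                      length = integer(0), stringsAsFactors = FALSE)
  if (depth == 0) return(empty)

  st <- transcript_structure(transcripts)
  g <- truth$genes[match(st$transcript_id, truth$genes$transcript_id), ]
  rate <- if (assay == "RNA") expected_rna_rate(truth, zt)[st$transcript_id] * st$tx_len
          else expected_rpf_rate(truth, zt)[st$transcript_id] * st$cds_len
  mu <- depth * rate / sum(rate)
  counts <- .draw_counts(mu, truth$config$dispersion)
  total <- sum(counts)
  if (total == 0) return(empty)

  tx_of <- rep.int(seq_len(nrow(st)), counts)

  if (assay == "RNA") {
    lo <- rna_length_range[1]; hi <- rna_length_range[2]
    len <- lo + floor(stats::runif(total) * (hi - lo + 1))
    txlen <- st$tx_len[tx_of]
    len <- pmin(len, txlen)
    pos5 <- floor(stats::runif(total) * (txlen - len + 1))
    return(data.frame(transcript_id = st$transcript_id[tx_of],
                      pos5 = as.integer(pos5), length = as.integer(len),
                      stringsAsFactors = FALSE))
  }

  # --- RPF ---
  utr5 <- st$utr5_len[tx_of]
  ncod <- (st$cds_len %/% 3L)[tx_of]
  fb <- g$frame_bias[tx_of]
  leak <- stats::runif(total) < utr5_leak & utr5 >= 3L

  asite <- integer(total)

  # CDS reads: uniform codon except pause sites; frame 0 w.p. frame_bias
  cds_i <- which(!leak)
  codon <- floor(stats::runif(length(cds_i)) * ncod[cds_i])
  if (nrow(truth$pauses) > 0) {
    # re-draw codons for pause genes with weighted sampling
    pg <- match(truth$pauses$transcript_id, st$transcript_id)
    hit <- tx_of[cds_i] %in% pg
    idx_by_gene <- split(which(hit), tx_of[cds_i][hit])
    for (p in seq_along(pg)) {
      sel <- idx_by_gene[[as.character(pg[p])]]
      if (is.null(sel)) next
      w <- rep(1, ncod[cds_i[sel][1]])
      w[truth$pauses$codon_index[p] + 1L] <- truth$pauses$multiplier[p]
      codon[sel] <- sample.int(length(w), length(sel), replace = TRUE,
                               prob = w) - 1L
    }
  }
  in_frame <- stats::runif(length(cds_i)) < fb[cds_i]
  off_frame <- 1L + (stats::runif(length(cds_i)) < 0.5)
  frame <- ifelse(in_frame, 0L, off_frame)
  asite[cds_i] <- utr5[cds_i] + 3L * codon + frame

  # 5'UTR leakage reads
  leak_i <- which(leak)
  if (length(leak_i) > 0) {
    u <- truth$uorfs
    pos_leak <- integer(length(leak_i))
    to_uorf <- rep(FALSE, length(leak_i))
    if (nrow(u) > 0) {
      has_u <- st$transcript_id[tx_of[leak_i]] %in% u$transcript_id
      to_uorf <- has_u & stats::runif(length(leak_i)) < uorf_concentration
    }
    # background: uniform over the 5'UTR
    bg <- which(!to_uorf)
    pos_leak[bg] <- floor(stats::runif(length(bg)) * utr5[leak_i][bg])
    # uORF-directed: choose a uORF by loading (translated weighted up),
    # then a codon within it; frame biased only when translated
    fg <- which(to_uorf)
    if (length(fg) > 0) {
      usplit <- split(u, u$transcript_id)
      fg_tx <- st$transcript_id[tx_of[leak_i[fg]]]
      for (tid in unique(fg_tx)) {
        sel <- fg[fg_tx == tid]
        uu <- usplit[[tid]]
        w <- uu$loading * ifelse(uu$translated, 4, 1)
        k <- sample.int(nrow(uu), length(sel), replace = TRUE, prob = w)
        ncu <- (uu$end - uu$start) %/% 3L
        cod <- floor(stats::runif(length(sel)) * ncu[k])
        r1 <- stats::runif(length(sel))
        r2 <- stats::runif(length(sel))
        fr <- ifelse(uu$translated[k],
                     ifelse(r1 < fb[leak_i[sel]], 0L, 1L + (r2 < 0.5)),
                     floor(r1 * 3))
        pos_leak[sel] <- uu$start[k] + 3L * cod + fr
      }
    }
    asite[leak_i] <- pmin(pos_leak, utr5[leak_i] - 1L)
  }

  len <- sample(rpf_lengths$length, total, replace = TRUE,
                prob = rpf_lengths$prob)
  off <- offsets$offset[match(len, offsets$length)]
  pos5 <- asite - off
  ok <- pos5 >= 0L & pos5 + len <= st$tx_len[tx_of]
  data.frame(transcript_id = st$transcript_id[tx_of][ok],
             pos5 = as.integer(pos5[ok]), length = as.integer(len[ok]),
             stringsAsFactors = FALSE)
}

#' Simulate a full experiment (alignments for every sample)
#'
#' @param transcripts,truth as in [simulate_sample()].
#' @param sheet a [sample_sheet()].
#' @param depth reads per library.
#' @param seed integer seed (one stream for the whole experiment).
#' @param ... passed to [simulate_sample()].
#' @return Named list of alignment data frames, one per `sample_id`.
#' @export
simulate_experiment <- function(transcripts, truth, sheet = sample_sheet(),
                                depth = 1e5, seed = 1, ...) {
  set.seed(as.integer(seed))
  out <- vector("list", nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    out[[i]] <- simulate_sample(transcripts, truth, zt = sheet$zt[i],
                                assay = sheet$assay[i], depth = depth,
                                seed = NULL, ...)
  }
  names(out) <- sheet$sample_id
  out
}

#' Simulate CDS count matrices directly (no read placement)
#'
#' Draws per-gene CDS counts from the identical negative binomial model as
#' [simulate_sample()] without materialising individual alignments; the fast
#' path for count-level studies (rhythm detection, differential TE) at large
#' depth. RPF expectations are scaled by `1 - utr5_leak`, mirroring the
#' leakage of footprints out of the CDS.
#'
#' @inheritParams simulate_experiment
#' @param utr5_leak fraction of RPF reads outside the CDS.
#' @return Matrix genes x samples of CDS counts (dimnames: transcript_id,
#'   sample_id).
#' @export
simulate_counts <- function(transcripts, truth, sheet = sample_sheet(),
                            depth = 1e6, seed = 1, utr5_leak = 0.06) {
  set.seed(as.integer(seed))
  st <- transcript_structure(transcripts)
  m <- matrix(0L, nrow(st), nrow(sheet),
              dimnames = list(st$transcript_id, sheet$sample_id))
  for (i in seq_len(nrow(sheet))) {
    if (sheet$assay[i] == "RNA") {
      rate <- expected_rna_rate(truth, sheet$zt[i])[st$transcript_id] * st$tx_len
      mu <- depth * rate / sum(rate)
      # CDS share of uniform RNA coverage
      mu <- mu * st$cds_len / st$tx_len
    } else {
      rate <- expected_rpf_rate(truth, sheet$zt[i])[st$transcript_id] * st$cds_len
      mu <- depth * rate / sum(rate) * (1 - utr5_leak)
    }
    m[, i] <- .draw_counts(mu, truth$config$dispersion)
  }
  m
}

#' Write alignments as a TSV/BED-like table
#' @param alignments data frame from [simulate_sample()].
#' @param path output path.
#' @param sample_id optional sample label added as a column.
#' @return Invisibly, `path`.
#' @export
write_alignments <- function(alignments, path, sample_id = NULL) {
  if (!is.null(sample_id)) alignments$sample_id <- sample_id
  utils::write.table(alignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an alignment table written by [write_alignments()]
#' @param path TSV path.
#' @return Data frame with `transcript_id`, `pos5`, `length` (and
#'   `sample_id` if present).
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
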