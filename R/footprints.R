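#' Default A-site offset table for mammalian 80S footprints
#'
#' Offsets from the read 5' end to the A-site: 14 nt for 26-28 nt reads,
#' 15 nt for 29-31 nt, 16 nt for 32-35 nt. Standard practice for mammalian
#' ribosome footprints; the table is a plain data frame so alternative rules
#' (or an entry per RNA read length, see [rna_offset_table()]) can be
#' supplied anywhere an `offsets` argument appears.
#'
#' @return Data frame with columns `length` and `offset`.
#' @export
default_offset_table <- function() {
  data.frame(length = 26:35,
             offset = c(14L, 14L, 14L, 15L, 15L, 15L, 16L, 16L, 16L, 16L))
}

#' Constant offset table for RNA-seq reads
#'
#' RNA fragments carry no ribosome, so any fixed offset merely shifts the
#' (uniform) position distribution; a constant 15 nt keeps RNA reads
#' comparable with footprints in region and frame analyses.
#'
#' @param min_len,max_len inclusive read-length range covered.
#' @param offset constant offset (must be < `min_len`).
#' @return Data frame with columns `length` and `offset`.
#' @export
rna_offset_table <- function(min_len = 21, max_len = 60, offset = 15L) {
  stopifnot(offset > 0, offset < min_len)
  data.frame(length = min_len:max_len, offset = as.integer(offset))
}

#' Filter alignments by read length
#'
#' @param alignments alignment data frame (`transcript_id`, `pos5`,
#'   `length`).
#' @param min_len,max_len inclusive bounds (`min_len <= max_len`).
#' @return The retained rows, original order preserved.
#' @export
filter_by_length <- function(alignments, min_len, max_len) {
  stopifnot(min_len <= max_len)
  alignments[alignments$length >= min_len & alignments$length <= max_len, ,
             drop = FALSE]
}

#' Assign A-site positions to alignments
#'
#' A-site = `pos5 + offset(length)`. Reads whose length has no offset entry,
#' or whose A-site falls outside the transcript, are dropped and counted.
#'
#' @param alignments alignment data frame.
#' @param structure transcript structure data frame (needs `transcript_id`,
#'   `tx_len`), e.g. from [transcript_structure()].
#' @param offsets offset table ([default_offset_table()]).
#' @return List with `asites` (data frame `transcript_id`, `pos`) and
#'   `dropped` (named counts: `no_offset`, `out_of_bounds`).
#' @export
assign_asite <- function(alignments, structure,
                         offsets = default_offset_table()) {
  off <- offsets$offset[match(alignments$length, offsets$length)]
  txlen <- structure$tx_len[match(alignments$transcript_id,
                                  structure$transcript_id)]
  pos <- alignments$pos5 + off
  no_offset <- is.na(off)
  oob <- !no_offset & (is.na(txlen) | pos < 0 | pos >= txlen)
  keep <- !no_offset & !oob
  list(asites = data.frame(transcript_id = alignments$transcript_id[keep],
                           pos = as.integer(pos[keep]),
                           stringsAsFactors = FALSE),
       dropped = c(no_offset = sum(no_offset), out_of_bounds = sum(oob)))
}

#' Count A-sites per transcript region
#'
#' Each A-site increments exactly one of 5'UTR / CDS / 3'UTR under the
#' half-open convention: position `utr5_len` is the first CDS nucleotide.
#'
#' @param asites data frame `transcript_id`, `pos` (from [assign_asite()]).
#' @param structure transcript structure data frame.
#' @return Data frame per transcript: `transcript_id`, `utr5`, `cds`,
#'   `utr3` (transcripts without reads included with zeros).
#' @export
count_by_region <- function(asites, structure) {
  i <- match(asites$transcript_id, structure$transcript_id)
  if (anyNA(i)) stop("A-sites on transcripts absent from the structure table")
  u5 <- structure$utr5_len[i]
  ce <- u5 + structure$cds_len[i]
  region <- ifelse(asites$pos < u5, 1L, ifelse(asites$pos < ce, 2L, 3L))
  n <- nrow(structure)
  out <- data.frame(transcript_id = structure$transcript_id,
                    utr5 = 0L, cds = 0L, utr3 = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(asites) > 0) {
    tab <- table(factor(i, levels = seq_len(n)), factor(region, levels = 1:3))
    out$utr5 <- as.integer(tab[, 1])
    out$cds <- as.integer(tab[, 2])
    out$utr3 <- as.integer(tab[, 3])
  }
  out
}

#' Observed/expected read share per region
#'
#' The expected share of each region is its share of total feature length;
#' the enrichment is observed share / expected share (1 = as expected by
#' chance).
#'
#' @param region_counts named totals `c(utr5=, cds=, utr3=)`.
#' @param region_lengths named length totals in nt, same names.
#' @return Named vector of enrichment ratios.
#' @export
region_enrichment <- function(region_counts, region_lengths) {
  regs <- c("utr5", "cds", "utr3")
  region_counts <- region_counts[regs]
  region_lengths <- region_lengths[regs]
  if (sum(region_lengths) <= 0) stop("total region length is zero")
  if (sum(region_counts) <= 0) stop("no reads to compute enrichment from")
  obs <- region_counts / sum(region_counts)
  exp <- region_lengths / sum(region_lengths)
  obs / exp
}

#' Reading-frame distribution of A-sites
#'
#' Fractions of A-sites in frames 0/1/2 relative to `anchor`
#' (`(pos - anchor) mod 3`): the CDS start for CDS analyses, the uORF start
#' for uORF analyses.
#'
#' @param positions integer A-site positions.
#' @param anchor frame anchor position (0-based).
#' @return List `f` (fractions, length 3), `n` (reads used). With `n = 0`
#'   the fractions are `NA` and the result is flagged (`undefined = TRUE`).
#' @export
frame_distribution <- function(positions, anchor = 0L) {
  n <- length(positions)
  if (n == 0)
    return(list(f = c(NA_real_, NA_real_, NA_real_), n = 0L,
                undefined = TRUE))
  fr <- (positions - anchor) %% 3
  list(f = as.numeric(tabulate(fr + 1L, 3L)) / n, n = n, undefined = FALSE)
}

#' Metagene A-site density around start and stop codons
#'
#' Per-nt A-site density over the first `window_nt` nt of the CDS (aligned
#' at the start codon) and the last `window_nt` nt (aligned at the stop).
#' Only transcripts with `cds_len > min_cds` qualify; each transcript's
#' profile is normalised by its own mean within the window before averaging,
#' so highly expressed genes do not dominate.
#'
#' @param alignments alignment data frame.
#' @param structure transcript structure data frame.
#' @param offsets offset table for A-site assignment.
#' @param window_nt window width in nt.
#' @param min_cds minimum CDS length (nt), exclusive.
#' @return List `start`, `stop` (numeric vectors of length `window_nt`) and
#'   `n_transcripts` used.
#' @export
metagene_profile <- function(alignments, structure,
                             offsets = default_offset_table(),
                             window_nt = 200, min_cds = 400) {
  qual <- structure[structure$cds_len > min_cds, , drop = FALSE]
  if (nrow(qual) == 0) stop("no transcripts with CDS > ", min_cds, " nt")
  as <- assign_asite(alignments, structure, offsets)$asites
  as <- as[as$transcript_id %in% qual$transcript_id, , drop = FALSE]
  i <- match(as$transcript_id, qual$transcript_id)
  u5 <- qual$utr5_len[i]
  ce <- u5 + qual$cds_len[i]
  rel_start <- as$pos - u5
  rel_stop <- as$pos - (ce - window_nt)

  acc <- function(rel, idx) {
    inw <- rel >= 0 & rel < window_nt
    prof <- numeric(window_nt)
    used <- 0L
    if (!any(inw)) return(list(prof = prof, used = used))
    by_tx <- split(rel[inw], idx[inw])
    for (v in by_tx) {
      h <- tabulate(v + 1L, window_nt)
      prof <- prof + h / mean(h)
      used <- used + 1L
    }
    list(prof = prof / max(used, 1L), used = used)
  }
  a1 <- acc(rel_start, i)
  a2 <- acc(rel_stop, i)
  list(start = a1$prof, stop = a2$prof,
       n_transcripts = max(a1$used, a2$used))
}

#' 3-nt periodicity score of a metagene profile
#'
#' Fraction of the (DC-removed) spectral power located at period 3: the
#' profile is trimmed to a multiple of 3, mean-centred, Fourier-transformed,
#' and the power in the period-3 bin (and its conjugate) is divided by the
#' total power. 1 for a pure period-3 impulse train, 0 for a constant
#' profile; monotone in reading-frame bias.
#'
#' @param profile numeric vector, length >= 6, not all zero.
#' @return Score in `[0, 1]`.
#' @export
periodicity_score <- function(profile) {
  if (length(profile) < 6) stop("profile must have length >= 6")
  if (all(profile == 0)) stop("all-zero profile")
  n <- 3L * (length(profile) %/% 3L)
  x <- profile[seq_len(n)] - mean(profile[seq_len(n)])
  pw <- Mod(stats::fft(x))^2
  total <- sum(pw[-1L])
  if (total <= .Machine$double.eps * n) return(0)
  k <- n %/% 3L
  unname((pw[k + 1L] + pw[2L * k + 1L]) / total)
}

#' Footprint QC summary
#'
#' One call computing the standard library QC block: read-length histogram,
#' region counts and enrichments, CDS frame fractions, and the 3-nt
#' periodicity score of the start-aligned metagene profile.
#'
#' @param alignments alignment data frame for one (or pooled) libraries.
#' @param structure transcript structure data frame.
#' @param offsets offset table.
#' @param min_cds minimum CDS length for the metagene profile.
#' @return List `length_histogram`, `region_counts`, `region_enrichment`,
#'   `frame`, `periodicity`, `dropped`.
#' @export
footprint_qc <- function(alignments, structure,
                         offsets = default_offset_table(), min_cds = 400) {
  aa <- assign_asite(alignments, structure, offsets)
  rc <- count_by_region(aa$asites, structure)
  tot <- c(utr5 = sum(rc$utr5), cds = sum(rc$cds), utr3 = sum(rc$utr3))
  lens <- c(utr5 = sum(structure$utr5_len), cds = sum(structure$cds_len),
            utr3 = sum(structure$utr3_len))
  i <- match(aa$asites$transcript_id, structure$transcript_id)
  u5 <- structure$utr5_len[i]
  in_cds <- aa$asites$pos >= u5 & aa$asites$pos < u5 + structure$cds_len[i]
  fd <- frame_distribution(aa$asites$pos[in_cds] - u5[in_cds], anchor = 0L)
  per <- tryCatch({
    mp <- metagene_profile(alignments, structure, offsets, min_cds = min_cds)
    periodicity_score(mp$start)
  }, error = function(e) NA_real_)
  list(length_histogram = table(alignments$length),
       region_counts = tot,
       region_enrichment = region_enrichment(tot, lens),
       frame = fd,
       periodicity = per,
       dropped = aa$dropped)
}
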