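.STOP_CODONS <- c("TAA", "TAG", "TGA")

.all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

.sense_codons <- function() setdiff(.all_codons(), .STOP_CODONS)

#' Configuration for the synthetic transcriptome generator
#'
#' Length distributions are log-normal (rounded, clamped to `[min, max]`);
#' CDS lengths are drawn in codons and include the stop codon. A fraction of
#' genes carries 1 to `max_uorfs` AUG-initiated uORFs fully contained in the
#' 5'UTR.
#'
#' @param utr5_meanlog,utr5_sdlog log-normal parameters for 5'UTR length (nt).
#' @param utr5_min,utr5_max clamp for 5'UTR length; set `utr5_max = 0` to
#'   force UTR-less transcripts.
#' @param cds_codons_meanlog,cds_codons_sdlog log-normal parameters for CDS
#'   length in codons (stop included).
#' @param cds_codons_min,cds_codons_max clamp for CDS codons (min 2 = AUG +
#'   stop).
#' @param utr3_meanlog,utr3_sdlog,utr3_min,utr3_max 3'UTR length parameters.
#' @param uorf_fraction fraction of genes carrying at least one uORF.
#' @param max_uorfs maximum uORFs per gene.
#' @param uorf_mean_codons mean uORF length in codons (start + body + stop).
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(utr5_meanlog = log(150), utr5_sdlog = 0.6,
                             utr5_min = 0, utr5_max = 600,
                             cds_codons_meanlog = log(400),
                             cds_codons_sdlog = 0.5,
                             cds_codons_min = 60, cds_codons_max = 2000,
                             utr3_meanlog = log(400), utr3_sdlog = 0.7,
                             utr3_min = 30, utr3_max = 2000,
                             uorf_fraction = 0.35, max_uorfs = 3,
                             uorf_mean_codons = 10) {
  cfg <- list(utr5_meanlog = utr5_meanlog, utr5_sdlog = utr5_sdlog,
              utr5_min = utr5_min, utr5_max = utr5_max,
              cds_codons_meanlog = cds_codons_meanlog,
              cds_codons_sdlog = cds_codons_sdlog,
              cds_codons_min = max(2L, as.integer(cds_codons_min)),
              cds_codons_max = as.integer(cds_codons_max),
              utr3_meanlog = utr3_meanlog, utr3_sdlog = utr3_sdlog,
              utr3_min = utr3_min, utr3_max = utr3_max,
              uorf_fraction = uorf_fraction, max_uorfs = as.integer(max_uorfs),
              uorf_mean_codons = uorf_mean_codons)
  if (cfg$uorf_fraction < 0 || cfg$uorf_fraction > 1)
    stop("uorf_fraction must be in [0, 1]")
  # a uORF needs at least AUG + stop = 6 nt of 5'UTR
  if (cfg$uorf_fraction > 0 && cfg$utr5_max < 6)
    stop("config cannot host a uORF: utr5_max < 6 nt while uorf_fraction > 0")
  class(cfg) <- "generator_config"
  cfg
}

.rlnorm_len <- function(n, meanlog, sdlog, lo, hi) {
  pmin(pmax(round(stats::rlnorm(n, meanlog, sdlog)), lo), hi)
}

#' Generate a synthetic transcriptome
#'
#' Draws `n_genes` single-isoform transcripts (one transcript per gene) with
#' random 5'UTR / CDS / 3'UTR lengths and sequences. The CDS begins with AUG,
#' ends with a stop codon, contains no internal in-frame stop, and its length
#' is a multiple of 3. A configurable fraction of genes carries AUG-initiated
#' uORFs fully contained in the 5'UTR; for every annotated uORF, in-frame
#' AUGs immediately upstream (that would share its stop) are disrupted so the
#' annotated start is the 5'-most start of its ORF.
#'
#' @param n_genes number of genes (>= 1).
#' @param seed integer seed; identical seeds give identical transcriptomes.
#' @param config a [generator_config()].
#' @return An object of class `"transcript_set"`: a list of transcripts, each
#'   with `gene_id`, `transcript_id`, `seq` (character, T not U), `utr5_len`,
#'   `cds_len`, `utr3_len` and a `uorfs` data frame (`start`, `end`; 0-based,
#'   half-open).
#' @export
generate_transcriptome <- function(n_genes, seed,
                                   config = generator_config()) {
  stopifnot(n_genes >= 1)
  if (!inherits(config, "generator_config")) config <- do.call(generator_config, config)
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  sense <- .sense_codons()
  utr5 <- .rlnorm_len(n_genes, config$utr5_meanlog, config$utr5_sdlog,
                      config$utr5_min, config$utr5_max)
  ncod <- .rlnorm_len(n_genes, config$cds_codons_meanlog,
                      config$cds_codons_sdlog,
                      config$cds_codons_min, config$cds_codons_max)
  utr3 <- .rlnorm_len(n_genes, config$utr3_meanlog, config$utr3_sdlog,
                      config$utr3_min, config$utr3_max)
  has_uorf <- stats::runif(n_genes) < config$uorf_fraction

  transcripts <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    u5 <- utr5[g]
    nc <- ncod[g]
    u3 <- utr3[g]
    utr5_seq <- if (u5 > 0) sample(bases, u5, replace = TRUE) else character(0)
    cds_seq <- c("A", "T", "G",
                 unlist(strsplit(sample(sense, nc - 2L, replace = TRUE), "")),
                 unlist(strsplit(sample(.STOP_CODONS, 1L), "")))
    utr3_seq <- if (u3 > 0) sample(bases, u3, replace = TRUE) else character(0)

    uorfs <- data.frame(start = integer(0), end = integer(0))
    if (has_uorf[g] && u5 >= 6) {
      n_u <- sample.int(config$max_uorfs, 1L)
      occupied <- rep(FALSE, u5)
      for (k in seq_len(n_u)) {
        for (try in 1:20) {
          ucod <- 2L + stats::rpois(1L, max(0, config$uorf_mean_codons - 2))
          ucod <- min(ucod, u5 %/% 3L)
          if (ucod < 2L) break
          L <- 3L * ucod
          s <- sample.int(u5 - L + 1L, 1L) - 1L  # 0-based
          span <- (s + 1L):(s + L)
          if (any(occupied[span])) next
          body <- if (ucod > 2L)
            unlist(strsplit(sample(sense, ucod - 2L, replace = TRUE), ""))
          else character(0)
          utr5_seq[span] <- c("A", "T", "G", body,
                              unlist(strsplit(sample(.STOP_CODONS, 1L), "")))
          occupied[span] <- TRUE
          uorfs <- rbind(uorfs, data.frame(start = s, end = s + L))
          break
        }
      }
      # disrupt upstream in-frame AUGs that would share an annotated stop
      if (nrow(uorfs) > 0) {
        uorfs <- uorfs[order(uorfs$start), , drop = FALSE]
        for (k in seq_len(nrow(uorfs))) {
          s <- uorfs$start[k]
          p <- s - 3L
          while (p >= 0L) {
            codon <- paste(utr5_seq[(p + 1L):(p + 3L)], collapse = "")
            if (codon %in% .STOP_CODONS) break
            if (occupied[p + 1L]) break
            if (codon == "ATG") utr5_seq[p + 1L] <- "C"
            p <- p - 3L
          }
        }
        # background AUGs reachable through another uORF's span can still
        # extend an ORF 5' of the placed start; adopt the 5'-most AUG per
        # stop so annotations obey the maximal-ORF convention
        cand <- find_candidate_uorfs(paste(utr5_seq, collapse = ""))
        hit <- match(uorfs$end, cand$end)
        ok <- !is.na(hit)
        uorfs$start[ok] <- cand$start[hit[ok]]
      }
    }
    tx <- list(gene_id = sprintf("gene%04d", g),
               transcript_id = sprintf("tx%04d", g),
               seq = paste(c(utr5_seq, cds_seq, utr3_seq), collapse = ""),
               utr5_len = as.integer(u5),
               cds_len = as.integer(3L * nc),
               utr3_len = as.integer(u3),
               uorfs = uorfs)
    transcripts[[g]] <- tx
  }
  names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  structure(transcripts, class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  st <- transcript_structure(x)
  cat(sprintf("transcript_set: %d transcripts\n", length(x)))
  cat(sprintf("  median lengths (nt): 5'UTR %d | CDS %d | 3'UTR %d\n",
              round(stats::median(st$utr5_len)),
              round(stats::median(st$cds_len)),
              round(stats::median(st$utr3_len))))
  n_u <- sum(vapply(x, function(t) nrow(t$uorfs) > 0, logical(1)))
  cat(sprintf("  genes with annotated uORFs: %d (%.1f%%)\n",
              n_u, 100 * n_u / length(x)))
  invisible(x)
}

#' Transcript structure table
#'
#' @param transcripts a `"transcript_set"`.
#' @return Data frame with one row per transcript: `transcript_id`,
#'   `gene_id`, `utr5_len`, `cds_len`, `utr3_len`, `tx_len`.
#' @export
transcript_structure <- function(transcripts) {
  df <- data.frame(
    transcript_id = vapply(transcripts, `[[`, "", "transcript_id"),
    gene_id = vapply(transcripts, `[[`, "", "gene_id"),
    utr5_len = vapply(transcripts, `[[`, 0L, "utr5_len"),
    cds_len = vapply(transcripts, `[[`, 0L, "cds_len"),
    utr3_len = vapply(transcripts, `[[`, 0L, "utr3_len"),
    stringsAsFactors = FALSE)
  df$tx_len <- df$utr5_len + df$cds_len + df$utr3_len
  rownames(df) <- NULL
  df
}

#' uORF annotation table (transcript space, 0-based half-open)
#'
#' @param transcripts a `"transcript_set"`.
#' @return Data frame `transcript_id`, `uorf_id`, `start`, `end`.
#' @export
uorf_annotation <- function(transcripts) {
  out <- lapply(transcripts, function(tx) {
    if (nrow(tx$uorfs) == 0) return(NULL)
    data.frame(transcript_id = tx$transcript_id,
               uorf_id = sprintf("%s.u%d", tx$transcript_id,
                                 seq_len(nrow(tx$uorfs))),
               start = tx$uorfs$start, end = tx$uorfs$end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(transcript_id = character(0), uorf_id = character(0),
                      start = integer(0), end = integer(0))
  rownames(out) <- NULL
  out
}

#' Validate transcript-model invariants
#'
#' Checks that UTR/CDS lengths tile the sequence, that the CDS is a multiple
#' of 3 (>= 6 nt) starting with AUG and ending with a stop, and that every
#' annotated uORF is an in-frame AUG..stop stretch contained in the 5'UTR.
#'
#' @param transcripts a `"transcript_set"`.
#' @return `TRUE` invisibly; stops with a message on the first violation.
#' @export
validate_transcripts <- function(transcripts) {
  for (tx in transcripts) {
    n <- nchar(tx$seq)
    if (tx$utr5_len + tx$cds_len + tx$utr3_len != n)
      stop(tx$transcript_id, ": region lengths do not sum to sequence length")
    if (tx$cds_len %% 3 != 0 || tx$cds_len < 6)
      stop(tx$transcript_id, ": CDS length not a multiple of 3 or < 6")
    cds_start <- tx$utr5_len
    if (substr(tx$seq, cds_start + 1, cds_start + 3) != "ATG")
      stop(tx$transcript_id, ": CDS does not start with ATG")
    last <- substr(tx$seq, cds_start + tx$cds_len - 2, cds_start + tx$cds_len)
    if (!last %in% .STOP_CODONS)
      stop(tx$transcript_id, ": CDS does not end with a stop codon")
    if (nrow(tx$uorfs) > 0) {
      for (k in seq_len(nrow(tx$uorfs))) {
        s <- tx$uorfs$start[k]; e <- tx$uorfs$end[k]
        if ((e - s) %% 3 != 0 || e - s < 6)
          stop(tx$transcript_id, ": uORF span not a multiple of 3 or < 6")
        if (e > tx$utr5_len)
          stop(tx$transcript_id, ": uORF not contained in 5'UTR")
        if (substr(tx$seq, s + 1, s + 3) != "ATG")
          stop(tx$transcript_id, ": uORF does not start with ATG")
        if (!substr(tx$seq, e - 2, e) %in% .STOP_CODONS)
          stop(tx$transcript_id, ": uORF does not end with a stop codon")
      }
    }
  }
  invisible(TRUE)
}

#' Write a transcriptome to disk
#'
#' Emits sequences as FASTA, structure as TSV (`transcript_id`, `utr5_len`,
#' `cds_len`, `utr3_len`) and uORFs as transcript-space BED (0-based,
#' half-open).
#'
#' @param transcripts a `"transcript_set"`.
#' @param fasta,structure_tsv,uorf_bed output paths (`NULL` to skip one).
#' @return Invisibly, the vector of paths written.
#' @export
write_transcriptome <- function(transcripts, fasta = NULL,
                                structure_tsv = NULL, uorf_bed = NULL) {
  written <- character(0)
  if (!is.null(fasta)) {
    seqs <- Biostrings::DNAStringSet(
      vapply(transcripts, `[[`, "", "seq"))
    names(seqs) <- vapply(transcripts, `[[`, "", "transcript_id")
    Biostrings::writeXStringSet(seqs, fasta)
    written <- c(written, fasta)
  }
  if (!is.null(structure_tsv)) {
    st <- transcript_structure(transcripts)
    utils::write.table(st[, c("transcript_id", "gene_id", "utr5_len",
                              "cds_len", "utr3_len")],
                       structure_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, structure_tsv)
  }
  if (!is.null(uorf_bed)) {
    ua <- uorf_annotation(transcripts)
    utils::write.table(ua[, c("transcript_id", "start", "end", "uorf_id")],
                       uorf_bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    written <- c(written, uorf_bed)
  }
  invisible(written)
}

#' Read a transcript structure TSV written by [write_transcriptome()]
#' @param path TSV path.
#' @return Data frame with a `tx_len` column added.
#' @export
read_transcript_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  st <- utils::read.delim(path, stringsAsFactors = FALSE)
  st$tx_len <- st$utr5_len + st$cds_len + st$utr3_len
  st
}
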