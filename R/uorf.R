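#' Find candidate AUG-initiated uORFs in a 5'UTR sequence
#'
#' Every maximal ORF starting at an AUG within the 5'UTR whose in-frame stop
#' also lies within the 5'UTR. Nested AUGs sharing a stop are reported once,
#' from the 5'-most AUG. AUGs without an in-frame stop before the end of the
#' UTR (i.e. ORFs overlapping the CDS) are not reported. Minimum span is
#' 6 nt (start + stop).
#'
#' @param utr5_sequence character string over A/C/G/T (U accepted).
#' @return Data frame `start`, `end` (0-based, half-open), ordered by
#'   `start`.
#' @export
find_candidate_uorfs <- function(utr5_sequence) {
  s <- chartr("u", "t", tolower(utr5_sequence))
  s <- toupper(s)
  if (nchar(s) > 0 && grepl("[^ACGT]", s)) stop("invalid characters in sequence")
  n <- nchar(s)
  out <- data.frame(start = integer(0), end = integer(0))
  if (n < 6) return(out)
  chars <- strsplit(s, "")[[1]]
  codon_at <- function(i) paste(chars[(i + 1):(i + 3)], collapse = "")
  starts <- which(chars == "A")
  for (i0 in starts) {
    i <- i0 - 1L  # 0-based
    if (i + 6 > n) next
    if (codon_at(i) != "ATG") next
    j <- i + 3L
    while (j + 3L <= n) {
      if (codon_at(j) %in% .STOP_CODONS) {
        out <- rbind(out, data.frame(start = i, end = j + 3L))
        break
      }
      j <- j + 3L
    }
  }
  if (nrow(out) > 0) {
    # collapse nested starts sharing a stop: keep the 5'-most
    out <- out[order(out$start), , drop = FALSE]
    out <- out[!duplicated(out$end), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Call a uORF translated from footprint frame preference
#'
#' A uORF is called translated when it carries at least `min_reads` A-sites,
#' the fraction in its own frame (frame 0, anchored at the uORF start) is at
#' least `min_frame_frac`, and a one-sided binomial test rejects
#' `f0 = 1/3` at `alpha`.
#'
#' @param uorf list or one-row data frame with `start` and `end`.
#' @param asite_positions integer A-site positions on the transcript
#'   (positions outside the uORF span are ignored).
#' @param min_reads minimum A-sites within the span.
#' @param min_frame_frac minimum in-frame fraction.
#' @param alpha binomial-test significance level.
#' @return List of class `"uorf_call"`: `start`, `end`, `n_asites`,
#'   `frame_fracs`, `p_value`, `translated`.
#' @export
call_translated <- function(uorf, asite_positions, min_reads = 10,
                            min_frame_frac = 0.5, alpha = 0.05) {
  pos <- asite_positions[asite_positions >= uorf$start &
                           asite_positions < uorf$end]
  fd <- frame_distribution(pos, anchor = uorf$start)
  n <- fd$n
  if (n > 0) {
    x0 <- round(fd$f[1] * n)
    p <- stats::binom.test(x0, n, p = 1 / 3,
                           alternative = "greater")$p.value
  } else p <- 1
  translated <- n >= min_reads && !fd$undefined &&
    fd$f[1] >= min_frame_frac && p < alpha
  structure(list(start = uorf$start, end = uorf$end, n_asites = n,
                 frame_fracs = fd$f, p_value = p, translated = translated),
            class = "uorf_call")
}

#' @export
print.uorf_call <- function(x, ...) {
  cat(sprintf("uORF [%d, %d): %d A-sites, frame fractions %s, p = %.3g -> %s\n",
              x$start, x$end, x$n_asites,
              paste(sprintf("%.2f", x$frame_fracs), collapse = "/"),
              x$p_value, if (x$translated) "translated" else "not translated"))
  invisible(x)
}

#' Detect ribosome pause sites by trimean excess
#'
#' Codons whose footprint count reaches `threshold_fold` times the
#' [trimean()] of the gene's per-codon counts; the trimean (rather than the
#' mean or median) keeps the baseline stable on sparsely covered CDSs.
#'
#' @param codon_counts per-codon A-site counts for one CDS (length >= 10).
#' @param threshold_fold multiple of the trimean a codon must reach.
#' @return Data frame `codon_index` (0-based), `score` (count / trimean),
#'   sorted by score, descending. When the trimean is 0 the gene cannot be
#'   scored: an empty frame is returned with attribute `skipped = TRUE` and
#'   a warning.
#' @export
detect_pause_sites <- function(codon_counts, threshold_fold = 5) {
  if (length(codon_counts) < 10) stop("need at least 10 codons")
  tm <- trimean(codon_counts)
  empty <- data.frame(codon_index = integer(0), score = numeric(0))
  if (tm <= 0) {
    warning("CDS trimean is zero; gene skipped")
    attr(empty, "skipped") <- TRUE
    return(empty)
  }
  score <- codon_counts / tm
  idx <- which(codon_counts >= threshold_fold * tm)
  out <- data.frame(codon_index = idx - 1L, score = score[idx])
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fisher enrichment test between two gene flags
#'
#' 2x2 table of two boolean gene annotations over the same universe;
#' two-sided Fisher's exact p, plus the fold enrichment of the observed
#' overlap over the overlap expected under independence.
#'
#' @param flags_a,flags_b logical vectors over the same gene universe.
#' @return List `odds_ratio`, `fold_enrichment`, `p_value`, `table`.
#'   Degenerate margins (a flag all TRUE or all FALSE) give `p = 1`.
#' @export
enrichment_test <- function(flags_a, flags_b) {
  stopifnot(length(flags_a) == length(flags_b))
  n <- length(flags_a)
  tab <- table(factor(flags_a, levels = c(TRUE, FALSE)),
               factor(flags_b, levels = c(TRUE, FALSE)))
  pa <- mean(flags_a); pb <- mean(flags_b)
  fold <- if (pa > 0 && pb > 0) mean(flags_a & flags_b) / (pa * pb) else NA_real_
  if (pa %in% c(0, 1) || pb %in% c(0, 1))
    return(list(odds_ratio = NA_real_, fold_enrichment = fold, p_value = 1,
                table = tab))
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), fold_enrichment = fold,
       p_value = ft$p.value, table = tab)
}
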