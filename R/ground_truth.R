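#' Configuration of the ground-truth expression program
#'
#' Defines the study conditions emulated by the simulator: a 24-h design in
#' which disjoint gene sets carry rhythmic mRNA abundance, rhythmic
#' translation efficiency (TE), or both; log-normal baselines; negative
#' binomial counting noise; CDS reading-frame bias; pause sites; and
#' per-uORF translation status.
#'
#' Fold-amplitudes are peak-to-trough ratios of the expected rate; rhythms
#' are cosines on the log2 scale so the fold-amplitude is exact. Translated
#' uORFs repress the TE of their host gene by `uorf_te_shift_log2` (log2
#' units); the residual log2-TE spread `te_sdlog2` is chosen so that,
#' together with that repression, 95% of TEs span roughly a 13-fold range,
#' the magnitude reported for liver.
#'
#' @param frac_rna fraction of genes with rhythmic mRNA only.
#' @param frac_te fraction with rhythmic TE only (mRNA flat).
#' @param frac_both fraction rhythmic in both. The three fractions must each
#'   lie in `[0, 1]` and sum to at most 1.
#' @param amp_range peak-to-trough fold-amplitude range (uniform draw, > 1).
#' @param phase_range peak-time range in hours, within `[0, 24)`.
#' @param dispersion negative binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param frame_bias probability that a CDS footprint A-site falls in frame 0.
#' @param rna_sdlog log-normal sd of the per-nt RNA baseline rate.
#' @param te_sdlog2 sd of log2 baseline TE.
#' @param uorf_translated_prob probability an annotated uORF is translated.
#' @param uorf_loading_range relative footprint loading per uORF (uniform).
#' @param uorf_te_shift_log2 log2 TE shift applied to genes with at least one
#'   translated uORF (negative = repression).
#' @param pause_fraction fraction of genes with a pause site.
#' @param pause_mult_range pause-site density multiplier range (uniform).
#' @return A list of class `"rhythm_config"`.
#' @export
rhythm_config <- function(frac_rna = 0.10, frac_te = 0.05, frac_both = 0,
                          amp_range = c(2, 3), phase_range = c(0, 24),
                          dispersion = 0.05, frame_bias = 0.9,
                          rna_sdlog = 1, te_sdlog2 = 0.93,
                          uorf_translated_prob = 0.5,
                          uorf_loading_range = c(0.5, 2),
                          uorf_te_shift_log2 = -0.525,
                          pause_fraction = 0.10,
                          pause_mult_range = c(5, 15)) {
  fr <- c(frac_rna, frac_te, frac_both)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stop("rhythm fractions must lie in [0, 1] and sum to at most 1")
  if (any(amp_range < 1)) stop("fold-amplitudes must be >= 1")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (frame_bias <= 1 / 3 || frame_bias > 1)
    stop("frame_bias must be in (1/3, 1]")
  structure(list(frac_rna = frac_rna, frac_te = frac_te,
                 frac_both = frac_both, amp_range = amp_range,
                 phase_range = phase_range, dispersion = dispersion,
                 frame_bias = frame_bias, rna_sdlog = rna_sdlog,
                 te_sdlog2 = te_sdlog2,
                 uorf_translated_prob = uorf_translated_prob,
                 uorf_loading_range = uorf_loading_range,
                 uorf_te_shift_log2 = uorf_te_shift_log2,
                 pause_fraction = pause_fraction,
                 pause_mult_range = pause_mult_range),
            class = "rhythm_config")
}

#' Log2-scale cosine modulation
#'
#' Multiplicative factor `2^((log2(amp)/2) * cos(2*pi*(t - phase)/period))`:
#' peak/trough ratio is exactly `amp`, with the peak at `t = phase`.
#'
#' @param t time in hours (ZT).
#' @param amp peak-to-trough fold-amplitude (>= 1).
#' @param phase_h peak time in hours.
#' @param period period in hours.
#' @return Multiplicative modulation factor(s).
#' @export
rhythm_factor <- function(t, amp, phase_h, period = 24) {
  2^((log2(amp) / 2) * cos(2 * pi * (t - phase_h) / period))
}

#' Draw the per-gene ground truth for a synthetic study
#'
#' Assigns disjoint rhythmic-mRNA / rhythmic-TE / both gene sets, baselines,
#' rhythm parameters, pause sites and per-uORF translation flags. The
#' expected footprint rate of gene g at time t is
#' `rna_baseline * te_baseline * rna_mod(t) * te_mod(t)`, each modulation a
#' log2-scale cosine ([rhythm_factor()]).
#'
#' @param transcripts a `"transcript_set"`.
#' @param config a [rhythm_config()].
#' @param seed integer seed.
#' @return Object of class `"ground_truth"`: list with data frames `genes`
#'   (baselines, rhythm flags and parameters, dispersion, frame bias),
#'   `uorfs` (`translated`, `loading` per annotated uORF) and `pauses`
#'   (`codon_index`, `multiplier`), plus the `config`.
#' @export
generate_ground_truth <- function(transcripts, config = rhythm_config(),
                                  seed = 1) {
  if (!inherits(config, "rhythm_config")) config <- do.call(rhythm_config, config)
  set.seed(as.integer(seed))
  st <- transcript_structure(transcripts)
  n <- nrow(st)

  ua <- uorf_annotation(transcripts)
  uorfs <- cbind(ua,
                 translated = stats::runif(nrow(ua)) < config$uorf_translated_prob,
                 loading = stats::runif(nrow(ua), config$uorf_loading_range[1],
                                        config$uorf_loading_range[2]))
  has_tr_uorf <- st$transcript_id %in%
    unique(uorfs$transcript_id[uorfs$translated])

  n_both <- round(config$frac_both * n)
  n_rna <- round(config$frac_rna * n)
  n_te <- round(config$frac_te * n)
  idx <- sample.int(n)
  rna_rhythmic <- te_rhythmic <- rep(FALSE, n)
  take <- function(k, off) if (k > 0) idx[(off + 1):(off + k)] else integer(0)
  i_both <- take(n_both, 0)
  i_rna <- take(n_rna, n_both)
  i_te <- take(n_te, n_both + n_rna)
  rna_rhythmic[c(i_both, i_rna)] <- TRUE
  te_rhythmic[c(i_both, i_te)] <- TRUE

  ramp <- function(k) stats::runif(k, config$amp_range[1], config$amp_range[2])
  rph <- function(k) stats::runif(k, config$phase_range[1], config$phase_range[2])
  genes <- data.frame(
    gene_id = st$gene_id,
    transcript_id = st$transcript_id,
    rna_baseline = stats::rlnorm(n, 0, config$rna_sdlog),
    te_baseline = 2^(stats::rnorm(n, 0, config$te_sdlog2) +
                       ifelse(has_tr_uorf, config$uorf_te_shift_log2, 0)),
    rna_rhythmic = rna_rhythmic,
    rna_amp = ifelse(rna_rhythmic, ramp(n), 1),
    rna_phase = ifelse(rna_rhythmic, rph(n), 0),
    te_rhythmic = te_rhythmic,
    te_amp = ifelse(te_rhythmic, ramp(n), 1),
    te_phase = ifelse(te_rhythmic, rph(n), 0),
    dispersion = config$dispersion,
    frame_bias = config$frame_bias,
    stringsAsFactors = FALSE)

  n_codons <- st$cds_len %/% 3L
  paused <- which(stats::runif(n) < config$pause_fraction & n_codons >= 20L)
  pauses <- data.frame(transcript_id = character(0), codon_index = integer(0),
                       multiplier = numeric(0))
  if (length(paused) > 0) {
    pauses <- data.frame(
      transcript_id = st$transcript_id[paused],
      codon_index = vapply(paused, function(g)
        sample(5:(n_codons[g] - 6L), 1L), 0L),
      multiplier = stats::runif(length(paused), config$pause_mult_range[1],
                                config$pause_mult_range[2]),
      stringsAsFactors = FALSE)
  }
  structure(list(genes = genes, uorfs = uorfs, pauses = pauses,
                 config = config),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  g <- x$genes
  cat(sprintf("ground_truth: %d genes\n", nrow(g)))
  cat(sprintf("  rhythmic mRNA: %d | rhythmic TE: %d | both: %d\n",
              sum(g$rna_rhythmic & !g$te_rhythmic),
              sum(g$te_rhythmic & !g$rna_rhythmic),
              sum(g$rna_rhythmic & g$te_rhythmic)))
  cat(sprintf("  translated uORFs: %d of %d annotated; pause sites: %d\n",
              sum(x$uorfs$translated), nrow(x$uorfs), nrow(x$pauses)))
  invisible(x)
}

#' Expected per-nt RNA rate at time t
#' @param truth a `"ground_truth"`.
#' @param t ZT hours (scalar).
#' @return Named numeric vector (per transcript).
#' @export
expected_rna_rate <- function(truth, t) {
  g <- truth$genes
  r <- g$rna_baseline *
    ifelse(g$rna_rhythmic, rhythm_factor(t, g$rna_amp, g$rna_phase), 1)
  stats::setNames(r, g$transcript_id)
}

#' Expected per-nt footprint (RPF) rate at time t
#' @inheritParams expected_rna_rate
#' @return Named numeric vector (per transcript).
#' @export
expected_rpf_rate <- function(truth, t) {
  g <- truth$genes
  te <- g$te_baseline *
    ifelse(g$te_rhythmic, rhythm_factor(t, g$te_amp, g$te_phase), 1)
  expected_rna_rate(truth, t) * te
}

#' Write ground truth as TSV files
#' @param truth a `"ground_truth"`.
#' @param genes_tsv,uorfs_tsv,pauses_tsv output paths (`NULL` to skip).
#' @return Invisibly, the vector of paths written.
#' @export
write_ground_truth <- function(truth, genes_tsv = NULL, uorfs_tsv = NULL,
                               pauses_tsv = NULL) {
  written <- character(0)
  wt <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  if (!is.null(genes_tsv)) written <- c(written, wt(truth$genes, genes_tsv))
  if (!is.null(uorfs_tsv)) written <- c(written, wt(truth$uorfs, uorfs_tsv))
  if (!is.null(pauses_tsv)) written <- c(written, wt(truth$pauses, pauses_tsv))
  invisible(written)
}
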