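#' Configuration of a full pipeline run
#'
#' Collects the seed, design, thresholds and paths for [run_pipeline()]. In
#' simulation mode (`simulate = TRUE`) the inputs are generated; otherwise
#' `structure_tsv`, `sample_sheet_tsv` and `alignments_dir` (one
#' `<sample_id>.tsv` per library) must exist, and `fasta` is needed for uORF
#' sequence scanning.
#'
#' @param out_dir output directory.
#' @param seed integer seed governing every random draw of the run.
#' @param simulate generate inputs with the synthetic-data module?
#' @param n_genes,depth simulated genes and reads per library.
#' @param timepoints,replicates circadian design.
#' @param generator a [generator_config()].
#' @param rhythm a [rhythm_config()].
#' @param amp_cutoff,fdr rhythm-detection thresholds.
#' @param min_uorf_reads,min_frame_frac,pause_fold feature-calling
#'   thresholds.
#' @param rpf_length_bounds,rna_length_bounds inclusive read-length filters.
#' @param utr5_leak simulated fraction of footprints in the 5'UTR.
#' @param rpkm_floor RNA-RPKM floor used for the TE gene set.
#' @param top_n_pca genes used for the sample PCA.
#' @param fasta,structure_tsv,sample_sheet_tsv,alignments_dir input paths
#'   when `simulate = FALSE`.
#' @return List of class `"run_config"`.
#' @export
pipeline_config <- function(out_dir, seed = 1, simulate = TRUE,
                            n_genes = 200, depth = 5e4,
                            timepoints = seq(0, 22, by = 2), replicates = 2,
                            generator = generator_config(),
                            rhythm = rhythm_config(),
                            amp_cutoff = 1.5, fdr = 0.05,
                            min_uorf_reads = 10, min_frame_frac = 0.5,
                            pause_fold = 5,
                            rpf_length_bounds = c(26, 35),
                            rna_length_bounds = c(21, 60),
                            utr5_leak = 0.06, rpkm_floor = 5,
                            top_n_pca = 4000,
                            fasta = NULL, structure_tsv = NULL,
                            sample_sheet_tsv = NULL, alignments_dir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

.config_as_yaml <- function(config) {
  plain <- lapply(unclass(config), function(x)
    if (is.list(x)) unclass(x) else x)
  yaml::as.yaml(plain)
}

.wtsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.cds_counts <- function(alignments, sheet, structure, config) {
  m <- matrix(0L, nrow(structure), nrow(sheet),
              dimnames = list(structure$transcript_id, sheet$sample_id))
  utr5 <- matrix(0L, nrow(structure), nrow(sheet),
                 dimnames = dimnames(m))
  for (i in seq_len(nrow(sheet))) {
    aln <- alignments[[sheet$sample_id[i]]]
    if (sheet$assay[i] == "RPF") {
      aln <- filter_by_length(aln, config$rpf_length_bounds[1],
                              config$rpf_length_bounds[2])
      off <- default_offset_table()
    } else {
      aln <- filter_by_length(aln, config$rna_length_bounds[1],
                              config$rna_length_bounds[2])
      off <- rna_offset_table(config$rna_length_bounds[1],
                              config$rna_length_bounds[2])
    }
    rc <- count_by_region(assign_asite(aln, structure, off)$asites,
                          structure)
    m[, i] <- rc$cds
    utr5[, i] <- rc$utr5
  }
  list(cds = m, utr5 = utr5)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order — `simulate` (or input loading),
#' `qc`, `quantify`, `features`, `rhythms`, `report` — writing every result
#' as TSV/BED/FASTA into `config$out_dir`, ending with a `manifest.tsv` of
#' md5 checksums and a verbatim `config.yaml` echo. Deterministic given the
#' seed; partially written outputs are removed if a stage fails.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of stages to run (dependencies are re-run as
#'   needed within one call; the default runs everything).
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "qc", "quantify", "features",
                                    "rhythms", "report")) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  created <- !dir.exists(out)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "alignments"), showWarnings = FALSE)
  on_fail <- function(e) {
    if (created) unlink(out, recursive = TRUE)
    stop("pipeline failed (outputs removed): ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch(.run_pipeline_impl(config, stages, out), error = on_fail)
  invisible(out)
}

.run_pipeline_impl <- function(config, stages, out) {
  message("riboclock pipeline -> ", out)
  writeLines(.config_as_yaml(config), file.path(out, "config.yaml"))
  sheet <- sample_sheet(config$timepoints, seq_len(config$replicates))

  # ---- inputs: simulate or load ----
  if (config$simulate) {
    message("[simulate] ", config$n_genes, " genes, depth ", config$depth)
    tx <- generate_transcriptome(config$n_genes, config$seed,
                                 config$generator)
    truth <- generate_ground_truth(tx, config$rhythm, config$seed + 1L)
    alignments <- simulate_experiment(tx, truth, sheet, config$depth,
                                      config$seed + 2L,
                                      utr5_leak = config$utr5_leak)
    write_transcriptome(tx, fasta = file.path(out, "transcripts.fa"),
                        structure_tsv = file.path(out, "transcript_structure.tsv"),
                        uorf_bed = file.path(out, "uorfs_annotated.bed"))
    write_ground_truth(truth,
                       genes_tsv = file.path(out, "truth_genes.tsv"),
                       uorfs_tsv = file.path(out, "truth_uorfs.tsv"),
                       pauses_tsv = file.path(out, "truth_pauses.tsv"))
    .wtsv(sheet, file.path(out, "sample_sheet.tsv"))
    for (sid in names(alignments))
      write_alignments(alignments[[sid]],
                       file.path(out, "alignments", paste0(sid, ".tsv")), sid)
    structure_df <- transcript_structure(tx)
    utr5_seq <- vapply(tx, function(t) substr(t$seq, 1, t$utr5_len), "")
  } else {
    for (p in c(config$structure_tsv, config$sample_sheet_tsv))
      if (is.null(p) || !file.exists(p))
        stop("missing input file: ", if (is.null(p)) "(unset path)" else p)
    structure_df <- read_transcript_structure(config$structure_tsv)
    sheet <- utils::read.delim(config$sample_sheet_tsv,
                               stringsAsFactors = FALSE)
    alignments <- lapply(sheet$sample_id, function(sid) {
      p <- file.path(config$alignments_dir, paste0(sid, ".tsv"))
      if (!file.exists(p)) stop("missing input file: ", p)
      read_alignments(p)
    })
    names(alignments) <- sheet$sample_id
    utr5_seq <- NULL
    if (!is.null(config$fasta)) {
      if (!file.exists(config$fasta))
        stop("missing input file: ", config$fasta)
      seqs <- Biostrings::readDNAStringSet(config$fasta)
      i <- match(structure_df$transcript_id, names(seqs))
      utr5_seq <- substr(as.character(seqs)[i], 1, structure_df$utr5_len)
      names(utr5_seq) <- structure_df$transcript_id
    }
  }
  is_rpf <- sheet$assay == "RPF"
  rpf_pooled <- do.call(rbind, alignments[sheet$sample_id[is_rpf]])
  rna_pooled <- do.call(rbind, alignments[sheet$sample_id[!is_rpf]])

  # ---- qc ----
  if ("qc" %in% stages) {
    message("[qc]")
    qr <- footprint_qc(filter_by_length(rpf_pooled,
                                        config$rpf_length_bounds[1],
                                        config$rpf_length_bounds[2]),
                       structure_df)
    qn <- footprint_qc(filter_by_length(rna_pooled,
                                        config$rna_length_bounds[1],
                                        config$rna_length_bounds[2]),
                       structure_df,
                       offsets = rna_offset_table(config$rna_length_bounds[1],
                                                  config$rna_length_bounds[2]))
    qc <- data.frame(
      metric = c("rpf_reads", "rna_reads",
                 "rpf_share_utr5", "rpf_share_cds", "rpf_share_utr3",
                 "rpf_enrich_utr5", "rpf_enrich_cds", "rpf_enrich_utr3",
                 "rna_enrich_cds",
                 "rpf_frame0", "rpf_frame1", "rpf_frame2",
                 "rna_frame0", "rna_frame1", "rna_frame2",
                 "rpf_periodicity", "rna_periodicity"),
      value = c(nrow(rpf_pooled), nrow(rna_pooled),
                unname(qr$region_counts / sum(qr$region_counts)),
                unname(qr$region_enrichment),
                unname(qn$region_enrichment["cds"]),
                qr$frame$f, qn$frame$f,
                qr$periodicity, qn$periodicity))
    .wtsv(qc, file.path(out, "qc_summary.tsv"))
    .wtsv(as.data.frame(table(length = rpf_pooled$length)),
          file.path(out, "qc_rpf_length_histogram.tsv"))
  }

  # ---- quantify ----
  cm <- .cds_counts(alignments, sheet, structure_df, config)
  norm <- list()
  rpkm_m <- matrix(NA_real_, nrow(structure_df), nrow(sheet),
                   dimnames = dimnames(cm$cds))
  for (assay in c("RPF", "RNA")) {
    cols <- sheet$sample_id[sheet$assay == assay]
    uq <- upper_quartile_normalize(cm$cds[, cols, drop = FALSE])
    norm[[assay]] <- uq
    lib <- colSums(uq$normalized)
    for (sid in cols)
      rpkm_m[, sid] <- rpkm(uq$normalized[, sid], structure_df$cds_len,
                            lib[sid])
  }
  rpf_cols <- sheet$sample_id[is_rpf]
  rna_cols <- sheet$sample_id[!is_rpf]
  key_rpf <- paste(sheet$zt[is_rpf], sheet$replicate[is_rpf])
  key_rna <- paste(sheet$zt[!is_rpf], sheet$replicate[!is_rpf])
  rna_match <- rna_cols[match(key_rpf, key_rna)]
  te <- translation_efficiency(rpkm_m[, rpf_cols, drop = FALSE],
                               rpkm_m[, rna_match, drop = FALSE],
                               floor = 0)
  colnames(te) <- sub("^RPF", "TE", rpf_cols)
  gene_te <- rowMeans(te, na.rm = TRUE)
  expressed <- rowMeans(rpkm_m[, rna_match, drop = FALSE]) > config$rpkm_floor
  if ("quantify" %in% stages) {
    message("[quantify]")
    wm <- function(m, f) .wtsv(data.frame(transcript_id = rownames(m),
                                          m, check.names = FALSE), f)
    wm(cm$cds, file.path(out, "cds_counts.tsv"))
    wm(round(rpkm_m, 4), file.path(out, "rpkm.tsv"))
    wm(round(te, 4), file.path(out, "te.tsv"))
    .wtsv(data.frame(sample_id = c(rpf_cols, rna_cols),
                     size_factor = c(norm$RPF$size_factors,
                                     norm$RNA$size_factors)),
          file.path(out, "size_factors.tsv"))
    defined <- gene_te[is.finite(gene_te) & gene_te > 0 & expressed]
    tr <- if (length(defined) >= 40) te_range(defined) else NA_real_
    pca <- pca_samples(rpkm_m, top_n = min(config$top_n_pca,
                                           nrow(rpkm_m)))
    .wtsv(data.frame(sample_id = rownames(pca$coordinates),
                     round(pca$coordinates[, seq_len(min(4, ncol(pca$coordinates)))], 4)),
          file.path(out, "pca_coordinates.tsv"))
    .wtsv(data.frame(component = seq_along(pca$var_explained),
                     var_explained = round(pca$var_explained, 4)),
          file.path(out, "pca_variance.tsv"))
    .wtsv(data.frame(metric = "te_fold_range_95", value = tr),
          file.path(out, "te_range.tsv"))
  }

  # ---- features ----
  if ("features" %in% stages) {
    message("[features]")
    aa <- assign_asite(filter_by_length(rpf_pooled,
                                        config$rpf_length_bounds[1],
                                        config$rpf_length_bounds[2]),
                       structure_df)$asites
    by_tx <- split(aa$pos, aa$transcript_id)
    calls <- NULL
    if (!is.null(utr5_seq)) {
      for (tid in structure_df$transcript_id) {
        cand <- find_candidate_uorfs(utr5_seq[[tid]])
        if (nrow(cand) == 0) next
        pos <- by_tx[[tid]]
        for (k in seq_len(nrow(cand))) {
          cl <- call_translated(cand[k, ], if (is.null(pos)) integer(0) else pos,
                                min_reads = config$min_uorf_reads,
                                min_frame_frac = config$min_frame_frac)
          calls <- rbind(calls, data.frame(
            transcript_id = tid, start = cl$start, end = cl$end,
            n_asites = cl$n_asites,
            f0 = cl$frame_fracs[1], f1 = cl$frame_fracs[2],
            f2 = cl$frame_fracs[3],
            p_value = cl$p_value, translated = cl$translated))
        }
      }
    }
    if (is.null(calls))
      calls <- data.frame(transcript_id = character(0), start = integer(0),
                          end = integer(0), n_asites = integer(0),
                          f0 = numeric(0), f1 = numeric(0), f2 = numeric(0),
                          p_value = numeric(0), translated = logical(0))
    .wtsv(calls, file.path(out, "uorf_calls.tsv"))
    tr_calls <- calls[calls$translated, , drop = FALSE]
    utils::write.table(tr_calls[, c("transcript_id", "start", "end")],
                       file.path(out, "uorfs_translated.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)

    pauses <- NULL
    for (tid in structure_df$transcript_id) {
      i <- match(tid, structure_df$transcript_id)
      pos <- by_tx[[tid]]
      if (is.null(pos)) next
      u5 <- structure_df$utr5_len[i]
      ncod <- structure_df$cds_len[i] %/% 3L
      inc <- pos >= u5 & pos < u5 + structure_df$cds_len[i]
      if (!any(inc) || ncod < 10) next
      cc <- tabulate((pos[inc] - u5) %/% 3L + 1L, ncod)
      ps <- suppressWarnings(detect_pause_sites(cc, config$pause_fold))
      if (nrow(ps) > 0)
        pauses <- rbind(pauses, cbind(transcript_id = tid, ps))
    }
    if (is.null(pauses))
      pauses <- data.frame(transcript_id = character(0),
                           codon_index = integer(0), score = numeric(0))
    .wtsv(pauses, file.path(out, "pause_sites.tsv"))

    uorf_genes <- unique(tr_calls$transcript_id)
    grp <- gene_te[rownames(te) %in% uorf_genes & expressed]
    ref <- gene_te[!(rownames(te) %in% uorf_genes) & expressed]
    grp <- grp[is.finite(grp) & grp > 0]; ref <- ref[is.finite(ref) & ref > 0]
    shift <- if (length(grp) >= 3 && length(ref) >= 3)
      suppressMessages(location_shift(grp, ref)) else
      list(delta_log2 = NA, percent_change = NA, p_value = NA)
    .wtsv(data.frame(comparison = "translated_uORF_vs_rest",
                     delta_log2 = shift$delta_log2,
                     percent_change = shift$percent_change,
                     p_value = shift$p_value),
          file.path(out, "uorf_te_shift.tsv"))
  }

  # ---- rhythms ----
  if ("rhythms" %in% stages) {
    message("[rhythms]")
    fits_rpf <- detect_rhythmic(rpkm_m[, rpf_cols, drop = FALSE],
                                sheet$zt[is_rpf],
                                amp_cutoff = config$amp_cutoff,
                                fdr = config$fdr)
    fits_rna <- detect_rhythmic(rpkm_m[, rna_cols, drop = FALSE],
                                sheet$zt[!is_rpf],
                                amp_cutoff = config$amp_cutoff,
                                fdr = config$fdr)
    cls <- classify_genes(fits_rna, fits_rpf)
    dte <- differential_te(cm$cds[, rpf_cols, drop = FALSE],
                           cm$cds[, rna_match, drop = FALSE],
                           sheet$zt[is_rpf])
    hc <- high_confidence_set(cls, dte, q_cutoff = config$fdr)
    .wtsv(cbind(assay = "RNA", fits_rna), file.path(out, "rhythms_rna.tsv"))
    .wtsv(cbind(assay = "RPF", fits_rpf), file.path(out, "rhythms_rpf.tsv"))
    .wtsv(cls$assignments, file.path(out, "categories.tsv"))
    .wtsv(data.frame(category = names(cls$counts),
                     count = as.integer(cls$counts)),
          file.path(out, "category_counts.tsv"))
    .wtsv(dte, file.path(out, "diff_te.tsv"))
    writeLines(hc, file.path(out, "high_confidence_genes.txt"))
    ph_rpf <- fits_rpf$phase_h[fits_rpf$rhythmic]
    ph_rna <- fits_rna$phase_h[fits_rna$rhythmic]
    circ <- data.frame(test = character(0), statistic = numeric(0),
                       p_value = numeric(0), n = integer(0))
    if (length(ph_rpf) >= 2) {
      rt <- rayleigh_test(ph_rpf)
      circ <- rbind(circ, data.frame(test = "rayleigh_rpf_phases",
                                     statistic = rt$statistic,
                                     p_value = rt$p_value, n = rt$n))
    }
    if (length(ph_rpf) >= 2 && length(ph_rna) >= 2) {
      ww <- suppressWarnings(watson_wheeler(ph_rpf, ph_rna))
      circ <- rbind(circ, data.frame(test = "watson_wheeler_rpf_vs_rna",
                                     statistic = ww$statistic,
                                     p_value = ww$p_value,
                                     n = ww$n1 + ww$n2))
    }
    .wtsv(circ, file.path(out, "circular_stats.tsv"))
    .wtsv(data.frame(bin_start_h = names(phase_histogram(ph_rpf %% 24)),
                     rpf = as.integer(phase_histogram(ph_rpf %% 24)),
                     rna = as.integer(phase_histogram(ph_rna %% 24))),
          file.path(out, "phase_histograms.tsv"))

    # relative daily biosynthesis of the most translated genes
    zt_u <- sort(unique(sheet$zt[is_rpf]))
    rpf_tp <- sapply(zt_u, function(z)
      rowMeans(rpkm_m[, rpf_cols[sheet$zt[is_rpf] == z], drop = FALSE]))
    topg <- order(rowMeans(rpf_tp), decreasing = TRUE)[seq_len(min(10, nrow(rpf_tp)))]
    ratios <- daily_biosynthesis_ratio(rpf_tp[topg, , drop = FALSE], zt_u,
                                       rownames(rpf_tp)[topg[1]])
    .wtsv(data.frame(transcript_id = names(ratios),
                     biosynthesis_ratio = round(ratios, 4)),
          file.path(out, "biosynthesis_ratios.tsv"))
  }

  if ("report" %in% stages) make_report(out)

  files <- setdiff(list.files(out, recursive = TRUE), "manifest.tsv")
  md5 <- tools::md5sum(file.path(out, files))
  .wtsv(data.frame(file = files, md5 = unname(md5)),
        file.path(out, "manifest.tsv"))
  invisible(out)
}

#' Assemble a human-readable run report
#'
#' Summarises a pipeline output directory into `report.txt`: QC metrics,
#' rhythmicity category counts, the high-confidence gene count, circular
#' statistics, the TE fold-range, the biosynthesis-ratio table, and a
#' verbatim echo of the run configuration. Every number is read back from a
#' TSV cell of the run.
#'
#' @param out_dir a [run_pipeline()] output directory.
#' @return Invisibly, the path of the report.
#' @export
make_report <- function(out_dir) {
  rd <- function(f) {
    p <- file.path(out_dir, f)
    if (file.exists(p)) utils::read.delim(p, stringsAsFactors = FALSE)
    else NULL
  }
  lines <- c("riboclock run report", strrep("=", 20), "")
  qc <- rd("qc_summary.tsv")
  if (!is.null(qc)) {
    lines <- c(lines, "QC (qc_summary.tsv):",
               sprintf("  %-18s %s", qc$metric, signif(qc$value, 4)), "")
  }
  tr <- rd("te_range.tsv")
  if (!is.null(tr))
    lines <- c(lines, sprintf("95%% TE fold-range (te_range.tsv): %s",
                              signif(tr$value, 4)), "")
  cc <- rd("category_counts.tsv")
  if (!is.null(cc)) {
    lines <- c(lines, "Rhythmicity categories (category_counts.tsv):",
               sprintf("  %-14s %d", cc$category, cc$count), "")
  }
  hc <- file.path(out_dir, "high_confidence_genes.txt")
  if (file.exists(hc))
    lines <- c(lines, sprintf(
      "High-confidence rhythmic-TE genes (high_confidence_genes.txt): %d",
      length(readLines(hc))), "")
  circ <- rd("circular_stats.tsv")
  if (!is.null(circ) && nrow(circ) > 0)
    lines <- c(lines, "Circular statistics (circular_stats.tsv):",
               sprintf("  %-26s stat=%.4g p=%.3g n=%d", circ$test,
                       circ$statistic, circ$p_value, circ$n), "")
  us <- rd("uorf_te_shift.tsv")
  if (!is.null(us))
    lines <- c(lines, sprintf(
      "TE location shift, translated-uORF genes (uorf_te_shift.tsv): delta_log2=%s (%s%%), p=%s",
      signif(us$delta_log2, 3), signif(us$percent_change, 3),
      signif(us$p_value, 3)), "")
  br <- rd("biosynthesis_ratios.tsv")
  if (!is.null(br)) {
    lines <- c(lines, "Relative daily biosynthesis (biosynthesis_ratios.tsv):",
               sprintf("  %-10s %.3f", br$transcript_id,
                       br$biosynthesis_ratio), "")
  }
  cfgp <- file.path(out_dir, "config.yaml")
  if (file.exists(cfgp))
    lines <- c(lines, "Configuration (config.yaml):",
               paste0("  ", readLines(cfgp)))
  p <- file.path(out_dir, "report.txt")
  writeLines(lines, p)
  invisible(p)
}
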