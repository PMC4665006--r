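# riboclock

Circadian translatome analysis from ribosome profiling, in R.

Around-the-clock ribosome profiling pairs footprint libraries (RPF-seq,
the ~29–30 nt mRNA fragments protected by translating ribosomes) with
matched RNA-seq over a 24-h design — here 12 timepoints (ZT0–ZT22, 2-h
spacing) × 2 replicates. From those two read layers the analysis resolves
*what is transcribed* from *what is translated*: per-gene translation
efficiency (TE = RPF-RPKM / RNA-RPKM over the CDS), daily rhythms in mRNA
abundance and in ribosome occupancy, the genes whose translation oscillates
while their mRNA stays flat, and the 5′UTR features (translated upstream
open reading frames, pause sites) that shape the TE landscape.

riboclock implements the full path in transcript coordinates:

* **Synthetic data with ground truth** — `generate_transcriptome()`,
  `generate_ground_truth()`, `simulate_sample()` / `simulate_counts()`
  produce transcriptomes, expression programs (rhythmic-mRNA /
  rhythmic-TE gene sets, negative binomial noise, frame bias, 5′UTR
  leakage, uORF loading, pause sites) and alignment tables, so every
  downstream stage is testable without sequencing data.
* **Footprint processing** — A-site assignment from a length-dependent
  offset table, read-length filtering, region counting (5′UTR/CDS/3′UTR),
  observed/expected region enrichment, reading-frame fractions, metagene
  profiles and a 3-nt periodicity score (`footprint_qc()`).
* **Quantification** — upper-quartile normalisation, RPKM, TE with
  expression floors, TE fold-range with a permutation test, TE–length
  regressions, Wilcoxon location shifts, sample PCA, daily
  protein-biosynthesis ratios.
* **Translational features** — AUG-initiated uORF detection
  (`find_candidate_uorfs()`), translated-uORF calling from footprint frame
  preference (`call_translated()`), Tukey-trimean pause-site detection,
  Fisher enrichment tests.
* **Rhythm analysis** — a 24-h cosinor model on the log2 scale
  (`harmonic_fit()`, a classed S3 object with `print`/`coef`/`predict`/
  `plot` methods): per-gene fold-amplitude `2^(2√(a²+b²))`, peak phase,
  F-test p-value; genome-wide detection with BH correction and a
  1.5-fold amplitude cutoff (`detect_rhythmic()`); Venn classification
  (`classify_genes()`); a moderated residual-harmonic differential-TE test
  (`differential_te()`); Rayleigh and Watson–Wheeler circular statistics
  for peak-phase distributions.
* **Pipeline** — `run_pipeline()` ties the stages into a deterministic,
  manifest-checksummed output directory; `make_report()` renders a
  human-readable summary. A thin CLI wrapper lives at
  `inst/scripts/riboclock-cli.R`.

## Worked example

```r
library(riboclock)

tx    <- generate_transcriptome(300, seed = 1)
truth <- generate_ground_truth(tx, rhythm_config(), seed = 2)
truth
#> ground_truth: 300 genes
#>   rhythmic mRNA: 30 | rhythmic TE: 15 | both: 0
#>   translated uORFs: 107 of 198 annotated; pause sites: 35

# one footprint library at ZT12, then the standard QC block
rpf <- simulate_sample(tx, truth, zt = 12, assay = "RPF", depth = 2e5, seed = 3)
st  <- transcript_structure(tx)
qc  <- footprint_qc(filter_by_length(rpf, 26, 35), st)
round(qc$region_enrichment, 2)   # read share / share expected from lengths
#> utr5  cds utr3
#> 0.64 1.42 0.00
round(qc$frame$f, 3)             # A-site frame fractions in the CDS
#> [1] 0.901 0.050 0.049
round(qc$periodicity, 3)         # period-3 share of metagene spectral power
#> [1] 0.976
```

Footprints concentrate in the CDS (1.42× over length expectation, with
~6% of reads leaking into 5′UTRs), sit in the annotated frame 90% of the
time, and give the 3-nt metagene periodicity that RNA-seq reads lack —
the three hallmarks of genuine ribosome footprints.

```r
# count-level study: fit the cosinor to one truly rhythmic gene
sheet  <- sample_sheet()                       # 12 ZT x 2 reps x 2 assays
counts <- simulate_counts(tx, truth, sheet, depth = 2e5, seed = 4)
rpf_cols <- sheet$sample_id[sheet$assay == "RPF"]
uq    <- upper_quartile_normalize(counts[, rpf_cols])
rpkms <- rpkm(uq$normalized, st$cds_len, sum(uq$normalized[, 1]))
fit <- harmonic_fit(rpkms[which(truth$genes$rna_rhythmic)[1], ],
                    sheet$zt[sheet$assay == "RPF"])
fit
#> harmonic fit (period 24 h, n = 24)
#>   mesor (log2) 12.070 | fold-amplitude 2.818 | peak phase ZT2.73 | p = 9.5e-08
truth$genes[truth$genes$rna_rhythmic, c("rna_amp", "rna_phase")][1, ]
#>     rna_amp rna_phase
#> 31 2.808249  2.969262
```

The fitted peak-to-trough fold-amplitude (2.82) and peak phase (ZT2.7)
recover the gene's ground truth (2.81, ZT3.0) from 24 noisy samples.
Genome-wide, `detect_rhythmic()` applies the same fit per gene with BH
correction, `classify_genes()` partitions genes into
both/mRNA-only/footprints-only/neither, and `high_confidence_set()`
intersects the footprints-only class with the significant
`differential_te()` genes.

A full, reproducible run of all stages:

```r
run_pipeline(pipeline_config(out_dir = "demo", seed = 1,
                             n_genes = 200, depth = 5e4))
# demo/ now holds FASTA + TSV/BED outputs for every stage, report.txt,
# config.yaml and manifest.tsv (md5 per file; byte-identical given a seed)
```

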