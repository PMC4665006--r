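---
title: "riboclock: models and methods for the circadian translatome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{riboclock: models and methods for the circadian translatome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboclock)
```

## The problem

Ribosome profiling sequences the ~29–30 nt mRNA fragments protected by
translating ribosomes (ribosome-protected fragments, RPFs). Paired with
matched RNA-seq, it resolves two layers of gene expression: how much mRNA a
gene has, and how densely that mRNA is covered by ribosomes. The ratio of
footprint density to mRNA density over a coding sequence — the translation
efficiency (TE) — is a proxy for protein output per transcript. In a
circadian design (here, 12 timepoints at 2-h spacing × 2 replicates × 2
assays), the questions become temporal: which genes oscillate in mRNA, which
in ribosome occupancy, which show daily TE rhythms despite flat mRNA, and
what sequence features (upstream open reading frames, pause sites) shape the
TE landscape.

riboclock implements this analysis end to end in transcript coordinates
(0-based, half-open, one transcript per gene), together with a synthetic-data
generator whose ground truth makes every stage testable without sequencing
data.

## Footprint processing

A footprint's A-site (the codon being decoded) sits at a length-dependent
offset from the read 5′ end. The default table — 14 nt for 26–28 nt reads,
15 nt for 29–31 nt, 16 nt for 32–35 nt — is standard practice for mammalian
80S footprints; it is a plain data frame argument everywhere, never
hard-coded, because offset rules are protocol-dependent. Reads whose length
has no table entry are dropped (not guessed) to avoid contaminating frame
statistics, and drops are counted. The A-site position alone decides region
membership (5′UTR / CDS / 3′UTR) under the half-open convention: position
`utr5_len` is the first CDS base.

QC statistics follow from the A-sites: region occupancy against the share
expected from feature lengths alone; reading-frame fractions `(pos − anchor)
mod 3`; and a metagene profile over the first/last 200 nt of CDSs longer
than 400 nt, each transcript normalised by its own mean coverage before
averaging so highly expressed genes do not dominate. The periodicity score
is the fraction of the profile's (mean-removed) discrete-spectrum power in
the period-3 bin and its conjugate, after trimming the window to a multiple
of 3 so the bin is exact: 1 for an equal-height period-3 impulse train, 0
for a constant profile, and monotone in frame bias in between. With varying
spike heights the codon-to-codon variance leaks power into other
frequencies, so simulated libraries with perfect frame bias score slightly
below 1 — the sharper invariant, which the tests use, is that off-frame
positions are exactly empty.

## Quantification

CDS counts are normalised by the upper-quartile method: each sample's size
factor is the 75th percentile of its nonzero gene counts, rescaled to
geometric mean 1. Quantiles throughout the package interpolate order
statistics at positions `p(n+1)` (type 6); under this rule the 75th
percentile of {1, 3, 5, 7} is 6.5, and the rule is asserted in the tests so
it cannot drift silently. RPKM is computed on the normalised counts
(`count / (kb) / (millions of normalised library reads)`) and TE as
RPF-RPKM / RNA-RPKM, defined only where the RNA signal exceeds a floor
(default: any positive RPKM; figure-style analyses use RPKM > 5). Undefined
TEs are `NA`, never zero.

The spread of the TE distribution is summarised as the fold-range covering
the central 95% (`q(0.975)/q(0.025)`), with a label-shuffling permutation
test for comparing two spreads. Associations between TE and transcript
features use ordinary least squares of log2 TE on log10 length, and group
shifts are reported as `median(log2 group) − median(log2 reference)` with a
two-sided Wilcoxon rank-sum p-value; a shift of −0.525 corresponds to
`100 × (1 − 2^−0.525)` ≈ 30.5% TE reduction. Sample structure is checked by
PCA of the 4000 top-expressed genes on gene-centred `log2(x + 1)` values
(pseudocount 1 everywhere a log of counts is taken, to avoid −∞). Because
footprint counts integrate translation over the CDS, the trapezoid mean of
a gene's RPF-RPKM over the wrapped 24-h cycle, relative to a reference
gene, reads out relative daily protein biosynthesis.

Two definitional choices were genuinely open and are recorded here: the
"top-ranked" genes for PCA are ranked by mean expression, and "modified
RPKM" is interpreted as RPKM computed on upper-quartile-normalised counts.

## uORFs and pause sites

Candidate uORFs are maximal AUG-to-stop open reading frames contained
entirely in the 5′UTR (CDS-overlapping uORFs are excluded as structurally
ambiguous); nested AUGs sharing a stop are collapsed to the 5′-most start,
and the minimum span is 6 nt. A 192-nt uORF therefore codes for
192/3 − 1 = 63 amino acids. A candidate is called *translated* when it
carries ≥ 10 A-sites, at least half of them in the uORF's own frame
(anchored at the uORF start), and a one-sided binomial test rejects
f0 = 1/3 at 0.05. All three thresholds are arguments; the binomial test
makes the frame-preference criterion scale with coverage rather than act as
a bare fraction cutoff.

Pause sites are codons whose footprint count reaches 5× (configurable) the
Tukey trimean `(H1 + 2·median + H2)/4` of the gene's per-codon counts. The
hinge-based trimean is deliberately used here instead of the package
quantile rule: on sparsely covered CDSs it is immune to a single extreme
codon (`trimean(c(0,0,0,0,100)) = 0`), which is the property that makes it
preferable to the mean — and less stochastic than the median — as a
coverage baseline. Genes whose trimean is 0 cannot be scored and are
skipped with a warning.

## Rhythm analysis

The rhythm model is a single 24-h harmonic (cosinor) on the log2 scale:
`log2(y + 1) ~ 1 + cos(2πt/24) + sin(2πt/24)`, the minimal model whose
parameters map onto mesor, peak-to-trough fold-amplitude and peak phase.
The fold-amplitude is read from the fitted curve, `2^(2√(a² + b²))`, not
from the raw max/min — noise-robust and consistent with a fitted-amplitude
cutoff — and the phase is the fitted-curve maximum in `[0, 24)` h. The
p-value is the F-test of the two harmonic terms against the intercept-only
model; replicates are pooled into a single 24-point fit rather than
averaged, keeping the degrees of freedom honest. `harmonic_fit()` returns a
classed object with `print`, `coef`, `predict`, `fitted`, `residuals` and
`plot` methods. On noiseless data (pseudocount 0) the fit recovers
amplitude and phase to better than 1e-6; with the default pseudocount, very
low-expressed genes have their fitted amplitudes damped — a deliberate
conservatism.

Genome-wide, `detect_rhythmic()` applies Benjamini–Hochberg correction
within each assay and flags genes with fold-amplitude > 1.5 at q < 0.05
(both cutoffs are arguments). Classification into mRNA-and-footprints
rhythmic / mRNA-only / footprints-only / neither follows directly, and the
counts obey the inclusion–exclusion identities by construction.

### Differential TE

Time-dependent TE is tested without forming noisy per-sample TE ratios:
per sample, a robust linear trend (`MASS::rlm`) of `log2(RPF + 1)` on
`log2(RNA + 1)` across genes absorbs the genome-wide occupancy/abundance
relationship, and each gene's standardised residual measures its relative
ribosome occupancy in that sample. Per gene, the harmonic time terms are
F-tested on the 24-point residual series. Per-gene residual variances are
shrunk towards the genome-wide variance distribution by empirical Bayes
(`limma::squeezeVar`); with 24 points and 21 residual degrees of freedom
the unmoderated F-test is noticeably underpowered for two-fold TE
oscillations at realistic dispersion, and moderation recovers that power
without inflating the null (the tests check both calibration and
recovery). The high-confidence rhythmically-translated set is then: genes
classified footprints-only rhythmic *and* differential-TE q < 0.05.

### Circular statistics

Peak phases are angles. Uniformity of a phase set is tested with the
Rayleigh statistic `R = |Σe^{iθ}|/n` and its standard large-sample
p-approximation `p = exp(√(1 + 4n + 4(n² − (nR)²)) − (1 + 2n))`, which the
tests validate against a 1e5-draw Monte-Carlo null (factor-2 agreement for
p in [1e-3, 0.5]). Homogeneity of two phase sets uses the Watson–Wheeler
rank test: combined circular ranks mapped to uniform scores
`β = 2πr/N` (ties by average rank), `W = 2Σ_g (C_g² + S_g²)/n_g`, p from
χ² with 2 df; the statistic is checked against a brute-force transcription
of the definition and the p-value against a permutation null in the regime
the permutation can resolve. Below ~10 angles per group the χ²
approximation is unreliable and the function warns.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions the rest of the package is validated under:

* **Design**: 12 timepoints (ZT0–ZT22) × 2 replicates × paired RPF/RNA
  libraries.
* **Transcripts**: single isoform per gene; log-normal 5′UTR / CDS / 3′UTR
  lengths (medians ≈ 150 nt / 400 codons / 400 nt); CDS starts AUG, ends
  with a stop, no internal in-frame stop; 35% of genes carry 1–3
  AUG-initiated uORFs confined to the 5′UTR. Annotated uORF starts follow
  the maximal-ORF convention (5′-most AUG per stop), reconciled against the
  detector so truth and caller agree on coordinates.
* **Expression program**: disjoint rhythmic sets (defaults 10% rhythmic
  mRNA, 5% rhythmic TE with flat mRNA), fold-amplitudes uniform in [2, 3],
  phases uniform in [0, 24). Rhythms are cosines on the log2 scale so the
  peak-to-trough fold is exact. Counts are negative binomial with
  dispersion 0.05, a standard overdispersion for replicated count data.
* **Footprint geometry**: lengths categorical over 26–35 nt with modes 29
  and 30 at probability 0.35 each; CDS A-sites land in frame 0 with
  probability 0.9, uniformly over codons except pause-site codons
  (multiplier 5–15 on ~10% of genes); 6% of footprints fall in the 5′UTR,
  80% of those directed at annotated uORFs in proportion to their loading,
  in-frame when the uORF is translated and frame-uniform otherwise.
* **TE structure**: baseline log2 TE is normal with sd 0.93, and genes with
  a translated uORF are repressed by −0.525 log2 units. The sd was chosen
  once so that the marginal 95% TE fold-range, including the uORF effect,
  is ~13-fold — the order of spread reported for liver; the repression
  magnitude mirrors the reported uORF-associated TE shift so that
  `location_shift()` has a known target to recover.
* **RNA reads**: positions uniform over the transcript, lengths uniform in
  21–60 nt — which is what makes RNA libraries frame-uniform and
  aperiodic, the negative control for every QC statistic.

Read 5′ ends are back-computed from simulated A-sites through the same
offset table the analysis uses; reads that would overhang a transcript end
are dropped, which is why the recovered 5′UTR share (~5.5%) sits slightly
below the nominal 6% leak. `simulate_counts()` draws CDS count matrices
from the identical negative binomial expectations without materialising
reads; count-level studies (rhythm detection, differential TE) use it so
that large depths stay cheap, and a test asserts that the two simulators
agree in expectation.

What the generator does **not** emulate: genome-space alignment ambiguity,
splicing and isoform mixtures, sequence-dependent offset heterogeneity,
sequencing errors, rRNA/tRNA contamination, non-AUG uORFs, and
NMD-coupled mRNA abundance effects beyond the injected TE/abundance
shifts. Passing recovery tests therefore demonstrate that the statistics
are implemented correctly and calibrated under the stated noise model —
not that they are robust to every artefact of real libraries.

## Numerical choices and degenerate inputs

* Quantiles: type 6 everywhere except the hinge-based trimean (above).
* Pseudocount 1 for all log2 transforms of counts/RPKM; 0 permitted where
  exactness matters (noiseless validation).
* Constant series: fold-amplitude 1, p = 1 (not an error). Perfect fits:
  p = 0 with a guard against 0/0 F-statistics.
* Degenerate Fisher margins report p = 1; the Watson–Wheeler test returns
  W = 0, p = 1 when all angles coincide; zero-trimean genes are skipped.
* Phase is reported at the fitted maximum; at fold-amplitude exactly 1 the
  phase is arbitrary and should be ignored (its fit carries p = 1).
* Ties in circular ranks take average ranks.

## Problem sizes used in validation

The test-suite and acceptance studies use 2000 genes at depth 1e6 for
count-level rhythm/differential-TE recovery, 500 genes with four pooled
1e6-read footprint libraries for alignment-level uORF calling and QC
separation, 1000 random count vectors for the pause-site oracle, 1e5
Monte-Carlo draws for the Rayleigh null, and 20-gene runs for end-to-end
pipeline determinism. Footprint libraries are pooled for uORF calling, as
is usual for coverage-limited feature analyses; with a single library the
read floor (min 10 A-sites) rather than the frame criterion limits
sensitivity on low-expressed genes.

## Known limitations

* The A-site offset table is length-only; sequence-dependent refinement is
  out of scope.
* Differential TE assumes a common genome-wide occupancy trend per sample;
  a condition that shifted most genes' TE simultaneously would be absorbed
  into the trend.
* The cosinor is a single-harmonic model; non-sinusoidal waveforms
  (sawtooth induction, pulses) lose amplitude and may escape detection.
* Published transcriptome-wide gene counts from tissue data depend on the
  underlying annotation, filtering and detection settings; the package
  reproduces the arithmetic and the statistical behaviour of the analysis,
  not those dataset-specific totals.
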