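#' Upper-quartile normalisation
#'
#' Per-sample size factor = 75th percentile of the sample's nonzero gene
#' counts (package quantile rule, [rc_quantile()]), rescaled so the factors
#' have geometric mean 1. Normalised count = raw / factor.
#'
#' @param counts genes x samples matrix of non-negative counts.
#' @return List `normalized` (matrix) and `size_factors` (named vector).
#' @export
upper_quartile_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  raw <- apply(counts, 2, function(x) {
    nz <- x[x > 0]
    if (length(nz) == 0) stop("all-zero sample: no nonzero counts")
    rc_quantile(nz, 0.75)
  })
  sf <- raw / exp(mean(log(raw)))
  list(normalized = sweep(counts, 2, sf, "/"), size_factors = sf)
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = count / (length_nt / 1000) / (library_size / 1e6)`.
#'
#' @param count read count(s) (possibly normalised).
#' @param feature_length_nt feature length(s) in nt, > 0.
#' @param library_size total mapped reads of the library, > 0.
#' @return RPKM value(s).
#' @export
rpkm <- function(count, feature_length_nt, library_size) {
  if (any(feature_length_nt <= 0)) stop("feature length must be > 0")
  if (any(library_size <= 0)) stop("library size must be > 0")
  count / (feature_length_nt / 1e3) / (library_size / 1e6)
}

#' Translation efficiency
#'
#' `TE = RPF-RPKM / RNA-RPKM`, defined only where the RNA RPKM exceeds
#' `floor`; elsewhere `NA` (flagged, not an error), to be excluded from
#' downstream statistics.
#'
#' @param rpf_rpkm,rna_rpkm footprint and RNA RPKM (vectors/matrices of
#'   matching shape).
#' @param floor RNA-RPKM expression floor (default 0: any positive RNA
#'   signal defines a TE).
#' @return TE values with `NA` where undefined.
#' @export
translation_efficiency <- function(rpf_rpkm, rna_rpkm, floor = 0) {
  te <- rpf_rpkm / rna_rpkm
  te[!(rna_rpkm > floor)] <- NA
  te
}

#' Central fold-range of a TE distribution
#'
#' Fold-range spanned by the central `central_mass` of the distribution:
#' `quantile(1 - a) / quantile(a)` with `a = (1 - central_mass)/2`, package
#' quantile rule. With `central_mass = 0.95` this is the "95% of TEs fall
#' into an x-fold range" statistic.
#'
#' @param te_values numeric TEs (`NA` ignored); at least 40 defined values.
#' @param central_mass central probability mass (1.0 gives max/min).
#' @return Fold-range (>= 1 for positive data).
#' @export
te_range <- function(te_values, central_mass = 0.95) {
  te <- te_values[!is.na(te_values)]
  if (length(te) < 40) stop("need at least 40 defined TE values")
  a <- (1 - central_mass) / 2
  if (central_mass >= 1) return(max(te) / min(te))
  q <- rc_quantile(te, c(a, 1 - a))
  q[2] / q[1]
}

#' Permutation test for a difference in TE fold-range
#'
#' Statistic `|log(range_a) - log(range_b)|`; the null is built by shuffling
#' group labels; `p = (1 + #(null >= observed)) / (1 + n_perm)`.
#'
#' @param te_a,te_b TE vectors (non-empty after `NA` removal).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param central_mass passed to [te_range()].
#' @return List `p_value`, `observed`, `n_perm`.
#' @export
range_permutation_test <- function(te_a, te_b, n_perm = 1000, seed = 1,
                                   central_mass = 0.95) {
  stopifnot(n_perm >= 100)
  te_a <- te_a[!is.na(te_a)]; te_b <- te_b[!is.na(te_b)]
  if (length(te_a) == 0 || length(te_b) == 0) stop("both groups must be non-empty")
  set.seed(as.integer(seed))
  obs <- abs(log(te_range(te_a, central_mass)) -
               log(te_range(te_b, central_mass)))
  pool <- c(te_a, te_b)
  na <- length(te_a)
  null <- replicate(n_perm, {
    idx <- sample.int(length(pool), na)
    abs(log(te_range(pool[idx], central_mass)) -
          log(te_range(pool[-idx], central_mass)))
  })
  list(p_value = (1 + sum(null >= obs)) / (1 + n_perm), observed = obs,
       n_perm = n_perm)
}

#' Regression of log2 TE on log10 feature length
#'
#' Ordinary least squares of `log2_te` on `log10_length`, with the two-sided
#' t-test on the slope. Gene-set filtering (expression floors, minimum UTR
#' lengths) is the caller's responsibility.
#'
#' @param log2_te response vector.
#' @param log10_length predictor vector.
#' @return List `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
te_length_regression <- function(log2_te, log10_length) {
  ok <- is.finite(log2_te) & is.finite(log10_length)
  x <- log10_length[ok]; y <- log2_te[ok]
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::var(x) == 0) stop("zero variance in predictor")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4],
       n = length(x))
}

#' Location shift of a group against a reference
#'
#' `delta_log2 = median(log2 group) - median(log2 reference)`, with a
#' two-sided Wilcoxon rank-sum p-value. Non-positive values are excluded
#' (with a message) since they have no log.
#'
#' @param group_values,reference_values positive numeric vectors.
#' @return List `delta_log2`, `percent_change` (`100 * (2^delta - 1)`),
#'   `p_value`, `n_group`, `n_reference`.
#' @export
location_shift <- function(group_values, reference_values) {
  cl <- function(x, what) {
    x <- x[!is.na(x)]
    bad <- x <= 0
    if (any(bad)) message("location_shift: dropping ", sum(bad),
                          " non-positive ", what, " values")
    x[!bad]
  }
  g <- cl(group_values, "group")
  r <- cl(reference_values, "reference")
  if (length(g) == 0 || length(r) == 0) stop("both inputs must be non-empty")
  delta <- stats::median(log2(g)) - stats::median(log2(r))
  p <- stats::wilcox.test(g, r, alternative = "two.sided", exact = FALSE)$p.value
  list(delta_log2 = delta, percent_change = 100 * (2^delta - 1),
       p_value = p, n_group = length(g), n_reference = length(r))
}

#' Principal component analysis of samples
#'
#' Genes are ranked by mean expression and the top `top_n` retained; the
#' matrix is `log2(x + pseudocount)`, gene-centred; samples are projected on
#' the principal components.
#'
#' @param expression_matrix genes x samples matrix (>= 3 samples).
#' @param top_n number of top-expressed genes used (all, with a warning, if
#'   fewer are available).
#' @param pseudocount added before log2.
#' @return List `coordinates` (samples x PCs), `var_explained` (fractions,
#'   non-increasing, summing to <= 1), `genes_used`.
#' @export
pca_samples <- function(expression_matrix, top_n = 4000, pseudocount = 1) {
  m <- as.matrix(expression_matrix)
  if (ncol(m) < 3) stop("need at least 3 samples")
  if (nrow(m) < top_n) {
    warning("fewer genes than top_n; using all ", nrow(m))
    top_n <- nrow(m)
  }
  keep <- order(rowMeans(m), decreasing = TRUE)[seq_len(top_n)]
  x <- log2(m[keep, , drop = FALSE] + pseudocount)
  xc <- x - rowMeans(x)
  pc <- stats::prcomp(t(xc), center = FALSE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  if (sum(pc$sdev^2) <= .Machine$double.eps) ve <- rep(0, length(pc$sdev))
  list(coordinates = pc$x, var_explained = ve, genes_used = top_n)
}

#' Daily relative protein-biosynthesis ratio
#'
#' Footprint RPKMs integrate translation over the CDS, so their daily mean
#' reads out relative protein biosynthesis. Each gene's RPF-RPKM series is
#' averaged over the 24-h cycle by the trapezoid rule (wrapping ZT back to
#' the first timepoint) and divided by the reference gene's mean; the
#' reference ratio is 1.
#'
#' @param rpf_rpkm genes x timepoints matrix (rownames = gene ids), all
#'   genes on the same timepoints.
#' @param zt timepoints in hours, increasing, within one period.
#' @param reference_gene rowname of the reference gene.
#' @param period cycle length in hours.
#' @return Named vector of per-gene ratios.
#' @export
daily_biosynthesis_ratio <- function(rpf_rpkm, zt, reference_gene,
                                     period = 24) {
  m <- as.matrix(rpf_rpkm)
  if (!reference_gene %in% rownames(m)) stop("reference gene absent")
  stopifnot(ncol(m) == length(zt))
  tt <- c(zt, zt[1] + period)
  mm <- cbind(m, m[, 1])
  dt <- diff(tt)
  means <- as.vector(((mm[, -ncol(mm), drop = FALSE] +
                         mm[, -1, drop = FALSE]) / 2) %*% dt) / period
  names(means) <- rownames(m)
  if (means[reference_gene] == 0) stop("reference gene has zero mean RPKM")
  means / means[reference_gene]
}
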