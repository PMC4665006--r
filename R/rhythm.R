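#' Fit a 24-h harmonic (cosinor) model to an expression series
#'
#' Ordinary least squares of `y` on `[1, cos(2*pi*t/period),
#' sin(2*pi*t/period)]`, where `y = log2(values + pseudocount)` (or the raw
#' values with `log2_transform = FALSE`). Writing the fit as
#' `m + A*cos(w*(t - phi))`, the reported quantities are the mesor `m`, the
#' peak-to-trough fold-amplitude of the fitted curve `2^(2A)`, the peak
#' phase `phi` in hours within `[0, period)`, and the p-value of the F-test
#' of the two harmonic terms against the intercept-only model.
#'
#' @param values non-negative expression values (RPKM, normalised counts).
#' @param zt_times sampling times in hours; at least 6 observations spanning
#'   at least half the period.
#' @param period period in hours.
#' @param log2_transform log2-transform the values first?
#' @param pseudocount added before the log2 transform.
#' @return An object of class `"harmonic_fit"` with fields `mesor_log2`,
#'   `amp_fold`, `phase_h`, `pvalue`, `coefficients` (`mesor`, `cos`,
#'   `sin`), `period`, `n`, and the data used. A constant series gives
#'   `amp_fold = 1` and `pvalue = 1`.
#' @seealso [detect_rhythmic()] for genome-wide application with FDR
#'   control; methods `print`, `coef`, `predict`, `fitted`, `residuals`,
#'   `plot`.
#' @export
#' @examples
#' zt <- rep(seq(0, 22, 2), 2)
#' y <- 2^(5 + 0.5 * cos(2 * pi * (zt - 12) / 24))
#' fit <- harmonic_fit(y, zt, pseudocount = 0)
#' fit$amp_fold  # 2
#' fit$phase_h   # 12
harmonic_fit <- function(values, zt_times, period = 24,
                         log2_transform = TRUE, pseudocount = 1) {
  stopifnot(length(values) == length(zt_times))
  ok <- is.finite(values) & is.finite(zt_times)
  values <- values[ok]; zt <- zt_times[ok]
  if (length(values) < 6) stop("need at least 6 observations")
  if (diff(range(zt)) < period / 2)
    stop("observations must span at least half the period")
  y <- if (log2_transform) log2(values + pseudocount) else values
  w <- 2 * pi * zt / period
  cw <- cos(w); sw <- sin(w)
  X <- cbind(1, cw, sw)
  cf <- stats::lm.fit(X, y)$coefficients
  a <- cf[2]; b <- cf[3]
  if (anyNA(c(a, b))) { a <- ifelse(is.na(a), 0, a); b <- ifelse(is.na(b), 0, b) }
  A <- sqrt(a^2 + b^2)
  fitted <- cf[1] + a * cw + b * sw
  rss1 <- sum((y - fitted)^2)
  rss0 <- sum((y - mean(y))^2)
  df2 <- length(y) - 3
  if (rss0 <= .Machine$double.eps * length(y)) {
    p <- 1
  } else if (rss1 <= .Machine$double.eps * rss0) {
    p <- 0
  } else {
    Fstat <- ((rss0 - rss1) / 2) / (rss1 / df2)
    p <- stats::pf(Fstat, 2, df2, lower.tail = FALSE)
  }
  structure(list(
    mesor_log2 = unname(cf[1]),
    amp_fold = unname(2^(2 * A)),
    phase_h = unname((atan2(b, a) * period / (2 * pi)) %% period),
    pvalue = unname(p),
    coefficients = c(mesor = unname(cf[1]), cos = unname(a), sin = unname(b)),
    period = period, n = length(y),
    zt = zt, y = y,
    log2_transform = log2_transform, pseudocount = pseudocount),
    class = "harmonic_fit")
}

#' @export
print.harmonic_fit <- function(x, ...) {
  cat(sprintf(
    "harmonic fit (period %g h, n = %d)\n  mesor (log2) %.3f | fold-amplitude %.3f | peak phase ZT%.2f | p = %.3g\n",
    x$period, x$n, x$mesor_log2, x$amp_fold, x$phase_h, x$pvalue))
  invisible(x)
}

#' @export
coef.harmonic_fit <- function(object, ...) object$coefficients

#' @export
fitted.harmonic_fit <- function(object, ...) {
  stats::predict(object, object$zt)
}

#' @export
residuals.harmonic_fit <- function(object, ...) {
  object$y - fitted(object)
}

#' Predict the fitted harmonic at new times
#' @param object a `"harmonic_fit"`.
#' @param newtimes hours at which to evaluate (defaults to the fitted
#'   times); values are on the fitting scale (log2 if transformed).
#' @param ... unused.
#' @export
predict.harmonic_fit <- function(object, newtimes = object$zt, ...) {
  w <- 2 * pi * newtimes / object$period
  cf <- object$coefficients
  unname(cf["mesor"] + cf["cos"] * cos(w) + cf["sin"] * sin(w))
}

#' @export
plot.harmonic_fit <- function(x, ...) {
  graphics::plot(x$zt, x$y, xlab = "ZT (h)",
                 ylab = if (x$log2_transform) "log2 expression" else "value",
                 ...)
  tt <- seq(0, x$period, length.out = 200)
  graphics::lines(tt, stats::predict(x, tt), col = "steelblue")
  invisible(x)
}

#' Genome-wide rhythm detection with FDR control
#'
#' Fits [harmonic_fit()] to every gene of one assay's expression matrix,
#' applies Benjamini-Hochberg correction across genes, and flags a gene
#' rhythmic when its fitted fold-amplitude exceeds `amp_cutoff` and its
#' q-value is below `fdr`.
#'
#' @param expression_matrix genes x samples matrix (rownames = gene ids).
#' @param zt sampling time in hours for each column; replicates are pooled
#'   into one fit (at least 12 usable points per gene).
#' @param amp_cutoff peak-to-trough fold-amplitude cutoff (> this value).
#' @param fdr FDR cutoff on BH q-values.
#' @param period period in hours.
#' @param log2_transform,pseudocount passed to [harmonic_fit()].
#' @return Data frame per gene: `gene_id`, `mesor_log2`, `amp_fold`,
#'   `phase_h`, `pvalue`, `qvalue`, `rhythmic`.
#' @export
detect_rhythmic <- function(expression_matrix, zt, amp_cutoff = 1.5,
                            fdr = 0.05, period = 24, log2_transform = TRUE,
                            pseudocount = 1) {
  m <- as.matrix(expression_matrix)
  if (nrow(m) == 0) stop("empty expression table")
  stopifnot(ncol(m) == length(zt))
  if (ncol(m) < 12) stop("need at least 12 samples")
  fits <- lapply(seq_len(nrow(m)), function(i)
    harmonic_fit(m[i, ], zt, period = period,
                 log2_transform = log2_transform,
                 pseudocount = pseudocount))
  out <- data.frame(
    gene_id = rownames(m),
    mesor_log2 = vapply(fits, `[[`, 0, "mesor_log2"),
    amp_fold = vapply(fits, `[[`, 0, "amp_fold"),
    phase_h = vapply(fits, `[[`, 0, "phase_h"),
    pvalue = vapply(fits, `[[`, 0, "pvalue"),
    stringsAsFactors = FALSE)
  out$qvalue <- stats::p.adjust(out$pvalue, method = "BH")
  out$rhythmic <- out$amp_fold > amp_cutoff & out$qvalue < fdr
  rownames(out) <- NULL
  out
}

.rhythmic_flags <- function(x) {
  if (is.data.frame(x)) stats::setNames(x$rhythmic, x$gene_id)
  else if (is.logical(x) && !is.null(names(x))) x
  else stop("expected a detect_rhythmic() frame or a named logical vector")
}

#' Classify genes by mRNA / footprint rhythmicity
#'
#' Partitions the gene universe into `both`, `rna_only`, `rpf_only`,
#' `neither`, with the Venn counts. The counts satisfy
#' `rna_only = rna_rhythmic - both` and `rpf_only = rpf_rhythmic - both`.
#'
#' @param rna_fits,rpf_fits [detect_rhythmic()] frames (or named logical
#'   vectors) over the same gene universe.
#' @return List `assignments` (data frame `gene_id`, `category`) and
#'   `counts` (named vector `n`, `rna_rhythmic`, `rpf_rhythmic`, `both`,
#'   `rna_only`, `rpf_only`, `neither`).
#' @export
classify_genes <- function(rna_fits, rpf_fits) {
  rna <- .rhythmic_flags(rna_fits)
  rpf <- .rhythmic_flags(rpf_fits)
  if (length(rna) != length(rpf) ||
      !setequal(names(rna), names(rpf)))
    stop("gene universes differ between assays")
  rpf <- rpf[names(rna)]
  category <- ifelse(rna & rpf, "both",
                     ifelse(rna, "rna_only",
                            ifelse(rpf, "rpf_only", "neither")))
  counts <- c(n = length(rna),
              rna_rhythmic = sum(rna), rpf_rhythmic = sum(rpf),
              both = sum(rna & rpf),
              rna_only = sum(rna & !rpf), rpf_only = sum(rpf & !rna),
              neither = sum(!rna & !rpf))
  list(assignments = data.frame(gene_id = names(rna), category = category,
                                stringsAsFactors = FALSE,
                                row.names = NULL),
       counts = counts)
}

#' Test for time-dependent translation efficiency
#'
#' For each sample, a robust linear trend of `log2(RPF + 1)` on
#' `log2(RNA + 1)` is fitted across genes ([MASS::rlm()]); each gene's
#' residual, standardised by the fit's scale estimate, measures its relative
#' ribosome occupancy in that sample. Per gene, the harmonic time terms are
#' then F-tested on the standardised residual series (replicates pooled),
#' with per-gene residual variances shrunk towards the genome-wide
#' distribution by empirical Bayes ([limma::squeezeVar()]); BH q-values are
#' computed across genes.
#'
#' @param rpf_counts,rna_counts genes x samples count matrices over the same
#'   genes; columns of the two matrices are paired (same ZT order).
#' @param zt ZT hours per column (at least 12 paired samples).
#' @param floor_rna genes with mean RNA count below this are returned as
#'   `NA` (insufficient signal to define a TE trend).
#' @param period period in hours.
#' @return Data frame `gene_id`, `pvalue`, `qvalue` (`NA` for genes under
#'   the floor).
#' @export
differential_te <- function(rpf_counts, rna_counts, zt, floor_rna = 10,
                            period = 24) {
  rpf <- as.matrix(rpf_counts); rna <- as.matrix(rna_counts)
  stopifnot(dim(rpf) == dim(rna), ncol(rpf) == length(zt))
  if (ncol(rpf) < 12) stop("need at least 12 paired samples")
  usable <- rowMeans(rna) >= floor_rna
  p <- rep(NA_real_, nrow(rpf))
  if (any(usable)) {
    lx <- log2(rna[usable, , drop = FALSE] + 1)
    ly <- log2(rpf[usable, , drop = FALSE] + 1)
    res <- matrix(NA_real_, sum(usable), ncol(rpf))
    for (j in seq_len(ncol(rpf))) {
      fit <- suppressWarnings(MASS::rlm(ly[, j] ~ lx[, j], maxit = 50))
      s <- fit$s
      if (!is.finite(s) || s <= 0) s <- stats::mad(stats::residuals(fit))
      res[, j] <- stats::residuals(fit) / s
    }
    w <- 2 * pi * zt / period
    X <- cbind(1, cos(w), sin(w))
    B <- res %*% X %*% solve(crossprod(X))
    fit1 <- B %*% t(X)
    rss1 <- rowSums((res - fit1)^2)
    rss0 <- rowSums((res - rowMeans(res))^2)
    d2 <- ncol(res) - 3L
    s2 <- rss1 / d2
    if (sum(usable) >= 10) {
      sv <- limma::squeezeVar(s2, df = d2)
      var_post <- sv$var.post
      df_post <- d2 + sv$df.prior
    } else {
      var_post <- s2
      df_post <- d2
    }
    Fm <- ((rss0 - rss1) / 2) / var_post
    pu <- stats::pf(Fm, 2, df_post, lower.tail = FALSE)
    pu[rss0 <= .Machine$double.eps * ncol(res)] <- 1
    p[usable] <- pu
  }
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  data.frame(gene_id = rownames(rpf), pvalue = p, qvalue = q,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' High-confidence rhythmically translated, mRNA-flat gene set
#'
#' Genes classified `rpf_only` (footprints rhythmic, mRNA not) whose
#' differential-TE q-value is below `q_cutoff`.
#'
#' @param classification result of [classify_genes()].
#' @param diff_te result of [differential_te()].
#' @param q_cutoff FDR cutoff on the differential-TE q-value.
#' @return Character vector of gene ids.
#' @export
high_confidence_set <- function(classification, diff_te, q_cutoff = 0.05) {
  a <- classification$assignments
  sig <- diff_te$gene_id[!is.na(diff_te$qvalue) & diff_te$qvalue < q_cutoff]
  intersect(a$gene_id[a$category == "rpf_only"], sig)
}

#' Rayleigh test of circular uniformity
#'
#' Phases in hours are mapped to angles by `theta = 2*pi*h/period`; the
#' mean resultant length is `R = |sum(exp(i*theta))|/n` and the p-value uses
#' the standard Rayleigh approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - (nR)^2)) - (1 + 2n))`.
#'
#' @param phases_h phases in hours.
#' @param period period in hours.
#' @return Object of class `"circular_stat"`: `statistic` (R, in `[0, 1]`),
#'   `p_value`, `n`, `method`.
#' @export
rayleigh_test <- function(phases_h, period = 24) {
  n <- length(phases_h)
  if (n < 2) stop("need at least 2 phases")
  th <- 2 * pi * phases_h / period
  C <- sum(cos(th)); S <- sum(sin(th))
  R <- sqrt(C^2 + S^2) / n
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (n * R)^2)) - (1 + 2 * n))
  structure(list(statistic = R, p_value = min(max(p, 0), 1), n = n,
                 method = "Rayleigh uniformity test"),
            class = "circular_stat")
}

#' Watson-Wheeler test for homogeneity of two samples of angles
#'
#' Combined circular ranks (ties broken by average rank) are mapped to
#' uniform scores `beta = 2*pi*rank/N`; with `C_g`, `S_g` the per-group
#' resultants of the scores, `W = 2 * sum((C_g^2 + S_g^2) / n_g)` and the
#' p-value comes from a chi-squared distribution with 2 df.
#'
#' @param phases_a,phases_b phases in hours (a warning is issued when a
#'   group has fewer than 10 angles, where the chi-squared approximation is
#'   poor).
#' @param period period in hours.
#' @return Object of class `"circular_stat"`: `statistic` (W >= 0),
#'   `p_value`, `n1`, `n2`. Degenerate input (all angles identical) gives
#'   `W = 0`, `p = 1`.
#' @export
watson_wheeler <- function(phases_a, phases_b, period = 24) {
  n1 <- length(phases_a); n2 <- length(phases_b)
  if (n1 < 10 || n2 < 10)
    warning("small samples: chi-squared approximation is unreliable")
  all_ph <- c(phases_a, phases_b) %% period
  if (length(unique(all_ph)) == 1)
    return(structure(list(statistic = 0, p_value = 1, n1 = n1, n2 = n2,
                          method = "Watson-Wheeler test"),
                     class = "circular_stat"))
  N <- n1 + n2
  r <- rank(all_ph, ties.method = "average")
  beta <- 2 * pi * r / N
  ga <- seq_len(n1)
  Ca <- sum(cos(beta[ga])); Sa <- sum(sin(beta[ga]))
  Cb <- sum(cos(beta[-ga])); Sb <- sum(sin(beta[-ga]))
  W <- 2 * ((Ca^2 + Sa^2) / n1 + (Cb^2 + Sb^2) / n2)
  structure(list(statistic = W,
                 p_value = stats::pchisq(W, df = 2, lower.tail = FALSE),
                 n1 = n1, n2 = n2, method = "Watson-Wheeler test"),
            class = "circular_stat")
}

#' @export
print.circular_stat <- function(x, ...) {
  nn <- if (!is.null(x$n)) sprintf("n = %d", x$n) else
    sprintf("n1 = %d, n2 = %d", x$n1, x$n2)
  cat(sprintf("%s: statistic = %.4g, p = %.3g (%s)\n",
              x$method, x$statistic, x$p_value, nn))
  invisible(x)
}

#' Histogram of peak phases over the cycle
#'
#' Bin `k` covers `[k*period/n_bins, (k+1)*period/n_bins)`; counts sum to
#' the number of phases.
#'
#' @param phases_h phases in `[0, period)`.
#' @param n_bins number of bins.
#' @param period period in hours.
#' @return Named integer vector of per-bin counts (names = bin start hour).
#' @export
phase_histogram <- function(phases_h, n_bins = 24, period = 24) {
  if (any(phases_h < 0 | phases_h >= period))
    stop("phases must lie in [0, ", period, ")")
  bin <- floor(phases_h * n_bins / period)
  counts <- tabulate(bin + 1L, n_bins)
  stats::setNames(as.integer(counts),
                  sprintf("%g", (0:(n_bins - 1)) * period / n_bins))
}
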