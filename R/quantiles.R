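#' Package-wide quantile rule
#'
#' Quantiles throughout the package (upper-quartile size factors, TE
#' fold-ranges) use linear interpolation of order statistics at plotting
#' positions `p * (n + 1)` (`stats::quantile` type 6). Under this rule the
#' 75th percentile of `c(1, 3, 5, 7)` is 6.5.
#'
#' @param x numeric vector.
#' @param probs probabilities in `[0, 1]`.
#' @return Numeric vector of quantiles, unnamed.
#' @seealso [trimean()], which deliberately uses Tukey hinges instead.
#' @export
#' @examples
#' rc_quantile(c(1, 3, 5, 7), 0.75)  # 6.5
rc_quantile <- function(x, probs) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("rc_quantile(): no non-missing values")
  stats::quantile(x, probs = probs, type = 6, names = FALSE)
}

#' Tukey's trimean
#'
#' `(H1 + 2 * median + H2) / 4` with `H1`, `H2` the Tukey hinges (from
#' [stats::fivenum()]). The hinge form is the classical trimean and is what
#' makes the estimator robust for sparsely covered coding sequences: a single
#' extreme codon cannot move it (`trimean(c(0, 0, 0, 0, 100))` is 0).
#'
#' @param x non-empty numeric vector.
#' @return A single number.
#' @export
#' @examples
#' trimean(1:5)                 # 3
#' trimean(c(0, 0, 0, 0, 100))  # 0
trimean <- function(x) {
  x <- as.numeric(x)
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("trimean(): needs at least one value")
  f <- stats::fivenum(x)
  unname((f[2L] + 2 * f[3L] + f[4L]) / 4)
}
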