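#' Greedy diversity selection of reference samples
#'
#' Builds an ordered panel of reference DNA samples for mixture design by
#' adding samples one at a time, each time choosing the sample that
#' contributes the largest number of loci whose genotype is not yet
#' represented among the samples already selected. Mass-fraction mixtures of
#' the selected samples then span many distinct expected allele fractions.
#' Ties are broken towards the lexicographically smallest sample identifier,
#' so the result is deterministic. Selection stops when no candidate adds
#' diversity or `n_max` samples have been chosen.
#'
#' @param gm Genotype matrix: loci in rows, samples in columns, alt-allele
#'   dosage in `{0, 1, 2}` or `NA` for missing.
#' @param seed_sample Column name of the first sample.
#' @param n_max Maximum number of samples to select.
#' @return Character vector of selected sample identifiers, in order.
#' @export
greedy_select <- function(gm, seed_sample, n_max = ncol(gm)) {
  gm <- as.matrix(gm)
  if (nrow(gm) == 0 || ncol(gm) == 0) stop("empty genotype matrix")
  ok <- gm %in% c(0, 1, 2) | is.na(gm)
  if (!all(ok)) stop("genotype dosages must be 0, 1, 2 or NA")
  if (!seed_sample %in% colnames(gm)) stop("seed_sample not in matrix")
  selected <- seed_sample
  remaining <- setdiff(colnames(gm), seed_sample)
  ## seen[l, g+1]: genotype g already represented at locus l
  seen <- matrix(FALSE, nrow(gm), 3)
  mark <- function(s) {
    d <- gm[, s]
    i <- which(!is.na(d))
    seen[cbind(i, d[i] + 1)] <<- TRUE
  }
  mark(seed_sample)
  while (length(remaining) > 0 && length(selected) < n_max) {
    gain <- vapply(remaining, function(s) {
      d <- gm[, s]
      i <- which(!is.na(d))
      sum(!seen[cbind(i, d[i] + 1)])
    }, 0)
    if (max(gain) == 0) break
    pick <- sort(remaining[gain == max(gain)])[1]
    selected <- c(selected, pick)
    mark(pick)
    remaining <- setdiff(remaining, pick)
  }
  selected
}

#' Expected percent variant of a DNA mixture
#'
#' With mass (genome-copy) fractions `c_k` over the constituent samples, a
#' locus with alt-allele dosages `d_k` has expected allele fraction
#' `sum(c_k d_k / 2)`, i.e. expected percent variant
#' `100 sum(c_k d_k) / 2`. Loci with a missing genotype in any sample that
#' actually contributes mass are flagged and reported as `NA`.
#'
#' @param coefficients Named numeric vector of mass fractions (one mixture),
#'   or a samples x mixtures matrix; each mixture must sum to 1 (+/- 1e-9).
#' @param gm Genotype matrix as in [greedy_select()].
#' @return Matrix of expected percent variant, loci x mixtures (a 1-column
#'   matrix for a vector input), with attribute `flagged_loci`.
#' @examples
#' gm <- rbind(L1 = c(A = 1, B = 0))
#' expected_pct_variant(c(A = 0.5, B = 0.5), gm) # 25%
#' @export
expected_pct_variant <- function(coefficients, gm) {
  gm <- as.matrix(gm)
  cf <- if (is.matrix(coefficients)) coefficients else
    matrix(coefficients,
      ncol = 1,
      dimnames = list(names(coefficients), "mixture1")
    )
  if (is.null(rownames(cf)) || !all(rownames(cf) %in% colnames(gm))) {
    stop("coefficient names must match genotype matrix samples")
  }
  if (any(abs(colSums(cf) - 1) > 1e-9)) {
    stop("mixing coefficients must sum to 1 within 1e-9")
  }
  if (any(cf < 0)) stop("mixing coefficients must be non-negative")
  g <- gm[, rownames(cf), drop = FALSE]
  contributes <- cf > 0
  flagged <- is.na(g) %*% contributes > 0
  g0 <- g
  g0[is.na(g0)] <- 0
  out <- 100 * (g0 %*% cf) / 2
  out[flagged] <- NA_real_
  attr(out, "flagged_loci") <- rownames(gm)[rowSums(flagged) > 0]
  out
}

#' Empirical CDF of expected percent variant
#'
#' Fraction of expected variants at or below `x` percent; used to verify a
#' mixture design enriches for low allele fractions (e.g. the design goal
#' that a third of variants sit at or below 8%).
#'
#' @param expected_pct Vector of expected percent variants in `[0, 100]`.
#' @param x Percent threshold(s).
#' @return Fraction(s) in `[0, 1]`.
#' @export
expected_cdf <- function(expected_pct, x) {
  expected_pct <- expected_pct[!is.na(expected_pct)]
  if (length(expected_pct) == 0) stop("no expected percent variants")
  vapply(x, function(q) mean(expected_pct <= q), 0)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement of paired measurements with the identity line:
#' `2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with 1/n moment
#' normalization. Unlike Pearson correlation it penalizes both location and
#' scale shifts, which is why it is the linearity/accuracy metric for
#' observed-versus-expected allele fractions.
#'
#' @param x,y Equal-length numeric vectors (length >= 2, finite).
#' @return CCC in `[-1, 1]`; `NA` with a warning when both inputs are
#'   constant with equal means (agreement undefined).
#' @export
ccc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop("x and y must have equal length >= 2")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("inputs must be finite")
  n <- length(x)
  mx <- mean(x)
  my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) {
    warning("both inputs constant with equal means; CCC undefined")
    return(NA_real_)
  }
  2 * sxy / denom
}

#' Precision summary of replicate measurements by expected level
#'
#' For replicate percent-variant measurements grouped by their expected
#' level, computes the median and interquartile range per level (type-7
#' interpolated quartiles) and then the median of those medians and of
#' those IQRs across levels — the headline precision numbers for a mixture
#' experiment.
#'
#' @param values Numeric vector of observed percent variants.
#' @param groups Grouping factor/vector (expected level per measurement).
#' @return List with `per_level` (data.frame: group, n, median, iqr),
#'   `median_of_medians` and `median_iqr`.
#' @export
precision_summary <- function(values, groups) {
  stopifnot(length(values) == length(groups), length(values) > 0)
  sp <- split(values, groups)
  per <- data.frame(
    group = names(sp),
    n = vapply(sp, length, 0L),
    median = vapply(sp, stats::median, 0, na.rm = TRUE),
    iqr = vapply(sp, iqr7, 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(
    per_level = per,
    median_of_medians = stats::median(per$median),
    median_iqr = stats::median(per$iqr)
  )
}
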