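#' Depth-based position filters
#'
#' `depth_filter()` retains hypotheses whose position depth is at least
#' `min_reads` *and* at least `min_frac_median` of the sample median depth
#' (defaults 100 reads and 0.1, the standard low-coverage filter for this
#' kind of panel). `fold_of_median_filter()` keeps positions with depth
#' within a multiplicative band `[median/fold, median*fold]` of the sample
#' median, the symmetric filter used before cross-platform comparisons.
#' Both use the linear-interpolation median over distinct covered positions
#' and are idempotent.
#'
#' @param x A [sample_table()].
#' @param min_reads Minimum absolute depth (>= 0).
#' @param min_frac_median Minimum depth as a fraction of the sample median,
#'   in `[0, 1]`.
#' @return The filtered [sample_table()].
#' @export
depth_filter <- function(x, min_reads = 100, min_frac_median = 0.1) {
  stopifnot(min_reads >= 0, min_frac_median >= 0, min_frac_median <= 1)
  if (nrow(x) == 0) {
    warning("empty sample table")
    return(x)
  }
  med <- median_depth(x)
  cut <- if (is.na(med)) {
    if (min_frac_median > 0 && min_reads > 0) {
      warning("no covered positions; median depth undefined")
    }
    min_reads
  } else {
    max(min_reads, min_frac_median * med)
  }
  keep <- x$depth >= cut
  out <- x[keep, , drop = FALSE]
  class(out) <- class(x)
  out
}

#' @rdname depth_filter
#' @param fold Fold band around the median, `> 1` (use `Inf` for identity).
#' @export
fold_of_median_filter <- function(x, fold = 10) {
  if (fold <= 1) stop("fold must be > 1")
  if (nrow(x) == 0 || is.infinite(fold)) {
    return(x)
  }
  med <- median_depth(x)
  if (is.na(med)) {
    warning("no covered positions; fold-of-median filter is a no-op")
    return(x)
  }
  keep <- x$depth >= med / fold & x$depth <= med * fold
  out <- x[keep, , drop = FALSE]
  class(out) <- class(x)
  out
}

#' Coverage uniformity of per-amplicon depths
#'
#' Summarizes how tightly per-amplicon median depths cluster around the
#' overall median: the fraction within 2-fold and within 5-fold of the
#' median. High values indicate the even amplification a clinical panel
#' needs.
#'
#' @param depths Non-negative numeric vector of per-amplicon median depths.
#' @return List with `frac_within_2fold`, `frac_within_5fold`,
#'   `overall_median`, and a logical `undefined` flag (all-zero input).
#' @examples
#' coverage_uniformity(c(100, 100, 30, 600))
#' @export
coverage_uniformity <- function(depths) {
  if (length(depths) == 0) stop("depths must be non-empty")
  if (any(depths < 0)) stop("depths must be non-negative")
  if (all(depths == 0)) {
    warning("all depths are zero; uniformity undefined")
    return(list(
      frac_within_2fold = NA_real_, frac_within_5fold = NA_real_,
      overall_median = 0, undefined = TRUE
    ))
  }
  med <- stats::median(depths)
  within <- function(k) mean(depths >= med / k & depths <= med * k)
  list(
    frac_within_2fold = within(2), frac_within_5fold = within(5),
    overall_median = med, undefined = FALSE
  )
}
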