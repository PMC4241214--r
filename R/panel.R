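#' Amplicon panel definitions
#'
#' A panel is a set of genomic intervals in 0-based half-open (BED)
#' coordinates. Each interrogated position carries exactly three
#' single-nucleotide hypotheses (one per non-reference base), so a panel of
#' `n` positions exposes `3 n` testable hypotheses. Hypothesis positions
#' elsewhere in the package are 1-based (VCF convention);
#' [bed_interval_positions()] converts.
#'
#' @param regions A data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), or `NULL` when only a size is known.
#' @param n_positions Total interrogated positions; computed from `regions`
#'   when omitted.
#' @return An object of class `tas_panel` with `regions`, `n_positions` and
#'   `size_kb` (`n_positions / 1000`).
#' @examples
#' p <- panel(n_positions = 109302)
#' count_hypotheses(p) # 327906
#' @export
panel <- function(regions = NULL, n_positions = NULL) {
  if (!is.null(regions)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
    if (any(regions$end <= regions$start)) {
      stop("panel intervals must satisfy start < end (0-based half-open)")
    }
    np <- sum(regions$end - regions$start)
    if (!is.null(n_positions) && n_positions != np) {
      stop("n_positions does not match the sum of interval lengths")
    }
    n_positions <- np
  }
  if (is.null(n_positions) || n_positions < 0) {
    stop("a panel needs regions or a non-negative n_positions")
  }
  structure(
    list(
      regions = regions, n_positions = as.numeric(n_positions),
      size_kb = n_positions / 1000
    ),
    class = "tas_panel"
  )
}

#' @rdname panel
#' @param path BED file path (parsed with \pkg{rtracklayer}).
#' @export
read_panel_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  panel(data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L, # back to 0-based half-open
    end = BiocGenerics::end(gr),
    stringsAsFactors = FALSE
  ))
}

#' Number of substitution hypotheses in a panel
#'
#' @param x A [panel()].
#' @return `3 * n_positions`.
#' @export
count_hypotheses <- function(x) {
  stopifnot(inherits(x, "tas_panel"))
  3 * x$n_positions
}

#' @rdname panel
#' @param chrom,start,end A single 0-based half-open interval.
#' @export
bed_interval_positions <- function(chrom, start, end) {
  stopifnot(length(chrom) == 1, end > start)
  data.frame(
    chrom = chrom, pos = seq.int(start + 1L, end),
    stringsAsFactors = FALSE
  )
}

#' @export
print.tas_panel <- function(x, ...) {
  cat(
    "<tas_panel>", format(x$n_positions, big.mark = ","), "positions,",
    format(count_hypotheses(x), big.mark = ","), "hypotheses,",
    sprintf("%.3f kb\n", x$size_kb)
  )
  invisible(x)
}
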