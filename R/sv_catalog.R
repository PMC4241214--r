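#' Positions-by-samples cohort matrices
#'
#' Container for cohort-level systematic-variant discovery: a percent-variant
#' matrix (hypotheses in rows, samples in columns, `NA` for missing
#' measurements), an optional depth matrix of the same shape, and the
#' hypothesis table the rows describe.
#'
#' @param pct Numeric matrix, hypotheses x samples, percent variant.
#' @param hypotheses Data.frame with `chrom`, `pos`, `ref`, `alt` (one row
#'   per matrix row).
#' @param depth Optional depth matrix matching `pct`.
#' @return A `tas_cohort_matrix` object.
#' @export
cohort_matrix <- function(pct, hypotheses, depth = NULL) {
  pct <- as.matrix(pct)
  stopifnot(
    nrow(pct) == nrow(hypotheses),
    all(c("chrom", "pos", "ref", "alt") %in% names(hypotheses))
  )
  if (!is.null(depth)) stopifnot(all(dim(depth) == dim(pct)))
  classify_substitution(hypotheses$ref, hypotheses$alt)
  rownames(pct) <- hyp_key(
    hypotheses$chrom, hypotheses$pos,
    hypotheses$ref, hypotheses$alt
  )
  if (anyDuplicated(rownames(pct))) stop("duplicate hypothesis keys")
  structure(list(pct = pct, depth = depth, hypotheses = hypotheses),
    class = "tas_cohort_matrix"
  )
}

#' @export
print.tas_cohort_matrix <- function(x, ...) {
  cat(
    "<tas_cohort_matrix>", nrow(x$pct), "hypotheses x", ncol(x$pct),
    "samples\n"
  )
  invisible(x)
}

#' Classify systematic variants against a Hardy-Weinberg envelope
#'
#' A hypothesis is catalogued as a systematic variant (SV) when all three
#' criteria hold: (a) its cohort (mean, SD) of percent variant falls outside
#' the simulated Hardy-Weinberg acceptance band at its mean, (b) it carries
#' no annotation, and (c) at least one sample shows at least `min_pct`
#' percent variant. Annotated out-of-band hypotheses are reported but
#' excluded from the catalog. Hypotheses measured in fewer than
#' `min_coverage_frac` of the samples are "unevaluable" and are reported,
#' not classified.
#'
#' @param cohort A [cohort_matrix()].
#' @param envelope A [simulate_envelope()] result built for the same cohort
#'   size.
#' @param annotations A [annotation_set()] or `NULL`.
#' @param min_pct Minimum percent variant that must be reached in at least
#'   one sample (default 2).
#' @param min_coverage_frac Minimum fraction of samples with a measurement
#'   (default 0.8).
#' @return A data.frame of class `tas_sv_catalog` with per-hypothesis
#'   evidence (`mean_pct`, `sd_pct`, `max_pct`, band, flags) and attributes
#'   `n_candidates` (out-of-band with the `min_pct` signal),
#'   `n_annotated_excluded`, `n_svs` and `n_unevaluable`.
#' @export
classify_svs <- function(cohort, envelope, annotations = NULL, min_pct = 2,
                         min_coverage_frac = 0.8) {
  stopifnot(
    inherits(cohort, "tas_cohort_matrix"),
    inherits(envelope, "tas_hw_envelope")
  )
  n <- ncol(cohort$pct)
  if (n < 2) stop("cohort must contain at least 2 samples")
  if (envelope$n_samples != n) {
    stop(
      "envelope was simulated for ", envelope$n_samples,
      " samples but the cohort has ", n,
      " (the acceptance band is cohort-size-specific)"
    )
  }
  ev <- sv_evidence(cohort, envelope, annotations, min_coverage_frac)
  ev$candidate <- ev$evaluable & ev$outlier & ev$max_pct >= min_pct
  ev$is_sv <- ev$candidate & !ev$annotated
  structure(ev,
    class = c("tas_sv_catalog", "data.frame"),
    n_candidates = sum(ev$candidate),
    n_annotated_excluded = sum(ev$candidate & ev$annotated),
    n_svs = sum(ev$is_sv),
    n_unevaluable = sum(!ev$evaluable),
    min_pct = min_pct
  )
}

## internal: shared per-hypothesis evidence for classify_svs and
## hw_consistency_report
sv_evidence <- function(cohort, envelope, annotations, min_coverage_frac) {
  pct <- cohort$pct
  n <- ncol(pct)
  n_obs <- rowSums(!is.na(pct))
  mean_pct <- rowMeans(pct, na.rm = TRUE)
  sd_pct <- apply(pct, 1, stats::sd, na.rm = TRUE)
  max_pct <- suppressWarnings(apply(pct, 1, max, na.rm = TRUE))
  max_pct[n_obs == 0] <- NA_real_
  ob <- envelope_outlier(envelope, mean_pct, sd_pct)
  hy <- cohort$hypotheses
  data.frame(
    chrom = hy$chrom, pos = hy$pos, ref = hy$ref, alt = hy$alt,
    n_obs = n_obs, mean_pct = mean_pct, sd_pct = sd_pct, max_pct = max_pct,
    band_lo = ob$band_lo, band_hi = ob$band_hi,
    outlier = ob$outlier,
    evaluable = n_obs >= ceiling(min_coverage_frac * n) & n_obs >= 2,
    annotated = is_annotated(hy$chrom, hy$pos, hy$ref, hy$alt, annotations),
    stringsAsFactors = FALSE
  )
}

#' Hardy-Weinberg consistency report for a cohort
#'
#' Counts the hypotheses whose (mean, SD) lies inside the envelope band
#' (restricted to those reaching `min_pct` in at least one sample, i.e.
#' hypotheses with variant-level signal rather than baseline noise) and the
#' fraction of those that are annotated.
#'
#' @inheritParams classify_svs
#' @return List with `n_within_band`, `n_within_annotated`,
#'   `fraction_annotated`.
#' @export
hw_consistency_report <- function(cohort, envelope, annotations = NULL,
                                  min_pct = 2, min_coverage_frac = 0.8) {
  stopifnot(inherits(cohort, "tas_cohort_matrix"))
  if (nrow(cohort$pct) == 0) {
    return(list(
      n_within_band = 0L, n_within_annotated = 0L,
      fraction_annotated = NaN
    ))
  }
  ev <- sv_evidence(cohort, envelope, annotations, min_coverage_frac)
  within <- ev$evaluable & !ev$outlier & !is.na(ev$max_pct) &
    ev$max_pct >= min_pct
  list(
    n_within_band = sum(within),
    n_within_annotated = sum(within & ev$annotated),
    fraction_annotated = if (any(within)) {
      sum(within & ev$annotated) / sum(within)
    } else {
      NaN
    }
  )
}

#' @rdname classify_svs
#' @param x A `tas_sv_catalog`.
#' @param path Output TSV path (columns chrom, pos, ref, alt, mean_pct,
#'   sd_pct, max_pct, band_lo, band_hi).
#' @export
write_sv_catalog <- function(x, path) {
  stopifnot(inherits(x, "tas_sv_catalog"))
  sv <- x[x$is_sv, c(
    "chrom", "pos", "ref", "alt", "mean_pct", "sd_pct",
    "max_pct", "band_lo", "band_hi"
  )]
  utils::write.table(sv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname classify_svs
#' @export
sv_keys <- function(x) {
  stopifnot(inherits(x, "tas_sv_catalog"))
  with(x[x$is_sv, ], hyp_key(chrom, pos, ref, alt))
}
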