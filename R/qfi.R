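#' qPCR calibration curve for absolute template quantification
#'
#' Fits the standard least-squares calibration line of quantification cycle
#' (Cq) against `log10(copies)` from a titration series of high-quality
#' genomic DNA (the reference assay uses a 5-fold series from 50 ng down to
#' 16 pg). Amplification efficiency is `10^(-1/slope) - 1` (1.0 for perfect
#' doubling, slope -3.32 cycles per decade).
#'
#' @param mass_ng Standard input masses in ng.
#' @param cq Measured Cq per standard.
#' @param copies_per_ng Haploid genome copies per ng of DNA (default 303,
#'   i.e. ~3.3 pg per haploid genome).
#' @return A `tas_calibration_curve` with `slope`, `intercept` (Cq at one
#'   copy), `r_squared`, `efficiency` and `copies_per_ng`.
#' @export
fit_calibration <- function(mass_ng, cq, copies_per_ng = 303) {
  keep <- !is.na(cq)
  mass_ng <- mass_ng[keep]
  cq <- cq[keep]
  if (length(mass_ng) < 3) stop("need at least 3 detected standards")
  lc <- log10(mass_ng * copies_per_ng)
  if (diff(range(lc)) < 1e-9) stop("standards are rank-deficient (one mass)")
  if (diff(range(lc)) < 2) {
    warning("standards span less than 2 logs; calibration may be unstable")
  }
  if (any(diff(cq[order(mass_ng)]) > 0)) {
    warning("Cq is not monotone decreasing with mass; fitting anyway")
  }
  fit <- stats::lm(cq ~ lc)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) warning("non-negative slope: invalid amplification")
  tss <- sum((cq - mean(cq))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  structure(
    list(
      slope = slope, intercept = unname(stats::coef(fit)[1]),
      r_squared = r2,
      efficiency = 10^(-1 / slope) - 1,
      copies_per_ng = copies_per_ng, n_standards = length(cq)
    ),
    class = "tas_calibration_curve"
  )
}

#' @export
print.tas_calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<tas_calibration_curve> slope %.3f Cq/log10, intercept %.2f, eff %.1f%%, R^2 %.4f\n",
    x$slope, x$intercept, 100 * x$efficiency, x$r_squared
  ))
  invisible(x)
}

#' Quantitative functional index (QFI) of a DNA sample
#'
#' The QFI is the percentage of input DNA templates that are actually
#' PCR-amplifiable: amplifiable copies are read off the calibration curve
#' from the sample Cq and divided by the copies expected from the
#' spectrophotometric input mass. Samples with no Cq by the final cycle are
#' `UNDETECTABLE`; detected samples pass qualification when QFI exceeds the
#' gate (default 3%) and are otherwise `MEASURABLE_LOW`. QFI above 100%
#' indicates a calibration anomaly and is flagged, not clipped.
#'
#' @param sample_id Sample identifiers.
#' @param cq Measured Cq per sample; `NA` means not detected by the final
#'   cycle (the assay runs 50 cycles).
#' @param curve A [fit_calibration()] result.
#' @param input_ng Input mass per reaction in ng (default 5).
#' @param gate_pct QFI pass threshold in percent (default 3, strict `>`).
#' @return A data.frame of class `tas_qfi_result`: `sample_id`, `cq`,
#'   `amplifiable_copies`, `expected_copies`, `qfi_percent`, `tier`
#'   (`PASS`, `MEASURABLE_LOW`, `UNDETECTABLE`) and an `anomaly` flag.
#' @export
compute_qfi <- function(sample_id, cq, curve, input_ng = 5, gate_pct = 3) {
  stopifnot(inherits(curve, "tas_calibration_curve"), input_ng > 0)
  amp <- 10^((cq - curve$intercept) / curve$slope)
  expected <- input_ng * curve$copies_per_ng
  qfi <- 100 * amp / expected
  qfi[is.na(cq)] <- 0
  ## strict > gate, with an epsilon so a sample computing to the gate value
  ## up to floating-point dust does not pass
  tier <- ifelse(is.na(cq), "UNDETECTABLE",
    ifelse(qfi > gate_pct + 1e-9, "PASS", "MEASURABLE_LOW")
  )
  structure(
    data.frame(
      sample_id = sample_id, cq = cq, amplifiable_copies = ifelse(
        is.na(cq), 0, amp
      ),
      expected_copies = expected, qfi_percent = qfi, tier = tier,
      anomaly = !is.na(cq) & qfi > 100,
      stringsAsFactors = FALSE
    ),
    class = c("tas_qfi_result", "data.frame"), gate_pct = gate_pct
  )
}

#' QFI-stratified inter-platform concordance at hotspot hypotheses
#'
#' For each QFI tier, tabulates per-(sample, hotspot) agreement between the
#' sequencing panel and a reference platform whose calls are taken as
#' truth: TP/FP/FN/TN where the panel has usable coverage, `LOW_COVERAGE`
#' below `low_coverage_reads`, and `NO_COVERAGE` where the panel produced
#' no reads (including sample-hotspot pairs absent from the panel data).
#' Every tier's counts total `n_samples_in_tier * n_hotspots`.
#'
#' @param qfi A [compute_qfi()] result covering every sample.
#' @param calls Data.frame with one row per observed (sample, hotspot):
#'   `sample_id`, `chrom`, `pos`, `ref`, `alt`, `depth`, `call` (logical
#'   panel call), `truth` (logical reference-platform call).
#' @param hotspots Data.frame of hotspot hypotheses (`chrom`, `pos`, `ref`,
#'   `alt`).
#' @param low_coverage_reads Depth below which a position is
#'   `LOW_COVERAGE` (default 100).
#' @return A data.frame: one row per tier with the six category counts and
#'   `total`.
#' @export
stratify_concordance <- function(qfi, calls, hotspots,
                                 low_coverage_reads = 100) {
  stopifnot(inherits(qfi, "tas_qfi_result"))
  hk <- hyp_key(hotspots$chrom, hotspots$pos, hotspots$ref, hotspots$alt)
  full <- expand.grid(
    sample_id = qfi$sample_id, key = hk,
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  calls$key <- hyp_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  dropped <- !calls$key %in% hk | !calls$sample_id %in% qfi$sample_id
  if (any(dropped)) {
    message(
      sum(dropped),
      " call rows outside the hotspot set or QFI cohort were excluded"
    )
    calls <- calls[!dropped, , drop = FALSE]
  }
  m <- merge(full, calls[c("sample_id", "key", "depth", "call", "truth")],
    by = c("sample_id", "key"), all.x = TRUE
  )
  m$truth[is.na(m$truth)] <- FALSE # no reference call recorded => wild type
  status <- ifelse(
    is.na(m$depth) | m$depth == 0, "NO_COVERAGE",
    ifelse(m$depth < low_coverage_reads, "LOW_COVERAGE",
      ifelse(m$call & m$truth, "TP",
        ifelse(m$call & !m$truth, "FP",
          ifelse(!m$call & m$truth, "FN", "TN")
        )
      )
    )
  )
  tier <- qfi$tier[match(m$sample_id, qfi$sample_id)]
  lv <- c("TP", "TN", "FP", "FN", "LOW_COVERAGE", "NO_COVERAGE")
  tiers <- c("PASS", "MEASURABLE_LOW", "UNDETECTABLE")
  tab <- table(
    factor(tier, levels = tiers),
    factor(status, levels = lv)
  )
  out <- as.data.frame.matrix(tab)
  out <- cbind(tier = rownames(out), out, total = rowSums(out))
  rownames(out) <- NULL
  out
}

#' Exact association between QFI tier and detection status
#'
#' Fisher's exact test on an R x C contingency table of QFI tiers against
#' mutation-detection status (complete enumeration for small tables, via
#' [stats::fisher.test()]).
#'
#' @param table Matrix of non-negative counts, at least 2 x 2.
#' @return Exact p-value.
#' @export
tier_association <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || sum(table) == 0) {
    stop("counts must be non-negative and not all zero")
  }
  if (nrow(table) < 2 || ncol(table) < 2) stop("need at least a 2x2 table")
  stats::fisher.test(table)$p.value
}
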