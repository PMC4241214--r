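#' F-measure of a variant-calling operating point
#'
#' Harmonic mean of sensitivity and positive predictive value, the standard
#' single-number summary when positives are rare (most panel positions are
#' wild type).
#'
#' @param sens,ppv Values in `[0, 1]`.
#' @return `2 * sens * ppv / (sens + ppv)`; 0 when both are 0.
#' @export
f_measure <- function(sens, ppv) {
  stopifnot(all(sens >= 0 & sens <= 1), all(ppv >= 0 & ppv <= 1))
  out <- ifelse(sens + ppv == 0, 0, 2 * sens * ppv / (sens + ppv))
  out
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion, by inversion of the
#' binomial tail probabilities via beta quantiles. The lower bound is 0 when
#' there are no successes and the upper bound 100 when every trial
#' succeeds. Returned in percent.
#'
#' @param successes,trials Non-negative integers, `successes <= trials`,
#'   `trials >= 1`.
#' @param conf Two-sided confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)` in percent.
#' @examples
#' clopper_pearson(18, 23) # c(56.3, 92.5) to one decimal
#' @export
clopper_pearson <- function(successes, trials, conf = 0.95) {
  stopifnot(
    trials >= 1, successes >= 0, successes <= trials,
    conf > 0, conf < 1
  )
  a <- (1 - conf) / 2
  lower <- if (successes == 0) 0 else
    stats::qbeta(a, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else
    stats::qbeta(1 - a, successes + 1, trials - successes)
  c(lower = 100 * lower, upper = 100 * upper)
}

#' Two-by-two confusion table with exact confidence intervals
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @param conf Confidence level for the Clopper-Pearson intervals.
#' @return A `tas_confusion_table` with sensitivity, PPV, f-measure and
#'   percent-scale exact CIs for sensitivity and PPV.
#' @export
confusion_table <- function(tp, fp, fn, tn, conf = 0.95) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  structure(
    list(
      tp = tp, fp = fp, fn = fn, tn = tn, sensitivity = sens, ppv = ppv,
      f_measure = if (!is.na(sens) && !is.na(ppv)) f_measure(sens, ppv)
      else NA_real_,
      ci_sensitivity = if (tp + fn > 0) clopper_pearson(tp, tp + fn, conf)
      else c(lower = NA_real_, upper = NA_real_),
      ci_ppv = if (tp + fp > 0) clopper_pearson(tp, tp + fp, conf)
      else c(lower = NA_real_, upper = NA_real_)
    ),
    class = "tas_confusion_table"
  )
}

#' @export
print.tas_confusion_table <- function(x, ...) {
  cat(sprintf(
    "<tas_confusion_table> TP %d FP %d FN %d TN %d | sens %.1f%% (%.1f, %.1f) PPV %.1f%% (%.1f, %.1f) f %.3f\n",
    x$tp, x$fp, x$fn, x$tn, 100 * x$sensitivity, x$ci_sensitivity[1],
    x$ci_sensitivity[2], 100 * x$ppv, x$ci_ppv[1], x$ci_ppv[2], x$f_measure
  ))
  invisible(x)
}

#' Joint two-platform variant calling by percent variant
#'
#' Restricted to hypotheses covered (after each platform's own depth
#' filtering) on both platforms, a positive is predicted when the percent
#' variant strictly exceeds the platform threshold on *both* platforms.
#' Platform-private artifacts — signal on one platform, zero on the other —
#' are thereby suppressed even at permissive thresholds.
#'
#' @param pct_a,pct_b Percent-variant vectors over the common hypotheses.
#' @param t_a,t_b Percent thresholds (strict `>`).
#' @return Logical vector of joint positives.
#' @export
joint_call <- function(pct_a, pct_b, t_a, t_b) {
  stopifnot(length(pct_a) == length(pct_b))
  if (length(pct_a) == 0) {
    warning("no common hypotheses between platforms")
    return(logical(0))
  }
  pct_a > t_a & pct_b > t_b
}

#' Exhaustive joint-threshold f-measure optimization
#'
#' Evaluates the f-measure against a truth set over the full Cartesian grid
#' of per-platform percent thresholds and reports the matrix and its
#' deterministic argmax (ties broken towards the lexicographically lowest
#' `(t_a, t_b)`, i.e. the most sensitive optimum). Passing `grid_b = NULL`
#' gives single-platform optimization on platform A alone.
#'
#' @param pct_a,pct_b Percent variants over the common hypotheses.
#' @param truth Logical vector: true-variant label per hypothesis.
#' @param grid_a,grid_b Ascending percent-threshold grids (default 0 to 50
#'   by 0.5).
#' @return A `tas_joint_grid`: `grid_a`, `grid_b`, `f_matrix`, `argmax`
#'   `(t_a, t_b)`, `f_max`, and the confusion counts at the argmax.
#' @export
grid_optimize <- function(pct_a, pct_b, truth,
                          grid_a = seq(0, 50, by = 0.5),
                          grid_b = seq(0, 50, by = 0.5)) {
  stopifnot(length(pct_a) == length(truth), length(pct_b) == length(truth))
  if (!any(truth)) stop("truth set is empty")
  single <- is.null(grid_b)
  if (single) grid_b <- -Inf
  grid_a <- sort(grid_a) # the attained optimum is order-invariant
  grid_b <- sort(grid_b)
  ga <- length(grid_a)
  gb <- length(grid_b)
  ## cell (i, j): number of grid_a values strictly below pct_a (resp. b);
  ## a hypothesis is positive at (t_i, t_j) iff i <= ka and j <= kb, so the
  ## positive count at each pair is a reverse 2-D cumulative sum.
  ka <- findInterval(pct_a, grid_a, left.open = TRUE)
  kb <- findInterval(pct_b, grid_b, left.open = TRUE)
  cum2 <- function(sel) {
    m <- matrix(0, ga + 1, gb + 1)
    tb <- table(factor(ka[sel], levels = 0:ga), factor(kb[sel], levels = 0:gb))
    m[] <- tb
    rc <- apply(apply(m, 2, function(col) rev(cumsum(rev(col)))), 1,
      function(row) rev(cumsum(rev(row)))
    )
    t(rc)[-1, -1, drop = FALSE] # positives at (t_i, t_j), i,j >= 1
  }
  tp <- cum2(truth)
  fp <- cum2(!truth)
  p <- sum(truth)
  fn <- p - tp
  fmat <- ifelse(2 * tp + fp + fn == 0, 0, 2 * tp / (2 * tp + fp + fn))
  idx <- which(fmat == max(fmat), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  i <- idx[1, 1]
  j <- idx[1, 2]
  structure(
    list(
      grid_a = grid_a, grid_b = if (single) NULL else grid_b,
      f_matrix = fmat, argmax = c(t_a = grid_a[i], t_b = grid_b[j]),
      f_max = fmat[i, j],
      counts = list(
        tp = tp[i, j], fp = fp[i, j], fn = fn[i, j],
        tn = length(truth) - tp[i, j] - fp[i, j] - fn[i, j]
      )
    ),
    class = "tas_joint_grid"
  )
}

#' @export
print.tas_joint_grid <- function(x, ...) {
  cat(sprintf(
    "<tas_joint_grid> f_max %.3f at (t_a = %.1f%%, t_b = %s)\n",
    x$f_max, x$argmax[1],
    if (is.null(x$grid_b)) "single-platform" else sprintf("%.1f%%", x$argmax[2])
  ))
  invisible(x)
}

#' Confirmation workflow with relaxed primary thresholds
#'
#' Re-calls the primary sample at thresholds relaxed multiplicatively on the
#' log-score scale (`t -> (1 - relax_fraction) t`), then keeps only
#' candidates whose percent variant on the confirmation platform is at
#' least `confirm_threshold`. Candidates without a confirmation measurement
#' are reported as unconfirmable and excluded from the confusion counts.
#' When a truth key set is supplied, a [confusion_table()] over the
#' sample's evaluated hypotheses is attached.
#'
#' @param sample Primary-platform [sample_table()] with scores.
#' @param pair The sample's primary `tas_threshold_pair`.
#' @param confirm_pct Named numeric vector: percent variant on the
#'   confirmation platform, named by hypothesis key
#'   (`chrom:pos:ref:alt`).
#' @param relax_fraction Fractional relaxation in `[0, 1)` (default 0.2).
#' @param confirm_threshold Confirmation percent threshold (`>=`,
#'   default 1).
#' @param sv_catalog Optional systematic-variant blacklist.
#' @param truth Optional character vector of true-variant hypothesis keys.
#' @return List with `candidates`, `confirmed`, `unconfirmable` (key
#'   vectors) and, when truth is given, `confusion`.
#' @export
confirm_workflow <- function(sample, pair, confirm_pct, relax_fraction = 0.2,
                             confirm_threshold = 1, sv_catalog = NULL,
                             truth = NULL) {
  stopifnot(
    relax_fraction >= 0, relax_fraction < 1, confirm_threshold >= 0,
    inherits(pair, "tas_threshold_pair"), pair$status == "PASS"
  )
  relaxed <- threshold_pair(
    (1 - relax_fraction) * pair$t_gc_at,
    (1 - relax_fraction) * pair$t_other
  )
  cand <- call_variants(sample, relaxed, sv_catalog)
  keys <- hyp_key(cand$chrom, cand$pos, cand$ref, cand$alt)
  has_conf <- keys %in% names(confirm_pct)
  unconfirmable <- keys[!has_conf]
  keys <- keys[has_conf]
  confirmed <- keys[confirm_pct[keys] >= confirm_threshold]
  out <- list(
    candidates = c(keys, unconfirmable), confirmed = confirmed,
    unconfirmable = unconfirmable
  )
  if (!is.null(truth)) {
    universe <- setdiff(
      hyp_key(sample$chrom, sample$pos, sample$ref, sample$alt),
      unconfirmable
    )
    truth <- intersect(truth, universe)
    tp <- sum(confirmed %in% truth)
    out$confusion <- confusion_table(
      tp = tp, fp = length(confirmed) - tp, fn = length(truth) - tp,
      tn = length(universe) - length(union(confirmed, truth))
    )
  }
  out
}
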