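#' Reference Poisson variant score
#'
#' A pluggable stand-in scorer on the log scale used throughout the
#' thresholding machinery: the score is `-log10` of the Poisson upper-tail
#' probability of seeing at least `alt_depth` alternate reads when the
#' expected artifactual count is `depth * error_rate`. It is monotone
#' increasing in `alt_depth` at fixed depth, 0 when `alt_depth = 0`, and
#' `NA` (flagged) at uncovered positions. Any caller producing a continuous
#' log-scale score can be substituted; the threshold search is agnostic to
#' the scorer.
#'
#' @param depth,alt_depth Non-negative integer read counts (vectors).
#' @param error_rate Per-read background substitution rate in `(0, 1)`.
#' @return Numeric score vector (`-log10` tail probability).
#' @examples
#' reference_score(1000, 10, error_rate = 0.001)
#' @export
reference_score <- function(depth, alt_depth, error_rate = 0.01) {
  stopifnot(error_rate > 0, error_rate < 1)
  if (any(alt_depth > depth, na.rm = TRUE)) stop("alt_depth exceeds depth")
  lam <- depth * error_rate
  lp <- stats::ppois(alt_depth - 1, lam, lower.tail = FALSE, log.p = TRUE)
  score <- -lp / log(10)
  score[alt_depth == 0] <- 0
  score[depth == 0] <- NA_real_
  score
}

#' SNP-rediscovery constraints for threshold selection
#'
#' The three cohort-level acceptability constraints a candidate threshold
#' pair must satisfy: a germline-dominated call rate of 0.36 to 1.5 variants
#' per kb, at least 75% of calls annotated in public resources (a surrogate
#' for PPV), and a Ti/Tv ratio between 1.58 and 4.53. The pair closest to
#' the fresh-frozen default (6, 6) among the feasible set is selected.
#'
#' @param panel_kb Panel size in kb (positions / 1000).
#' @param calls_per_kb_range,titv_range Closed intervals.
#' @param min_pct_annotated Percent-annotated floor.
#' @param default_pair Reference threshold pair for the distance criterion.
#' @return A `tas_constraint_set`.
#' @export
constraint_set <- function(panel_kb, calls_per_kb_range = c(0.36, 1.5),
                           min_pct_annotated = 75,
                           titv_range = c(1.58, 4.53),
                           default_pair = c(6, 6)) {
  stopifnot(panel_kb > 0, length(default_pair) == 2)
  structure(
    list(
      panel_kb = panel_kb, calls_per_kb_range = calls_per_kb_range,
      min_pct_annotated = min_pct_annotated, titv_range = titv_range,
      default_pair = default_pair
    ),
    class = "tas_constraint_set"
  )
}

#' Callset QC metrics
#'
#' @param calls Data.frame of called hypotheses with at least `chrom`,
#'   `pos`, `ref`, `alt`.
#' @param annotations A [annotation_set()] or `NULL`.
#' @param panel_kb Panel size in kb.
#' @return List with `n_calls`, `calls_per_kb`, `pct_annotated`, `titv`
#'   (all `NA` for an empty call set, which fails any constraint check).
#' @export
qc_metrics <- function(calls, annotations, panel_kb) {
  stopifnot(panel_kb > 0)
  n <- nrow(calls)
  if (n == 0) {
    return(list(
      n_calls = 0L, calls_per_kb = NA_real_,
      pct_annotated = NA_real_, titv = NA_real_
    ))
  }
  ann <- is_annotated(calls$chrom, calls$pos, calls$ref, calls$alt,
    annotations
  )
  list(
    n_calls = n, calls_per_kb = n / panel_kb,
    pct_annotated = 100 * mean(ann),
    titv = titv_ratio(calls$ref, calls$alt)
  )
}

## internal: constraint check on the metric triple
constraints_ok <- function(cpk, pct_ann, titv, cs) {
  !is.na(cpk) & cpk >= cs$calls_per_kb_range[1] &
    cpk <= cs$calls_per_kb_range[2] &
    !is.na(pct_ann) & pct_ann >= cs$min_pct_annotated &
    is.finite(titv) & titv >= cs$titv_range[1] & titv <= cs$titv_range[2]
}

#' Two-dimensional adaptive threshold search
#'
#' Evaluates every pair `(t_gc_at, t_other)` on an evenly spaced log-score
#' grid. A hypothesis is called when its score is at least the threshold
#' for its substitution class (GC>AT transitions versus everything else;
#' the two thresholds are independent because FFPE deamination inflates only
#' the GC>AT background). Feasible pairs satisfy all three
#' [constraint_set()] constraints; among them the pair minimizing Euclidean
#' distance to the default `(6, 6)` is returned, with ties broken towards
#' the smaller `t_gc_at` then smaller `t_other` (favoring sensitivity).
#' When no pair is feasible the sample fails threshold qualification.
#'
#' @param sample A [sample_table()] with scores (apply [depth_filter()]
#'   first; the constraint metrics are computed over the hypotheses that
#'   survive it, per sample).
#' @param annotations A [annotation_set()].
#' @param constraints A [constraint_set()].
#' @param grid List with `min`, `max`, `step` on the log-score scale
#'   (default 2 to 20 by 0.5).
#' @return A `tas_threshold_pair`: `t_gc_at`, `t_other`, the QC `metrics`
#'   achieved, `status` (`"PASS"` or `"QUALIFICATION_FAIL"`), `n_feasible`,
#'   and the grid used.
#' @export
grid_search <- function(sample, annotations, constraints,
                        grid = list(min = 2, max = 20, step = 0.5)) {
  stopifnot(inherits(constraints, "tas_constraint_set"))
  if (is.null(grid$step)) grid$step <- 0.5
  if (grid$min >= grid$max) stop("grid$min must be below grid$max")
  thr <- seq(grid$min, grid$max, by = grid$step)
  fail <- function(reason) {
    structure(
      list(
        t_gc_at = NA_real_, t_other = NA_real_, metrics = NULL,
        status = "QUALIFICATION_FAIL", reason = reason, n_feasible = 0L,
        grid = grid
      ),
      class = "tas_threshold_pair"
    )
  }
  if (nrow(sample) == 0) {
    return(fail("empty sample table"))
  }
  keep <- !is.na(sample$score)
  s <- sample[keep, , drop = FALSE]
  if (nrow(s) == 0) {
    return(fail("no scored hypotheses"))
  }
  cls <- classify_substitution(s$ref, s$alt)
  ann <- is_annotated(s$chrom, s$pos, s$ref, s$alt, annotations)
  ti <- cls$titv == "TRANSITION"
  gc <- cls$gc_at
  ## per-class cumulative counts over single thresholds; pair metrics are
  ## additive across the two disjoint classes
  count_ge <- function(x, w = NULL) {
    if (is.null(w)) {
      vapply(thr, function(t) sum(x >= t), 0)
    } else {
      vapply(thr, function(t) sum(w[x >= t]), 0)
    }
  }
  sg <- s$score[gc]
  so <- s$score[!gc]
  n_g <- count_ge(sg)
  ann_g <- count_ge(sg, ann[gc]) # GC>AT hypotheses are all transitions
  n_o <- count_ge(so)
  ann_o <- count_ge(so, ann[!gc])
  ti_o <- count_ge(so, ti[!gc])
  tv_o <- n_o - ti_o
  n_mat <- outer(n_g, n_o, `+`)
  cpk <- n_mat / constraints$panel_kb
  pct_ann <- 100 * outer(ann_g, ann_o, `+`) / n_mat
  titv <- outer(n_g, ti_o, `+`) / outer(rep(0, length(thr)), tv_o, `+`)
  feas <- constraints_ok(cpk, pct_ann, titv, constraints) & n_mat > 0
  if (!any(feas)) {
    return(fail("no threshold pair satisfies all constraints"))
  }
  idx <- which(feas, arr.ind = TRUE)
  tg <- thr[idx[, 1]]
  to <- thr[idx[, 2]]
  dp <- constraints$default_pair
  d2 <- (tg - dp[1])^2 + (to - dp[2])^2
  best <- order(d2, tg, to)[1]
  i <- idx[best, 1]
  j <- idx[best, 2]
  structure(
    list(
      t_gc_at = thr[i], t_other = thr[j],
      metrics = list(
        n_calls = n_mat[i, j], calls_per_kb = cpk[i, j],
        pct_annotated = pct_ann[i, j], titv = titv[i, j]
      ),
      status = "PASS", reason = NULL, n_feasible = sum(feas), grid = grid
    ),
    class = "tas_threshold_pair"
  )
}

#' @export
print.tas_threshold_pair <- function(x, ...) {
  if (x$status == "PASS") {
    cat(sprintf(
      "<tas_threshold_pair> (GC>AT %.2f, other %.2f) PASS: %d calls, %.2f/kb, %.1f%% annotated, Ti/Tv %.2f\n",
      x$t_gc_at, x$t_other, x$metrics$n_calls, x$metrics$calls_per_kb,
      x$metrics$pct_annotated, x$metrics$titv
    ))
  } else {
    cat("<tas_threshold_pair> QUALIFICATION_FAIL:", x$reason, "\n")
  }
  invisible(x)
}

#' Manually specified threshold pair
#'
#' Wraps fixed thresholds (e.g. the fresh-frozen default `(6, 6)`) in the
#' object [call_variants()] expects.
#'
#' @param t_gc_at,t_other Log-score thresholds.
#' @return A passing `tas_threshold_pair`.
#' @export
threshold_pair <- function(t_gc_at, t_other) {
  structure(
    list(
      t_gc_at = t_gc_at, t_other = t_other, metrics = NULL,
      status = "PASS", reason = NULL, n_feasible = NA_integer_, grid = NULL
    ),
    class = "tas_threshold_pair"
  )
}

#' Call variants at a threshold pair
#'
#' A hypothesis is called when `score >= t_gc_at` (GC>AT class) or
#' `score >= t_other` (all other substitutions). Hypotheses present in the
#' systematic-variant catalog are removed from the call set when one is
#' supplied.
#'
#' @param sample A [sample_table()].
#' @param pair A passing `tas_threshold_pair`.
#' @param sv_catalog Optional [classify_svs()] result (or a character vector
#'   of hypothesis keys) to blacklist.
#' @return The subset of `sample` rows that are called.
#' @export
call_variants <- function(sample, pair, sv_catalog = NULL) {
  stopifnot(inherits(pair, "tas_threshold_pair"))
  if (pair$status != "PASS") {
    stop("cannot call variants with a QUALIFICATION_FAIL threshold pair")
  }
  gc <- is_gc_at(sample$ref, sample$alt)
  thr <- ifelse(gc, pair$t_gc_at, pair$t_other)
  called <- !is.na(sample$score) & sample$score >= thr
  if (!is.null(sv_catalog)) {
    keys <- if (inherits(sv_catalog, "tas_sv_catalog")) {
      sv_keys(sv_catalog)
    } else {
      as.character(sv_catalog)
    }
    called <- called &
      !(hyp_key(sample$chrom, sample$pos, sample$ref, sample$alt) %in% keys)
  }
  out <- sample[called, , drop = FALSE]
  class(out) <- class(sample)
  out
}
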