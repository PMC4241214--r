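#' Classify base substitutions
#'
#' Every single-nucleotide hypothesis is classified on two axes: whether it is
#' a GC>AT transition (G>A or C>T, the substitution class inflated by formalin
#' deamination in FFPE DNA) and whether it is a transition or a transversion.
#' Both classifications are on the reference plus strand; the GC>AT label
#' pairs G>A with C>T by definition, with no further strand collapsing.
#'
#' @param ref,alt Character vectors of single bases in `A`, `C`, `G`, `T`.
#'   Recycled to a common length; `ref[i] != alt[i]` is required.
#' @return A data.frame with one row per hypothesis and columns
#'   `gc_at` (logical), `class` (`"GC_AT"` or `"OTHER"`) and
#'   `titv` (`"TRANSITION"` or `"TRANSVERSION"`).
#' @examples
#' classify_substitution(c("C", "A", "A"), c("T", "G", "C"))
#' @export
classify_substitution <- function(ref, alt) {
  n <- max(length(ref), length(alt))
  ref <- rep_len(as.character(ref), n)
  alt <- rep_len(as.character(alt), n)
  bases <- c("A", "C", "G", "T")
  if (!all(ref %in% bases) || !all(alt %in% bases)) {
    stop("ref and alt must be single bases in {A, C, G, T}")
  }
  if (any(ref == alt)) {
    stop("alt must differ from ref for every hypothesis")
  }
  gc_at <- (ref == "G" & alt == "A") | (ref == "C" & alt == "T")
  ti <- paste0(ref, alt) %in% c("AG", "GA", "CT", "TC")
  data.frame(
    gc_at = gc_at,
    class = ifelse(gc_at, "GC_AT", "OTHER"),
    titv = ifelse(ti, "TRANSITION", "TRANSVERSION"),
    stringsAsFactors = FALSE
  )
}

#' @rdname classify_substitution
#' @export
is_gc_at <- function(ref, alt) classify_substitution(ref, alt)$gc_at

#' @rdname classify_substitution
#' @export
is_transition <- function(ref, alt) {
  classify_substitution(ref, alt)$titv == "TRANSITION"
}

#' Transition/transversion ratio of a call set
#'
#' Ti/Tv is a standard callset-quality heuristic: germline SNV sets are
#' expected to be transition-rich. Returns `Inf` when there are transitions
#' but no transversions and `NaN` for an empty call set.
#'
#' @param ref,alt Base vectors as in [classify_substitution()].
#' @return Ratio of transition calls to transversion calls.
#' @export
titv_ratio <- function(ref, alt) {
  if (length(ref) == 0) {
    return(NaN)
  }
  ti <- is_transition(ref, alt)
  sum(ti) / sum(!ti)
}

## internal: unique hypothesis key
hyp_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
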