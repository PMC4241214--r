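#' Annotation membership sets
#'
#' An annotation set records which hypotheses are present in a public
#' variant resource (dbSNP- or COSMIC-style), keyed exactly by
#' `(chrom, pos, ref, alt)`. Membership is a surrogate for "previously
#' observed variant" and drives both the systematic-variant exclusion rule
#' and the percent-annotated constraint of the adaptive threshold search.
#'
#' @param df Data.frame with columns `chrom`, `pos`, `ref`, `alt` and an
#'   optional `source` column.
#' @param source_label Label used when `df` lacks a `source` column.
#' @return Object of class `tas_annotation_set`.
#' @export
annotation_set <- function(df, source_label = "annotation") {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(df)))
  classify_substitution(df$ref, df$alt)
  keys <- unique(hyp_key(df$chrom, df$pos, df$ref, df$alt))
  src <- if (!is.null(df$source)) unique(df$source) else source_label
  structure(list(keys = keys, source_label = src),
    class = "tas_annotation_set"
  )
}

#' @rdname annotation_set
#' @param path 4/5-column TSV (`chrom pos ref alt [source]`), with header.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = list(
    chrom = "character", ref = "character", alt = "character"
  ))
  annotation_set(df)
}

#' @rdname annotation_set
#' @param ... `tas_annotation_set` objects to union.
#' @export
union_annotations <- function(...) {
  sets <- list(...)
  stopifnot(all(vapply(sets, inherits, TRUE, "tas_annotation_set")))
  structure(
    list(
      keys = unique(unlist(lapply(sets, `[[`, "keys"))),
      source_label = unlist(lapply(sets, `[[`, "source_label"))
    ),
    class = "tas_annotation_set"
  )
}

#' Exact-key annotation lookup
#'
#' @param chrom,pos,ref,alt Hypothesis fields (vectors, recycled).
#' @param annotations A [annotation_set()] (or `NULL`: everything
#'   unannotated).
#' @return Logical vector.
#' @export
is_annotated <- function(chrom, pos, ref, alt, annotations) {
  if (is.null(annotations)) {
    return(rep(FALSE, max(length(chrom), length(pos))))
  }
  stopifnot(inherits(annotations, "tas_annotation_set"))
  hyp_key(chrom, pos, ref, alt) %in% annotations$keys
}

#' @export
print.tas_annotation_set <- function(x, ...) {
  cat(
    "<tas_annotation_set>", length(x$keys), "keys [",
    paste(x$source_label, collapse = ", "), "]\n"
  )
  invisible(x)
}
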