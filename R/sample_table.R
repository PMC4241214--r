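#' Per-sample hypothesis measurement tables
#'
#' The unit of analysis throughout the package is the *hypothesis*: one of
#' the three possible base substitutions at a panel position. A sample table
#' holds one row per measured hypothesis with its sequencing depth,
#' alternate-allele-supporting depth, percent variant (allele fraction x 100)
#' and a log-scale variant-caller score. Positions with zero depth are
#' retained (flagged `no_coverage`) so that low/no-coverage accounting is
#' possible, but they are excluded from all statistics.
#'
#' @param df A data.frame with columns `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `depth`, `alt_depth` and optionally `percent_variant` and
#'   `score`. `percent_variant` is recomputed as `100 * alt_depth / depth`
#'   when absent (and validated to 1e-9 when present).
#' @return The validated data.frame with class `tas_sample_table`, a
#'   `percent_variant` column, and a logical `no_coverage` column.
#' @export
sample_table <- function(df) {
  need <- c("sample_id", "chrom", "pos", "ref", "alt", "depth", "alt_depth")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("sample table is missing columns: ", paste(miss, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (any(df$depth < 0) || any(df$alt_depth < 0)) {
    stop("depth and alt_depth must be non-negative")
  }
  if (any(df$alt_depth > df$depth)) {
    stop("alt_depth cannot exceed depth")
  }
  classify_substitution(df$ref, df$alt) # validates bases
  pv <- ifelse(df$depth > 0, 100 * df$alt_depth / df$depth, NA_real_)
  if (is.null(df$percent_variant)) {
    df$percent_variant <- pv
  } else {
    ok <- is.na(pv) | is.na(df$percent_variant) |
      abs(df$percent_variant - pv) <= 1e-9
    if (!all(ok)) {
      stop("percent_variant inconsistent with alt_depth/depth")
    }
  }
  if (is.null(df$score)) df$score <- NA_real_
  df$no_coverage <- df$depth == 0
  key <- hyp_key(df$chrom, df$pos, df$ref, df$alt)
  if (anyDuplicated(key)) {
    stop("(chrom, pos, ref, alt) must be a unique key within a sample table")
  }
  class(df) <- c("tas_sample_table", "data.frame")
  df
}

#' Median panel depth of a sample
#'
#' The median is taken over distinct genomic positions (hypotheses at the
#' same position share one depth) using the linear-interpolation convention,
#' and excludes zero-depth positions.
#'
#' @param x A [sample_table()].
#' @return Median depth (numeric scalar), `NA` if no covered positions.
#' @export
median_depth <- function(x) {
  pos <- !duplicated(paste(x$chrom, x$pos))
  d <- x$depth[pos & x$depth > 0]
  if (length(d) == 0) {
    return(NA_real_)
  }
  stats::median(d)
}

#' Read and write sample tables in the package TSV dialect
#'
#' Tab-separated, UTF-8, header
#' `sample_id chrom pos ref alt depth alt_depth percent_variant score`,
#' with `.` for missing values. Numeric columns are serialized with `%.17g`
#' so a write/read round trip is bit-exact.
#'
#' @param path File path.
#' @param x A [sample_table()].
#' @return `read_sample_table` returns a [sample_table()];
#'   `write_sample_table` returns `path` invisibly.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, na.strings = ".", colClasses = list(
    sample_id = "character", chrom = "character", ref = "character",
    alt = "character"
  ), stringsAsFactors = FALSE)
  sample_table(df)
}

#' @rdname read_sample_table
#' @export
write_sample_table <- function(x, path) {
  cols <- c(
    "sample_id", "chrom", "pos", "ref", "alt", "depth", "alt_depth",
    "percent_variant", "score"
  )
  out <- x[cols]
  for (cc in c("pos", "depth", "alt_depth", "percent_variant", "score")) {
    v <- out[[cc]]
    out[[cc]] <- ifelse(is.na(v), ".", sprintf("%.17g", v))
  }
  utils::write.table(out, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' VCF 4.2 export and import of sample tables
#'
#' Export writes one record per hypothesis with depth in `FORMAT/DP`,
#' ref/alt depths in `FORMAT/AD` and the variant score in `QUAL`. Import
#' reads the same fields back. I/O is delegated to \pkg{vcfR}; note that
#' `vcfR::write.vcf` gzip-compresses, so `path` should end in `.vcf.gz`.
#'
#' @param x A [sample_table()].
#' @param path Output (input) VCF path.
#' @param sample_id Sample name to assign on import.
#' @return `write_sample_vcf` returns `path` invisibly; `read_sample_vcf`
#'   returns a [sample_table()] (score taken from `QUAL`).
#' @export
write_sample_vcf <- function(x, path) {
  o <- order(x$chrom, x$pos, x$ref, x$alt)
  x <- x[o, , drop = FALSE]
  qual <- ifelse(is.na(x$score), ".", sprintf("%.17g", x$score))
  fix <- cbind(
    CHROM = as.character(x$chrom), POS = as.character(x$pos), ID = ".",
    REF = x$ref, ALT = x$alt, QUAL = qual, FILTER = ".", INFO = "."
  )
  gt <- cbind(
    FORMAT = "DP:AD",
    sprintf("%d:%d,%d", x$depth, x$depth - x$alt_depth, x$alt_depth)
  )
  colnames(gt)[2] <- x$sample_id[1]
  meta <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0(
      "##FORMAT=<ID=AD,Number=R,Type=Integer,",
      "Description=\"Allelic depths\">"
    )
  )
  v <- methods::new(
    methods::getClass("vcfR", where = asNamespace("vcfR")),
    meta = meta, fix = fix, gt = gt
  )
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' @rdname write_sample_vcf
#' @export
read_sample_vcf <- function(path, sample_id = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  dp <- as.integer(vcfR::extract.gt(v, "DP")[, 1])
  ad <- vcfR::extract.gt(v, "AD")[, 1]
  alt_depth <- as.integer(vapply(
    strsplit(ad, ",", fixed = TRUE),
    function(z) z[2], ""
  ))
  if (is.null(sample_id)) sample_id <- colnames(v@gt)[2]
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  sample_table(data.frame(
    sample_id = sample_id, chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]), ref = fix[, "REF"], alt = fix[, "ALT"],
    depth = dp, alt_depth = alt_depth, score = qual,
    stringsAsFactors = FALSE
  ))
}
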