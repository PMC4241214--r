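# Small in-code fixtures shared across test files.

# minimal sample table from parallel vectors; depth defaults high enough to
# clear the default depth filter
toy_table <- function(ref, alt, score, depth = 1000L, alt_depth = NULL,
                      sample_id = "toy", pos = NULL) {
  n <- length(ref)
  if (is.null(pos)) pos <- seq_len(n)
  depth <- rep_len(as.integer(depth), n)
  if (is.null(alt_depth)) alt_depth <- pmin(depth, 50L)
  sample_table(data.frame(
    sample_id = sample_id, chrom = "t1", pos = pos, ref = ref, alt = alt,
    depth = depth, alt_depth = rep_len(as.integer(alt_depth), n),
    score = score, stringsAsFactors = FALSE
  ))
}

# annotation set covering the given rows of a table-like object
toy_annotations <- function(df, idx) {
  annotation_set(df[idx, c("chrom", "pos", "ref", "alt")])
}

# all 12 ordered substitution pairs
all_substitutions <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(ref = b, alt = b, stringsAsFactors = FALSE)
  g[g$ref != g$alt, ]
}
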