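test_that("substitution classification follows the GC>AT and Ti/Tv rules", {
  cl <- classify_substitution(c("C", "G", "A", "A"), c("T", "A", "G", "C"))
  expect_equal(cl$class, c("GC_AT", "GC_AT", "OTHER", "OTHER"))
  expect_equal(cl$titv, c(
    "TRANSITION", "TRANSITION", "TRANSITION",
    "TRANSVERSION"
  ))

  # enumeration over all 12 ordered pairs: 2 GC>AT, 4 transitions,
  # 8 transversions
  g <- all_substitutions()
  cl <- classify_substitution(g$ref, g$alt)
  expect_equal(sum(cl$gc_at), 2)
  expect_equal(sum(cl$titv == "TRANSITION"), 4)
  expect_equal(sum(cl$titv == "TRANSVERSION"), 8)

  expect_error(classify_substitution("N", "A"), "single bases")
  expect_error(classify_substitution("A", "A"), "differ")

  expect_equal(titv_ratio(c("A", "C", "A"), c("G", "T", "C")), 2)
  expect_identical(titv_ratio(character(0), character(0)), NaN)
})

test_that("panel hypothesis counting is 3 per position", {
  expect_equal(count_hypotheses(panel(n_positions = 109302)), 327906)
  expect_equal(count_hypotheses(panel(n_positions = 0)), 0)
  expect_equal(count_hypotheses(panel(n_positions = 7)), 21)
  # from intervals
  p <- panel(data.frame(
    chrom = c("chr1", "chr2"), start = c(10, 0),
    end = c(20, 5)
  ))
  expect_equal(p$n_positions, 15)
  expect_equal(p$size_kb, 0.015)
  expect_error(
    panel(data.frame(chrom = "c", start = 5, end = 5)),
    "half-open"
  )
})

test_that("BED panels import through rtracklayer with coordinates intact", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t110\tamp1", "chr1\t200\t250\tamp2"), bed)
  p <- read_panel_bed(bed)
  expect_equal(p$n_positions, 60)
  expect_equal(p$regions$start, c(100, 200))
  expect_equal(p$regions$end, c(110, 250))
  pos <- bed_interval_positions("chr1", 100, 110)
  expect_equal(pos$pos, 101:110) # 1-based hypothesis coordinates
})

test_that("depth filter applies both the absolute and median-relative rule", {
  s <- toy_table(rep("A", 3), rep("G", 3),
    score = 1,
    depth = c(50L, 200L, 3000L)
  )
  kept <- depth_filter(s) # defaults (100, 0.1); median 200
  expect_equal(sort(kept$depth), c(200, 3000))

  expect_equal(nrow(depth_filter(s, 0, 0)), nrow(s)) # identity
  s0 <- toy_table(rep("A", 3), rep("G", 3),
    score = 1, depth = 0L,
    alt_depth = 0L
  )
  expect_warning(f0 <- depth_filter(s0), "median depth undefined")
  expect_equal(nrow(f0), 0)

  # idempotent and monotone in min_reads
  expect_equal(depth_filter(depth_filter(s))$pos, depth_filter(s)$pos)
  for (mr in c(0, 100, 250, 5000)) {
    expect_true(all(
      depth_filter(s, mr, 0.1)$pos %in% depth_filter(s, 0, 0.1)$pos
    ))
  }
})

test_that("fold-of-median filter keeps the symmetric depth band", {
  s <- toy_table(rep("A", 4), rep("G", 4),
    score = 1,
    depth = c(10L, 100L, 500L, 5000L)
  )
  # interpolated median 300; band [30, 3000]
  expect_equal(sort(fold_of_median_filter(s, 10)$depth), c(100, 500))
  expect_equal(nrow(fold_of_median_filter(s, Inf)), 4)
  sc <- toy_table(rep("A", 3), rep("G", 3), score = 1, depth = 777L)
  expect_equal(nrow(fold_of_median_filter(sc, 10)), 3)
  expect_error(fold_of_median_filter(s, 1), "fold")
})

test_that("coverage uniformity fractions match hand-computed cases", {
  u <- coverage_uniformity(rep(1000, 5))
  expect_equal(u$frac_within_2fold, 1)
  expect_equal(u$frac_within_5fold, 1)

  u <- coverage_uniformity(c(100, 100, 100, 10))
  expect_equal(u$frac_within_2fold, 0.75)
  expect_equal(u$frac_within_5fold, 0.75)

  # median 100: 2-fold band [50, 200] keeps the two 100s; 5-fold band
  # [20, 500] additionally keeps 30 but still excludes 600
  u <- coverage_uniformity(c(100, 100, 30, 600))
  expect_equal(u$frac_within_2fold, 0.5)
  expect_equal(u$frac_within_5fold, 0.75)
  expect_true(u$frac_within_2fold <= u$frac_within_5fold)

  expect_warning(u0 <- coverage_uniformity(c(0, 0)), "undefined")
  expect_true(u0$undefined)
})

test_that("sample tables validate invariants and recompute percent variant", {
  df <- data.frame(
    sample_id = "s", chrom = "c", pos = 1:2, ref = "A", alt = "G",
    depth = c(200L, 0L), alt_depth = c(30L, 0L)
  )
  s <- sample_table(df)
  expect_equal(s$percent_variant, c(15, NA))
  expect_equal(s$no_coverage, c(FALSE, TRUE))
  expect_error(
    sample_table(transform(df, alt_depth = c(300L, 0L))),
    "exceed"
  )
  dup <- rbind(df[1, ], df[1, ])
  dup$pos <- c(1L, 1L)
  expect_error(sample_table(dup), "unique")

  # stored percent must agree with depth ratio to 1e-9
  df$percent_variant <- c(15, NA)
  expect_silent(sample_table(df))
  df$percent_variant <- c(15.001, NA)
  expect_error(sample_table(df), "inconsistent")
})

test_that("TSV dialect round trips bit-exactly and VCF preserves fields", {
  set.seed(7)
  n <- 40
  g <- all_substitutions()[sample.int(12, n, replace = TRUE), ]
  depth <- as.integer(sample(100:5000, n))
  s <- sample_table(data.frame(
    sample_id = "rt", chrom = "chr9", pos = seq_len(n), ref = g$ref,
    alt = g$alt, depth = depth,
    alt_depth = as.integer(floor(depth * runif(n))),
    score = rexp(n) * pi, stringsAsFactors = FALSE
  ))
  tsv <- tempfile(fileext = ".tsv")
  write_sample_table(s, tsv)
  s2 <- read_sample_table(tsv)
  for (cc in c("pos", "depth", "alt_depth", "percent_variant", "score")) {
    expect_identical(as.numeric(s[[cc]]), as.numeric(s2[[cc]]), label = cc)
  }

  vcf <- tempfile(fileext = ".vcf.gz")
  write_sample_vcf(s, vcf)
  s3 <- read_sample_vcf(vcf)
  o1 <- order(s$chrom, s$pos, s$ref, s$alt)
  for (cc in c("chrom", "pos", "ref", "alt", "depth", "alt_depth")) {
    expect_equal(s[[cc]][o1], s3[[cc]], label = cc)
  }
  expect_equal(s$score[o1], s3$score) # QUAL carries the score
})

test_that("median depth uses distinct covered positions", {
  s <- sample_table(data.frame(
    sample_id = "m", chrom = "c", pos = c(1L, 1L, 2L, 3L),
    ref = c("C", "C", "A", "A"), alt = c("T", "G", "G", "C"),
    depth = c(100L, 100L, 300L, 0L), alt_depth = 0L
  ))
  # positions: 100 (once), 300; zero-depth position excluded
  expect_equal(median_depth(s), 200)
})
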