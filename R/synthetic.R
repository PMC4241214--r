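#' Noise profiles for synthetic TAS data
#'
#' A noise profile captures the statistical fingerprint of a library
#' preparation at a given DNA input: the 99th percentile of the background
#' percent variant for GC>AT transitions and for other substitutions (the
#' GC>AT percentile is never below the other — the central FFPE
#' observation), the SD of heterozygous percent-variant measurements, and a
#' negative-binomial depth model with an amplicon-dropout component.
#'
#' @param gc_at_p99,other_p99 Background 99th percentiles, percent.
#' @param het_sd Heterozygote percent-variant SD, percent points.
#' @param depth_median Median sequencing depth (reads).
#' @param depth_size Negative-binomial size (dispersion) parameter.
#' @param dropout_frac Fraction of positions drawn from the low-coverage
#'   dropout component.
#' @return A `tas_noise_profile`.
#' @export
noise_profile <- function(gc_at_p99, other_p99, het_sd, depth_median = 150,
                          depth_size = 8, dropout_frac = 0.07) {
  stopifnot(
    gc_at_p99 >= other_p99, gc_at_p99 >= 0, other_p99 >= 0, het_sd >= 0,
    depth_median > 0, depth_size > 0, dropout_frac >= 0, dropout_frac < 1
  )
  structure(
    list(
      gc_at_p99 = gc_at_p99, other_p99 = other_p99, het_sd = het_sd,
      depth_median = depth_median, depth_size = depth_size,
      dropout_frac = dropout_frac
    ),
    class = "tas_noise_profile"
  )
}

## Calibration anchors: heterozygote SD 5.1 -> 15.6 (FFPE) and 3.0 -> 5.5
## (intact) across the 2000 -> 250 ng titration; GC>AT background 99th
## percentile 2.6 -> 8.4 for FFPE. Intermediate masses interpolate
## geometrically between the stated endpoints.
geo_ladder <- function(lo_2000, hi_250) {
  r <- (hi_250 / lo_2000)^(1 / 3)
  stats::setNames(lo_2000 * r^(0:3), c("2000", "1000", "500", "250"))
}

#' @rdname noise_profile
#' @param kind `"INTACT"` (cell-line DNA) or `"FFPE"`.
#' @param mass_ng DNA input preset: 2000, 1000, 500 or 250 ng.
#' @export
preset_profile <- function(kind = c("FFPE", "INTACT"),
                           mass_ng = c(250, 2000, 1000, 500)) {
  kind <- match.arg(kind)
  mass_ng <- as.character(mass_ng[1])
  if (!mass_ng %in% c("2000", "1000", "500", "250")) {
    stop("mass preset must be one of 2000, 1000, 500, 250 ng")
  }
  if (kind == "FFPE") {
    noise_profile(
      gc_at_p99 = geo_ladder(2.6, 8.4)[[mass_ng]],
      other_p99 = geo_ladder(1.3, 2.0)[[mass_ng]],
      het_sd = geo_ladder(5.1, 15.6)[[mass_ng]]
    )
  } else {
    noise_profile(
      gc_at_p99 = geo_ladder(2.0, 2.7)[[mass_ng]],
      other_p99 = geo_ladder(1.0, 1.4)[[mass_ng]],
      het_sd = geo_ladder(3.0, 5.5)[[mass_ng]]
    )
  }
}

## Background percent variant: zero-inflated exponential whose 99th
## percentile matches the profile anchor (the field reports percentiles,
## not a family; the family is a calibration convenience).
## P(X > q) = (1 - zero_prob) exp(-q / theta) = 0.01 at q = p99.
draw_background <- function(n, p99, zero_prob = 0.5) {
  if (n == 0) {
    return(numeric(0))
  }
  theta <- p99 / log((1 - zero_prob) / 0.01)
  x <- ifelse(
    stats::runif(n) < zero_prob, 0,
    stats::rexp(n, rate = 1 / theta)
  )
  pmin(x, 100)
}

draw_depth <- function(n, profile) {
  drop <- stats::runif(n) < profile$dropout_frac
  d <- stats::rnbinom(n,
    mu = profile$depth_median,
    size = profile$depth_size
  )
  low <- as.integer(stats::runif(n, 0, profile$depth_median / 5))
  out <- ifelse(drop, low, d)
  as.integer(out)
}

## Substitution-class mix for planted germline SNPs: stratified so the
## composition is fixed at 35% GC>AT, 36% other transitions, 29%
## transversions (Ti/Tv ~ 2.45, inside the expected germline range) with
## only the order and the within-class base pair randomized.
draw_snp_classes <- function(n) {
  gc_pairs <- list(c("C", "T"), c("G", "A"))
  other_ti <- list(c("A", "G"), c("T", "C"))
  tv <- list(
    c("A", "C"), c("A", "T"), c("C", "A"), c("C", "G"),
    c("G", "C"), c("G", "T"), c("T", "A"), c("T", "G")
  )
  n_gc <- round(0.35 * n)
  n_ti <- round(0.36 * n)
  grp <- sample(rep(
    c("gc", "ti", "tv"),
    c(n_gc, n_ti, n - n_gc - n_ti)
  ))
  t(vapply(grp, function(g) {
    switch(g,
      gc = gc_pairs[[sample.int(2, 1)]],
      ti = other_ti[[sample.int(2, 1)]],
      tv = tv[[sample.int(8, 1)]]
    )
  }, c("", "")))
}

#' Generate a diploid cohort with planted SNPs and systematic variants
#'
#' Emulates the cohort used for systematic-variant discovery: SNP loci
#' follow Hardy-Weinberg multinomial genotypes with measurement noise (so
#' their cohort (mean, SD) sits on the Hardy-Weinberg parabola), systematic
#' variants show near-constant percent variant in every sample (violating
#' the parabola), and background hypotheses follow the zero-inflated
#' low-percent profile distribution.
#'
#' @param n_samples Cohort size (default 29).
#' @param snp_spec Data.frame with `penetrance` and `annotated` per planted
#'   SNP (default: 200 loci, penetrance uniform on 0.05-0.5, 75%
#'   annotated).
#' @param sv_spec Data.frame with `mean` and `sd` percent per planted
#'   systematic variant (default: 50 loci, mean uniform on 3-20%, sd
#'   uniform on 0.2-1.5).
#' @param n_background Background hypotheses per class pair (default 1000).
#' @param profile A [noise_profile()]; the heterozygote SD and wild-type
#'   noise floor define the cohort's measurement model (default FFPE
#'   250 ng preset).
#' @param sigma_wt Wild-type half-normal noise scale used for SNP loci
#'   (default 0.5 percent).
#' @param seed Integer seed.
#' @return List with `cohort` ([cohort_matrix()]), `annotations`,
#'   `truth` (key vectors `snp`, `sv`, `background`), `model` (the
#'   [measurement_model()] matching the generator), `profile`, `seed`.
#' @export
gen_cohort <- function(n_samples = 29, snp_spec = NULL, sv_spec = NULL,
                       n_background = 1000,
                       profile = preset_profile("FFPE", 250),
                       sigma_wt = 0.5, seed = 1L) {
  stopifnot(n_samples >= 2)
  with_seed(seed, {
    if (is.null(snp_spec)) {
      snp_spec <- data.frame(
        penetrance = stats::runif(200, 0.05, 0.5),
        annotated = stats::runif(200) < 0.75
      )
    }
    if (is.null(sv_spec)) {
      sv_spec <- data.frame(
        mean = stats::runif(50, 3, 20),
        sd = stats::runif(50, 0.2, 1.5)
      )
    }
    n_snp <- nrow(snp_spec)
    n_sv <- nrow(sv_spec)
    model <- measurement_model(
      sigma_wt = sigma_wt,
      sigma_het = profile$het_sd
    )
    pct_snp <- matrix(0, n_snp, n_samples)
    for (i in seq_len(n_snp)) {
      fr <- genotype_frequencies(snp_spec$penetrance[i])[1, ]
      g <- sample.int(3L, n_samples, replace = TRUE, prob = fr)
      pct_snp[i, ] <- draw_percent(g, model)
    }
    pct_sv <- matrix(0, max(n_sv, 0), n_samples)
    for (i in seq_len(n_sv)) {
      pct_sv[i, ] <- pmin(100, pmax(0, stats::rnorm(
        n_samples,
        sv_spec$mean[i], sv_spec$sd[i]
      )))
    }
    n_bg_gc <- n_background
    n_bg_ot <- n_background
    pct_bg <- rbind(
      matrix(draw_background(n_bg_gc * n_samples, profile$gc_at_p99),
        n_bg_gc, n_samples
      ),
      matrix(draw_background(n_bg_ot * n_samples, profile$other_p99),
        n_bg_ot, n_samples
      )
    )
    snp_ra <- draw_snp_classes(n_snp)
    sv_ra <- draw_snp_classes(max(n_sv, 1))[seq_len(n_sv), , drop = FALSE]
    bg_gc_ra <- t(vapply(
      seq_len(n_bg_gc),
      function(i) if (stats::runif(1) < 0.5) c("C", "T") else c("G", "A"),
      c("", "")
    ))
    bg_ot_ra <- draw_snp_classes(2 * n_bg_ot)
    bg_ot_ra <- bg_ot_ra[
      !paste0(bg_ot_ra[, 1], bg_ot_ra[, 2]) %in% c("CT", "GA"), ,
      drop = FALSE
    ][seq_len(n_bg_ot), , drop = FALSE]
    bg_ra <- rbind(bg_gc_ra, bg_ot_ra)
    hyp <- data.frame(
      chrom = "sim1",
      pos = seq_len(n_snp + n_sv + n_bg_gc + n_bg_ot),
      ref = c(snp_ra[, 1], sv_ra[, 1], bg_ra[, 1]),
      alt = c(snp_ra[, 2], sv_ra[, 2], bg_ra[, 2]),
      stringsAsFactors = FALSE
    )
    pct <- rbind(pct_snp, pct_sv, pct_bg)
    depth <- matrix(
      draw_depth(length(pct), profile),
      nrow(pct), n_samples
    )
    keys <- hyp_key(hyp$chrom, hyp$pos, hyp$ref, hyp$alt)
    ann <- annotation_set(
      hyp[seq_len(n_snp), ][snp_spec$annotated, ],
      source_label = "synthetic-dbSNP"
    )
    truth <- list(
      snp = keys[seq_len(n_snp)],
      sv = keys[n_snp + seq_len(n_sv)],
      background = keys[-seq_len(n_snp + n_sv)]
    )
  })
  list(
    cohort = cohort_matrix(pct, hyp, depth), annotations = ann,
    truth = truth, model = model, profile = profile, seed = seed
  )
}

#' Generate a DNA-input titration of single samples
#'
#' For each input-mass preset, emits a scored [sample_table()] emulating a
#' sample with heterozygous germline variants at ~50% variant plus
#' class-specific background noise that grows as input DNA shrinks (FFPE)
#' or only mildly (intact DNA). Read counts are binomial at the generated
#' allele fraction over negative-binomial depths; scores come from
#' [reference_score()].
#'
#' @param masses Input presets among 2000, 1000, 500, 250 ng.
#' @param kind `"FFPE"` or `"INTACT"`.
#' @param n_het Planted heterozygous SNP loci (default 100).
#' @param frac_annotated Fraction of planted SNPs that are annotated
#'   (default 0.85).
#' @param n_background Background hypotheses per class (default 15000).
#' @param panel_kb Nominal panel size in kb for call-rate metrics
#'   (default 100; with `n_het = 100` this gives the ~1 germline variant
#'   per kb a panel expects).
#' @param error_rate Background rate for the reference scorer (default
#'   0.02, the raw substitution noise floor of a deaminated amplicon
#'   library).
#' @param seed Integer seed.
#' @return List with `samples` (named list of [sample_table()]s, one per
#'   preset), `annotations`, `truth` (het keys), `profiles`, `panel_kb`,
#'   `seed`.
#' @export
gen_titration <- function(masses = c(2000, 1000, 500, 250), kind = "FFPE",
                          n_het = 100, frac_annotated = 0.85,
                          n_background = 15000, panel_kb = 100,
                          error_rate = 0.02, seed = 1L) {
  bad <- setdiff(masses, c(2000, 1000, 500, 250))
  if (length(bad)) stop("unknown mass preset: ", paste(bad, collapse = ", "))
  with_seed(seed, {
    het_ra <- draw_snp_classes(n_het)
    bg_gc <- t(vapply(
      seq_len(n_background),
      function(i) if (stats::runif(1) < 0.5) c("C", "T") else c("G", "A"),
      c("", "")
    ))
    bg_ot <- draw_snp_classes(n_background)
    bg_ot_tv <- !paste0(bg_ot[, 1], bg_ot[, 2]) %in%
      c("CT", "GA") # keep non-GC>AT only
    bg_ot <- bg_ot[bg_ot_tv, , drop = FALSE]
    hyp <- data.frame(
      chrom = "sim1",
      pos = seq_len(n_het + nrow(bg_gc) + nrow(bg_ot)),
      ref = c(het_ra[, 1], bg_gc[, 1], bg_ot[, 1]),
      alt = c(het_ra[, 2], bg_gc[, 2], bg_ot[, 2]),
      stringsAsFactors = FALSE
    )
    annotated <- c(
      stats::runif(n_het) < frac_annotated,
      rep(FALSE, nrow(bg_gc) + nrow(bg_ot))
    )
    profiles <- lapply(masses, function(m) preset_profile(kind, m))
    names(profiles) <- as.character(masses)
    is_gc <- is_gc_at(hyp$ref, hyp$alt)
    samples <- lapply(as.character(masses), function(m) {
      pr <- profiles[[m]]
      true_pct <- numeric(nrow(hyp))
      true_pct[seq_len(n_het)] <- pmin(99, pmax(
        1,
        stats::rnorm(n_het, 50, pr$het_sd)
      ))
      bg_idx <- (n_het + 1):nrow(hyp)
      gci <- bg_idx[is_gc[bg_idx]]
      oti <- bg_idx[!is_gc[bg_idx]]
      true_pct[gci] <- draw_background(length(gci), pr$gc_at_p99)
      true_pct[oti] <- draw_background(length(oti), pr$other_p99)
      depth <- draw_depth(nrow(hyp), pr)
      alt <- stats::rbinom(nrow(hyp), depth, true_pct / 100)
      sample_table(data.frame(
        sample_id = sprintf("%s_%sng", tolower(kind), m),
        chrom = hyp$chrom, pos = hyp$pos, ref = hyp$ref, alt = hyp$alt,
        depth = depth, alt_depth = alt,
        score = reference_score(depth, alt, error_rate),
        stringsAsFactors = FALSE
      ))
    })
    names(samples) <- as.character(masses)
    ann <- annotation_set(hyp[annotated, , drop = FALSE],
      source_label = "synthetic-dbSNP"
    )
    truth <- hyp_key(hyp$chrom, hyp$pos, hyp$ref, hyp$alt)[seq_len(n_het)]
  })
  list(
    samples = samples, annotations = ann, truth = truth,
    profiles = profiles, panel_kb = panel_kb, seed = seed
  )
}

#' Generate paired two-platform percent-variant measurements
#'
#' True variants appear on both platforms with correlated percent variants
#' near the identity line; platform-private systematic artifacts carry
#' signal on one platform and exactly zero on the other (the axis-hugging
#' pattern that motivates joint calling); background hypotheses carry small
#' independent noise on each platform.
#'
#' @param n_truth True shared variants (default 150), with expected percent
#'   uniform on `truth_range`.
#' @param n_private_a,n_private_b Platform-private artifacts (default 60
#'   each), percent uniform on `private_range` on their own platform.
#' @param n_background Background hypotheses (default 2000).
#' @param truth_range,private_range Percent ranges.
#' @param noise_sd Measurement SD around the shared expectation (default
#'   1.5 percent points).
#' @param bg_scale Half-normal scale of background noise (default 0.3).
#' @param seed Integer seed.
#' @return List with `data` (data.frame: key, `pct_a`, `pct_b`, `truth`
#'   logical) and `truth`/`private_a`/`private_b` key vectors.
#' @export
gen_two_platform <- function(n_truth = 150, n_private_a = 60,
                             n_private_b = 60, n_background = 2000,
                             truth_range = c(2, 40),
                             private_range = c(2, 15), noise_sd = 1.5,
                             bg_scale = 0.3, seed = 1L) {
  with_seed(seed, {
    exp_truth <- stats::runif(n_truth, truth_range[1], truth_range[2])
    pct_a <- c(
      pmax(0.2, exp_truth + stats::rnorm(n_truth, 0, noise_sd)),
      stats::runif(n_private_a, private_range[1], private_range[2]),
      rep(0, n_private_b),
      abs(stats::rnorm(n_background, 0, bg_scale))
    )
    pct_b <- c(
      pmax(0.2, exp_truth + stats::rnorm(n_truth, 0, noise_sd)),
      rep(0, n_private_a),
      stats::runif(n_private_b, private_range[1], private_range[2]),
      abs(stats::rnorm(n_background, 0, bg_scale))
    )
  })
  n <- n_truth + n_private_a + n_private_b + n_background
  key <- sprintf("sim1:%d:C:T", seq_len(n))
  truth <- c(
    rep(TRUE, n_truth),
    rep(FALSE, n_private_a + n_private_b + n_background)
  )
  list(
    data = data.frame(
      key = key, pct_a = pct_a, pct_b = pct_b,
      truth = truth, stringsAsFactors = FALSE
    ),
    truth = key[truth],
    private_a = key[n_truth + seq_len(n_private_a)],
    private_b = key[n_truth + n_private_a + seq_len(n_private_b)]
  )
}

#' Generate qPCR standards and sample Cq values
#'
#' Standards follow a log-linear calibration line with the requested
#' amplification efficiency; each sample's Cq is shifted by its amplifiable
#' fraction (`Cq = intercept + slope log10(copies x fraction) + noise`).
#' Fraction 0 and reactions that would cross the final cycle (50) come back
#' not detected (`NA` Cq).
#'
#' @param standard_masses Standard masses in ng (default the 5-fold series
#'   50 ng down to 16 pg).
#' @param sample_fractions Amplifiable template fractions in `[0, 1]`.
#' @param efficiency Amplification efficiency in `(0.7, 1.1]` (default 1).
#' @param noise_sd_cq Gaussian Cq noise SD (default 0).
#' @param input_ng Sample input mass (default 5 ng).
#' @param copies_per_ng Copies per ng (default 303).
#' @param intercept_cq Cq at a single copy (default 38).
#' @param max_cycles Final cycle; later detections are censored
#'   (default 50).
#' @param seed Integer seed.
#' @return List with `standards` (mass_ng, cq), `samples` (sample_id, cq,
#'   input_ng), and `truth` (the fractions).
#' @export
gen_qpcr <- function(standard_masses = 50 / 5^(0:5), sample_fractions,
                     efficiency = 1, noise_sd_cq = 0, input_ng = 5,
                     copies_per_ng = 303, intercept_cq = 38,
                     max_cycles = 50, seed = 1L) {
  stopifnot(
    all(sample_fractions >= 0 & sample_fractions <= 1),
    efficiency > 0.7, efficiency <= 1.1
  )
  slope <- -1 / log10(1 + efficiency)
  with_seed(seed, {
    cq_std <- intercept_cq +
      slope * log10(standard_masses * copies_per_ng) +
      stats::rnorm(length(standard_masses), 0, noise_sd_cq)
    copies <- input_ng * copies_per_ng * sample_fractions
    cq_s <- ifelse(
      copies > 0,
      intercept_cq + slope * log10(copies) +
        stats::rnorm(length(copies), 0, noise_sd_cq),
      NA_real_
    )
    cq_s[!is.na(cq_s) & cq_s > max_cycles] <- NA_real_
  })
  list(
    standards = data.frame(mass_ng = standard_masses, cq = cq_std),
    samples = data.frame(
      sample_id = sprintf("S%02d", seq_along(sample_fractions)),
      cq = cq_s, input_ng = input_ng, stringsAsFactors = FALSE
    ),
    truth = sample_fractions
  )
}
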