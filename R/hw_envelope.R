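#' Hardy-Weinberg mean-SD relationship for diploid cohorts
#'
#' For a biallelic site with non-reference allele frequency (penetrance) `p`
#' under Hardy-Weinberg equilibrium, the three genotypes occur at
#' `(1-p)^2`, `2p(1-p)` and `p^2` and the population standard deviation of
#' the per-sample allele fraction is `sqrt(p (1-p) / 2)` (fraction scale).
#' Across a cohort, true germline variants therefore trace a parabola of SD
#' versus mean allele fraction; recurrent technical artifacts (systematic
#' variants) violate it, typically appearing with near-constant low-level
#' signal in every sample (high mean, tiny SD).
#'
#' @param p Penetrance in `[0, 1]`.
#' @return `hw_sd`: SD on the fraction scale; `genotype_frequencies`: named
#'   vector `(wt, het, hom)` summing to 1.
#' @examples
#' hw_sd(0.5) # sqrt(0.125)
#' genotype_frequencies(0.1)
#' @export
hw_sd <- function(p) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  sqrt(p * (1 - p) / 2)
}

#' @rdname hw_sd
#' @export
genotype_frequencies <- function(p) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  cbind(wt = (1 - p)^2, het = 2 * p * (1 - p), hom = p^2)
}

#' Measurement models for percent-variant draws by genotype
#'
#' Maps genotypes to noisy percent-variant observations. The parametric
#' model draws wild type as `|N(0, sigma_wt)|` (a half-normal noise floor),
#' heterozygotes as `N(het_mean, sigma_het)` clamped to `[0, 100]`, and
#' homozygotes as `100 - |N(0, sigma_het)|` (exactly normal truncated at
#' 100). Setting both sigmas to 0 gives the noise-free model (0/50/100).
#' An empirical model resamples user-supplied percent-variant clusters.
#'
#' @param sigma_wt Wild-type half-normal scale, percent points.
#' @param sigma_het Heterozygote/homozygote SD, percent points.
#' @param het_mean Heterozygote center, percent (default 50).
#' @return A `tas_measurement_model` object.
#' @export
measurement_model <- function(sigma_wt = 0.5, sigma_het = 3, het_mean = 50) {
  stopifnot(sigma_wt >= 0, sigma_het >= 0, het_mean > 0, het_mean < 100)
  structure(
    list(
      type = "parametric", sigma_wt = sigma_wt, sigma_het = sigma_het,
      het_mean = het_mean
    ),
    class = "tas_measurement_model"
  )
}

#' @rdname measurement_model
#' @param wt,het,hom Numeric vectors of observed percent variants to
#'   resample from, one per genotype cluster.
#' @export
empirical_measurement_model <- function(wt, het, hom) {
  stopifnot(length(wt) > 0, length(het) > 0, length(hom) > 0)
  structure(list(type = "empirical", wt = wt, het = het, hom = hom),
    class = "tas_measurement_model"
  )
}

## internal: draw percent variants for genotype codes 1=wt, 2=het, 3=hom
draw_percent <- function(g, model) {
  out <- numeric(length(g))
  iw <- g == 1L
  ih <- g == 2L
  io <- g == 3L
  if (model$type == "parametric") {
    out[iw] <- abs(stats::rnorm(sum(iw), 0, 1)) * model$sigma_wt
    out[ih] <- pmin(100, pmax(
      0,
      stats::rnorm(sum(ih), model$het_mean, model$sigma_het)
    ))
    out[io] <- 100 - abs(stats::rnorm(sum(io), 0, 1)) * model$sigma_het
  } else {
    out[iw] <- sample(model$wt, sum(iw), replace = TRUE)
    out[ih] <- sample(model$het, sum(ih), replace = TRUE)
    out[io] <- sample(model$hom, sum(io), replace = TRUE)
  }
  out
}

#' Simulate the Hardy-Weinberg acceptance envelope of cohort SD given mean
#'
#' For each penetrance on a grid, cohorts of `n_samples` diploid samples are
#' drawn: genotype counts follow a multinomial over the Hardy-Weinberg
#' frequencies and percent variants are sampled from the measurement model.
#' The per-cohort mean and SD of percent variant are pooled over the whole
#' grid and binned by mean; within each mean bin the central 99.8% interval
#' of the SD (the "3 SD" band) forms the acceptance envelope used by
#' [classify_svs()].
#'
#' @param n_samples Cohort size the envelope is built for (>= 2).
#' @param n_sim Simulation replicates per grid point (>= 1).
#' @param grid Penetrance grid in `(0, 1)`.
#' @param model A [measurement_model()].
#' @param seed Integer seed; recorded in the envelope for provenance.
#' @param n_bins Number of equal-width bins on mean percent (default 100).
#' @param band Central coverage of the SD band (default 0.998).
#' @return A `tas_hw_envelope`: the grid with analytic and simulated SD
#'   summaries (`expected_sd` in percent, `sim_sd_mean`, `sim_sd_rms`,
#'   `sim_var_se`), bin edges with `band_lo`/`band_hi`/`bin_n`, and the
#'   parameters used.
#' @export
simulate_envelope <- function(n_samples, n_sim = 1e5,
                              grid = seq(0.01, 0.99, by = 0.01),
                              model = measurement_model(), seed = 1L,
                              n_bins = 100, band = 0.998) {
  stopifnot(
    n_samples >= 2, n_sim >= 1, all(grid > 0 & grid < 1),
    band > 0 && band < 1
  )
  with_seed(seed, {
    ng <- length(grid)
    means <- numeric(ng * n_sim)
    sds <- numeric(ng * n_sim)
    sd_mean <- sd_rms <- var_se <- numeric(ng)
    for (i in seq_len(ng)) {
      fr <- genotype_frequencies(grid[i])[1, ]
      g <- sample.int(3L, n_samples * n_sim, replace = TRUE, prob = fr)
      v <- matrix(draw_percent(g, model), nrow = n_samples)
      m <- colMeans(v)
      s2 <- (colSums(v * v) - n_samples * m * m) / (n_samples - 1)
      s2[s2 < 0] <- 0 # guard rounding
      s <- sqrt(s2)
      idx <- (i - 1) * n_sim + seq_len(n_sim)
      means[idx] <- m
      sds[idx] <- s
      sd_mean[i] <- mean(s)
      sd_rms[i] <- sqrt(mean(s2))
      var_se[i] <- stats::sd(s2) / sqrt(n_sim)
    }
  })
  if (length(unique(round(sds, 12))) == 1) {
    warning("degenerate measurement model: zero-width envelope band")
  }
  edges <- seq(0, 100, length.out = n_bins + 1)
  bin <- findInterval(means, edges, rightmost.closed = TRUE)
  alpha <- (1 - band) / 2
  band_lo <- rep(NA_real_, n_bins)
  band_hi <- rep(NA_real_, n_bins)
  bin_n <- tabulate(bin, nbins = n_bins)
  for (b in which(bin_n > 0)) {
    q <- stats::quantile(sds[bin == b], c(alpha, 1 - alpha),
      names = FALSE, type = 7
    )
    band_lo[b] <- q[1]
    band_hi[b] <- q[2]
  }
  structure(
    list(
      grid = grid, expected_sd = 100 * hw_sd(grid), sim_sd_mean = sd_mean,
      sim_sd_rms = sd_rms, sim_var_se = var_se, bin_edges = edges,
      band_lo = band_lo, band_hi = band_hi, bin_n = bin_n,
      n_samples = n_samples, n_sim = n_sim, band = band, model = model,
      seed = seed
    ),
    class = "tas_hw_envelope"
  )
}

#' @export
print.tas_hw_envelope <- function(x, ...) {
  cat(
    "<tas_hw_envelope> n_samples =", x$n_samples, ", n_sim =", x$n_sim,
    "per grid point,", length(x$grid), "grid points, seed =", x$seed, "\n"
  )
  invisible(x)
}

## internal: envelope band lookup + outlier test for (mean, sd) pairs.
## Means falling in a bin no Hardy-Weinberg-consistent cohort ever reached
## are outliers by construction.
envelope_outlier <- function(envelope, mean_pct, sd_pct) {
  b <- findInterval(mean_pct, envelope$bin_edges, rightmost.closed = TRUE)
  b[b < 1] <- 1
  nb <- length(envelope$band_lo)
  b[b > nb] <- nb
  lo <- envelope$band_lo[b]
  hi <- envelope$band_hi[b]
  out <- is.na(lo) | sd_pct < lo | sd_pct > hi
  list(outlier = out, band_lo = lo, band_hi = hi)
}
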