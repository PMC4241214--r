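test_that("calibration fitting recovers slope and efficiency", {
  # perfect doubling: slope -1/log10(2) = -3.3219 cycles per decade
  masses <- 50 / 5^(0:5)
  cq <- 38 - log10(masses * 303) / log10(2)
  cv <- fit_calibration(masses, cq)
  expect_equal(cv$slope, -1 / log10(2), tolerance = 1e-9)
  expect_equal(cv$efficiency, 1, tolerance = 1e-6)
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)
  # the 5-fold series from 50 ng to 16 pg spans ~3.5 logs: a valid fit
  expect_equal(diff(range(log10(masses))), 5 * log10(5), tolerance = 1e-9)

  expect_error(fit_calibration(c(50, 50), c(20, 20)), "3 detected")
  expect_error(
    fit_calibration(c(50, 50, 50), c(20, 20, 20)),
    "rank-deficient"
  )
  expect_warning(
    fit_calibration(c(50, 2, 0.08), c(20, 19, 26)),
    "monotone"
  )
})

test_that("QFI recovers generator amplifiable fractions and tiers", {
  q <- gen_qpcr(sample_fractions = c(0.005, 0.02, 0.10, 1), seed = 17)
  cv <- fit_calibration(q$standards$mass_ng, q$standards$cq)
  r <- compute_qfi(q$samples$sample_id, q$samples$cq, cv)
  rel_err <- abs(r$qfi_percent / 100 - q$truth) / q$truth
  expect_true(all(rel_err < 0.10))
  expect_equal(r$tier, c(
    "MEASURABLE_LOW", "MEASURABLE_LOW", "PASS", "PASS"
  ))

  # the calibrator itself reads back ~100%
  self <- compute_qfi("cal", cv$intercept + cv$slope * log10(5 * 303), cv)
  expect_equal(self$qfi_percent, 100, tolerance = 1e-6)

  # no Cq by the final cycle: undetectable, QFI 0
  r0 <- compute_qfi("nd", NA_real_, cv)
  expect_equal(r0$tier, "UNDETECTABLE")
  expect_equal(r0$qfi_percent, 0)

  # monotone: later Cq means lower QFI
  cqs <- seq(25, 40, by = 0.5)
  qs <- compute_qfi(paste0("m", seq_along(cqs)), cqs, cv)$qfi_percent
  expect_true(all(diff(qs) < 0))

  # tiers partition the cohort
  q2 <- gen_qpcr(sample_fractions = c(0, 0.01, 0.02, 0.5, 1), seed = 18)
  r2 <- compute_qfi(q2$samples$sample_id, q2$samples$cq, cv)
  expect_equal(nrow(r2), sum(table(r2$tier)))
  expect_true(all(r2$tier[q2$truth == 0] == "UNDETECTABLE"))
})

test_that("fraction-0 samples and the 3% gate flow through the tiers", {
  q <- gen_qpcr(sample_fractions = c(0, 0.0299, 0.031, 0.9), seed = 19)
  cv <- fit_calibration(q$standards$mass_ng, q$standards$cq)
  r <- compute_qfi(q$samples$sample_id, q$samples$cq, cv)
  # the gate is strict: QFI must exceed 3%
  expect_equal(r$tier[2], "MEASURABLE_LOW")
  expect_equal(r$tier[3], "PASS")
  expect_equal(r$tier[1], "UNDETECTABLE")
})

test_that("stratified concordance totals samples x hotspots per tier", {
  hot <- data.frame(
    chrom = "h1", pos = 1:15, ref = "C", alt = "T",
    stringsAsFactors = FALSE
  )
  mk_qfi <- function(ids, tier) {
    cqv <- switch(tier,
      PASS = 28, MEASURABLE_LOW = 34, UNDETECTABLE = NA_real_
    )
    data.frame(sample_id = ids, cq = cqv)
  }
  q <- gen_qpcr(sample_fractions = rep(1, 1), seed = 20)
  cv <- fit_calibration(q$standards$mass_ng, q$standards$cq)
  ids <- sprintf("p%02d", 1:18)
  qfi <- compute_qfi(ids, rep(28, 18), cv)
  expect_true(all(qfi$tier == "PASS"))

  # all wild type with good coverage: everything TN
  calls <- expand.grid(
    sample_id = ids, pos = 1:15,
    stringsAsFactors = FALSE
  )
  calls$chrom <- "h1"
  calls$ref <- "C"
  calls$alt <- "T"
  calls$depth <- 500
  calls$call <- FALSE
  calls$truth <- FALSE
  got <- stratify_concordance(qfi, calls, hot)
  pass_row <- got[got$tier == "PASS", ]
  expect_equal(pass_row$total, 18 * 15) # 270 entries
  expect_equal(pass_row$TN, 270)

  # missing rows count as NO_COVERAGE; low depth as LOW_COVERAGE
  ids26 <- sprintf("u%02d", 1:26)
  qfi26 <- compute_qfi(ids26, rep(NA_real_, 26), cv)
  calls26 <- expand.grid(
    sample_id = ids26[1:2], pos = 1:15,
    stringsAsFactors = FALSE
  )
  calls26$chrom <- "h1"
  calls26$ref <- "C"
  calls26$alt <- "T"
  calls26$depth <- rep(c(50, 400), 15)
  calls26$call <- FALSE
  calls26$truth <- FALSE
  got26 <- stratify_concordance(qfi26, calls26, hot)
  und <- got26[got26$tier == "UNDETECTABLE", ]
  expect_equal(und$total, 26 * 15) # 390 entries
  expect_equal(und$LOW_COVERAGE, 15)
  expect_equal(und$NO_COVERAGE, 390 - 30)
})

test_that("tier association matches hypergeometric enumeration", {
  # identical row distributions: no association
  expect_equal(tier_association(rbind(c(5, 5), c(10, 10))), 1)

  # 2x2 enumeration oracle: sum hypergeometric probabilities of tables
  # as or more extreme than observed, margins fixed
  fisher_2x2_oracle <- function(m) {
    r1 <- sum(m[1, ])
    c1 <- sum(m[, 1])
    n <- sum(m)
    support <- max(0, c1 - (n - r1)):min(r1, c1)
    probs <- dhyper(support, r1, n - r1, c1)
    p_obs <- dhyper(m[1, 1], r1, n - r1, c1)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  tabs <- list(
    rbind(c(10, 0), c(0, 10)),
    rbind(c(3, 7), c(6, 2)),
    rbind(c(1, 9), c(8, 4))
  )
  for (m in tabs) {
    expect_equal(tier_association(m), fisher_2x2_oracle(m),
      tolerance = 1e-9
    )
  }

  # 3x2 tier-by-status table: independent fixed-margin enumeration
  fisher_rx2_oracle <- function(m) {
    rs <- rowSums(m)
    cs <- colSums(m)
    n <- sum(m)
    prob <- function(t) {
      exp(sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(n) -
        sum(lfactorial(t)))
    }
    p_obs <- prob(m)
    total <- 0
    for (a in 0:min(rs[1], cs[1])) {
      for (b in 0:min(rs[2], cs[1] - a)) {
        cc <- cs[1] - a - b
        if (cc < 0 || cc > rs[3]) next
        t <- cbind(c(a, b, cc), c(rs - c(a, b, cc)))
        if (any(t < 0)) next
        p <- prob(t)
        if (p <= p_obs * (1 + 1e-7)) total <- total + p
      }
    }
    total
  }
  m <- rbind(c(9, 1), c(6, 7), c(2, 5))
  expect_equal(tier_association(m), fisher_rx2_oracle(m),
    tolerance = 1e-9
  )
  expect_error(tier_association(matrix(0, 2, 2)), "zero")
})
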