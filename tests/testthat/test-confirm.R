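test_that("f-measure is the harmonic mean with the 0/0 convention", {
  expect_equal(f_measure(1, 1), 1)
  expect_equal(f_measure(0, 0.8), 0)
  expect_equal(f_measure(0, 0), 0)
  expect_equal(f_measure(0.78, 1), 2 * 0.78 / 1.78)
  # bounded by min/max and by the arithmetic mean
  set.seed(4)
  s <- runif(50)
  p <- runif(50)
  f <- f_measure(s, p)
  expect_true(all(f >= pmin(s, p) - 1e-12 & f <= pmax(s, p) + 1e-12))
  expect_true(all(f <= (s + p) / 2 + 1e-12))
})

test_that("clopper_pearson matches a bisection inversion of binomial tails", {
  # independent oracle: invert the exact binomial tail by bisection
  cp_oracle <- function(x, n, conf = 0.95) {
    a <- (1 - conf) / 2
    bis <- function(f, lo, hi) {
      for (i in 1:200) {
        mid <- (lo + hi) / 2
        if (f(mid)) lo <- mid else hi <- mid
      }
      (lo + hi) / 2
    }
    lower <- if (x == 0) 0 else
      bis(function(p) sum(dbinom(x:n, n, p)) < a, 0, 1)
    upper <- if (x == n) 1 else
      bis(function(p) sum(dbinom(0:x, n, p)) > a, 0, 1)
    c(100 * lower, 100 * upper)
  }
  for (n in c(1, 2, 5, 10, 16, 18, 23, 30)) {
    for (x in 0:n) {
      got <- clopper_pearson(x, n)
      expect_equal(unname(got), cp_oracle(x, n),
        tolerance = 0.05,
        label = sprintf("x=%d n=%d", x, n)
      )
    }
  }
  # agreement with the base-R exact test
  bt <- binom.test(7, 19)$conf.int
  expect_equal(unname(clopper_pearson(7, 19)), 100 * as.numeric(bt),
    tolerance = 1e-9
  )
  expect_equal(unname(clopper_pearson(0, 10))[1], 0)
  expect_equal(unname(clopper_pearson(10, 10))[2], 100)
  expect_error(clopper_pearson(3, 0), "trials")
})

test_that("confusion tables carry consistent rates and CIs", {
  ct <- confusion_table(18, 0, 5, 100)
  expect_equal(ct$sensitivity, 18 / 23)
  expect_equal(ct$ppv, 1)
  expect_equal(
    ct$f_measure,
    f_measure(ct$sensitivity, ct$ppv)
  )
  # CIs contain the point estimates
  expect_true(ct$ci_sensitivity[1] <= 100 * ct$sensitivity)
  expect_true(ct$ci_sensitivity[2] >= 100 * ct$sensitivity)
  expect_true(ct$ci_ppv[1] <= 100 * ct$ppv)
})

test_that("joint calling suppresses platform-private artifacts", {
  # the axis-hugging artifact: strong on A, zero on B
  expect_false(joint_call(10, 0, 2, 2))
  expect_true(joint_call(10, 8, 2, 2))
  # thresholds are strict
  expect_false(joint_call(2, 8, 2, 2))
  expect_warning(joint_call(numeric(0), numeric(0), 1, 1), "common")
  # at (0,0), exactly the hypotheses nonzero on both platforms
  pa <- c(0, 1, 3, 0.5)
  pb <- c(2, 0, 4, 1)
  expect_equal(joint_call(pa, pb, 0, 0), c(FALSE, FALSE, TRUE, TRUE))
})

test_that("grid_optimize matches brute force and breaks ties low", {
  set.seed(6)
  pa <- runif(300, 0, 30)
  pb <- runif(300, 0, 30)
  tr <- runif(300) < 0.25
  ga <- seq(0, 20, 2.5)
  gb <- seq(0, 20, 5)
  g <- grid_optimize(pa, pb, tr, ga, gb)
  brute <- matrix(NA_real_, length(ga), length(gb))
  for (i in seq_along(ga)) {
    for (j in seq_along(gb)) {
      pred <- pa > ga[i] & pb > gb[j]
      tp <- sum(pred & tr)
      fp <- sum(pred & !tr)
      fn <- sum(!pred & tr)
      brute[i, j] <- if (2 * tp + fp + fn == 0) 0 else
        2 * tp / (2 * tp + fp + fn)
    }
  }
  expect_equal(g$f_matrix, brute, tolerance = 1e-12)
  expect_equal(g$f_max, max(brute))
  # reversing the grid order leaves the attained maximum unchanged
  g2 <- grid_optimize(pa, pb, tr, ga, rev(-gb) * -1)
  expect_equal(g2$f_max, g$f_max)
  # perfect separation in single-platform mode reaches f = 1
  sep <- c(rep(10, 20), rep(1, 80))
  gtr <- c(rep(TRUE, 20), rep(FALSE, 80))
  gs <- grid_optimize(sep, sep, gtr, seq(0, 20, 0.5), NULL)
  expect_equal(gs$f_max, 1)
  expect_error(grid_optimize(pa, pb, rep(FALSE, 300), ga, gb), "empty")
})

test_that("confusion counts conserve the evaluated universe", {
  set.seed(9)
  pa <- runif(200, 0, 20)
  pb <- runif(200, 0, 20)
  tr <- runif(200) < 0.3
  g <- grid_optimize(pa, pb, tr, seq(0, 10, 1), seq(0, 10, 1))
  expect_equal(
    g$counts$tp + g$counts$fp + g$counts$fn + g$counts$tn, 200
  )
})

test_that("joint calling never adds false positives over either platform", {
  tp <- gen_two_platform(seed = 12)
  d <- tp$data
  for (t in c(0.5, 2, 5)) {
    fp_joint <- sum(joint_call(d$pct_a, d$pct_b, t, t) & !d$truth)
    fp_a <- sum(d$pct_a > t & !d$truth)
    fp_b <- sum(d$pct_b > t & !d$truth)
    expect_lte(fp_joint, min(fp_a, fp_b))
  }
})

test_that("confirmation with relaxed thresholds recovers sensitivity at full PPV", {
  # primary platform: true variants score high, a cluster of borderline
  # true variants sits just under the strict threshold, artifacts score
  # mid-range but show nothing on the confirmation platform
  n_hi <- 12
  n_border <- 6
  n_art <- 8
  n_bg <- 80
  ref <- rep("C", n_hi + n_border + n_art + n_bg)
  alt <- rep("T", length(ref))
  score <- c(
    rep(12, n_hi), rep(5.2, n_border), rep(6.5, n_art),
    rep(0.2, n_bg)
  )
  s <- toy_table(ref, alt, score = score)
  truth_idx <- seq_len(n_hi + n_border)
  keys <- paste("t1", seq_along(ref), "C", "T", sep = ":")
  confirm_pct <- c(
    rep(30, n_hi), rep(8, n_border), rep(0, n_art),
    rep(0.2, n_bg)
  )
  names(confirm_pct) <- keys
  pair <- threshold_pair(6, 6)

  strict <- confirm_workflow(s, pair, confirm_pct,
    relax_fraction = 0,
    confirm_threshold = 0, truth = keys[truth_idx]
  )
  # relax_fraction 0 + confirm_threshold 0 reproduces the primary calls
  prim <- call_variants(s, pair)
  expect_setequal(
    strict$confirmed,
    paste("t1", prim$pos, "C", "T", sep = ":")
  )

  relaxed <- confirm_workflow(s, pair, confirm_pct,
    relax_fraction = 0.2,
    confirm_threshold = 1, truth = keys[truth_idx]
  )
  # the borderline true variants enter at 0.8 * 6 = 4.8 and are confirmed;
  # artifacts are screened out at the confirmation step
  expect_gt(
    relaxed$confusion$sensitivity,
    confusion_table(
      sum(prim$pos %in% truth_idx),
      sum(!prim$pos %in% truth_idx),
      sum(!truth_idx %in% prim$pos), 0
    )$sensitivity
  )
  expect_equal(relaxed$confusion$ppv, 1)

  # sub-threshold confirmation drops a candidate
  low <- confirm_pct
  low[keys[1]] <- 0.5
  got <- confirm_workflow(s, pair, low, 0.2, 1)
  expect_false(keys[1] %in% got$confirmed)

  # missing confirmation measurements are unconfirmable, not confirmed
  partial <- confirm_pct[-(1:2)]
  got2 <- confirm_workflow(s, pair, partial, 0.2, 1)
  expect_setequal(got2$unconfirmable, keys[1:2])
})
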