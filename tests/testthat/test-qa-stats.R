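test_that("QIBA summary metrics follow the closed forms", {
  # scans exactly at truth: all metrics zero and conformant
  m <- qibaSummary(rep(1100, 8), rep(1:2, each = 4), truth = 1100)
  expect_equal(unlist(m[c("pct_bias", "rc_st", "cv_st", "rc_lt", "cv_lt")]),
               c(pct_bias = 0, rc_st = 0, cv_st = 0, rc_lt = 0, cv_lt = 0))
  expect_true(all(m$conformant))

  # per-session means with SD 10 um2/s -> RC_LT = 2.77 * 10 / 1000 um2/ms
  sess_means <- seq(1100 - 11 * 5, by = 10, length.out = 12)
  adc <- rep(sess_means, each = 2)  # zero within-session spread
  m <- qibaSummary(adc, rep(1:12, each = 2), truth = 1100)
  expect_equal(m$rc_lt, adcUm2sToUm2ms(2.77 * sd(sess_means)))
  expect_equal(m$rc_st, 0)

  # single session: long-term metrics undefined
  m1 <- qibaSummary(c(1100, 1105, 1098), rep(1, 3), truth = 1100)
  expect_true(is.na(m1$rc_lt) && is.na(m1$cv_lt))

  # scale invariance of %bias and CVs
  a <- c(1080, 1110, 1095, 1125, 1090, 1100)
  s <- rep(1:3, each = 2)
  m1 <- qibaSummary(a, s, truth = 1100)
  m2 <- qibaSummary(3 * a, s, truth = 3300)
  expect_equal(m2$pct_bias, m1$pct_bias)
  expect_equal(m2$cv_st, m1$cv_st)
  expect_equal(m2$cv_lt, m1$cv_lt)
})

test_that("RC_ST Monte-Carlo average matches 2.77 * sigma (12x4 design)", {
  set.seed(303)
  sigma <- 2
  reps <- replicate(500, {
    adc <- 1100 + rnorm(48, 0, sigma)
    qibaSummary(adc, rep(1:12, each = 4), truth = 1100)$rc_st
  })
  expected <- adcUm2sToUm2ms(2.77 * sigma)
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - expected), 3 * se + 0.01 * expected)
})

test_that("%RC and %RDC match their arithmetic definitions", {
  expect_equal(pctRC(rep(1100, 4), rep("A", 4), rep("v", 4))$per_vial$pct_rc, 0)
  got <- pctRC(c(1090, 1110), c("A", "A"), c("v", "v"))
  expect_equal(got$per_vial$pct_rc, 100 * 2.77 * sd(c(1090, 1110)) / 1100)
  expect_equal(round(got$per_vial$pct_rc, 2), 3.56)

  # institutes without repeats are excluded, like a site with single scans
  mixed <- pctRC(c(1090, 1110, 1200), c("A", "A", "J"), rep("v", 3))
  expect_identical(mixed$excluded, "J")
  expect_identical(sum(!is.na(mixed$per_vial$pct_rc)), 1L)

  expect_equal(pctRDC(rep(1100, 3), c("A", "B", "C"), rep("v", 3))$median, 0)
  rdc <- pctRDC(c(1000, 1100, 1200), c("A", "B", "C"), rep("v", 3))
  expect_equal(rdc$median, 100 * 2.77 * 100 / 1100)
  expect_equal(round(rdc$median, 1), 25.2)
  expect_error(pctRDC(c(1000, 1100), c("A", "B"), c("v", "v")), "at least 3")

  # scale invariance
  a <- c(1000, 1075, 1150, 1210)
  r1 <- pctRDC(a, LETTERS[1:4], rep("v", 4))$median
  r2 <- pctRDC(5 * a, LETTERS[1:4], rep("v", 4))$median
  expect_equal(r1, r2)
})

test_that("simulated institutes with 1% CV give the predicted median %RC", {
  set.seed(404)
  meds <- replicate(200, {
    adc <- as.vector(vapply(1:12, function(i) 1100 * (1 + rnorm(4, 0, 0.01)),
                            numeric(4)))
    pctRC(adc, rep(1:12, each = 4), rep("v", 48))$median
  })
  # per-institute SD has 3 df: median of SD/sigma is sqrt(qchisq(0.5, 3)/3),
  # so the median %RC concentrates at 2.77 * that factor (~2.46%)
  expected <- 2.77 * sqrt(qchisq(0.5, 3) / 3)
  expect_lt(abs(mean(meds) - expected) / expected, 0.05)
})

test_that("exact Pratt signed-rank p equals brute-force enumeration", {
  set.seed(505)
  for (i in 1:40) {
    n <- sample(3:12, 1)
    x <- sample(c(-4:4), n, replace = TRUE) +
      sample(c(0, 0.5), n, replace = TRUE)
    for (alt in c("greater", "less")) {
      expect_equal(phantomADC:::.signed_rank_p(x, alt),
                   bf_signed_rank_p(x, alt), tolerance = 1e-12,
                   info = paste(alt, paste(x, collapse = ",")))
    }
  }
})

test_that("signed-rank p agrees with stats::wilcox.test without zeros/ties", {
  set.seed(606)
  for (i in 1:20) {
    x <- round(rnorm(10, 0.3, 1), 6)  # continuous: no zeros, no ties
    expect_equal(phantomADC:::.signed_rank_p(x, "greater"),
                 wilcox.test(x, alternative = "greater", exact = TRUE)$p.value)
  }
})

test_that("TOST declares equivalence for zero differences at delta = 1", {
  t <- tostWilcoxon(rep(0, 10), delta = 1)
  expect_equal(t$p_tost, 1 / 2^10)
  expect_true(t$equivalent)
  expect_identical(t$stars, "***")

  # wide spread with a tiny tolerance: not equivalent
  spread <- c(-2, -1.5, -1, -0.5, 0.5, 1, 1.5, 2)
  t2 <- tostWilcoxon(spread, delta = 0.1)
  expect_gte(t2$p_tost, 0.05)
  expect_false(t2$equivalent)

  # monotone in delta
  expect_lte(tostWilcoxon(spread, 5)$p_tost, tostWilcoxon(spread, 2)$p_tost)
  expect_error(tostWilcoxon(spread, -1), "positive")
  expect_warning(tostWilcoxon(rep(0.1, 4), 1), "fewer than 6")
})

test_that("TOST p is monotone non-increasing in delta over random sets", {
  set.seed(707)
  deltas <- c(0.5, 1, 2, 5, 10)
  for (i in 1:100) {
    d <- rnorm(sample(8:20, 1), rnorm(1, 0, 2), runif(1, 0.5, 3))
    p <- vapply(deltas, function(dd)
      suppressWarnings(tostWilcoxon(d, dd)$p_tost), numeric(1))
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("minimal equivalence tolerance search hits the exact crossing", {
  zero13 <- setNames(replicate(13, rep(0, 48), simplify = FALSE),
                     paste0("v", 1:13))
  got <- minimalEquivalenceTolerance(zero13)
  expect_equal(got$delta, 0.01)

  # one vial shifted by +3.5: the first integer tolerance that exceeds the
  # shift with exact one-sided significance is 4
  shifted <- zero13
  shifted$v1 <- rep(3.5, 48)
  got <- minimalEquivalenceTolerance(shifted)
  expect_equal(got$delta, 4)

  # adding a constant to one vial never lowers the result
  worse <- shifted
  worse$v2 <- shifted$v2 + 10
  expect_gte(minimalEquivalenceTolerance(worse)$delta, got$delta)

  # hopeless differences: not equivalent at the grid maximum
  big <- zero13
  big$v1 <- rep(100, 48)
  res <- minimalEquivalenceTolerance(big)
  expect_false(res$achieved)
  expect_true(is.na(res$delta))
})
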