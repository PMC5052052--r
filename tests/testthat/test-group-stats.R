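test_that("the exact MWU path reproduces enumeration on worked examples", {
  got <- mwuTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$U, 0)
  expect_equal(got$p, 0.1)
  expect_true(got$exact)
  expect_equal(enum_mwu_p(c(1, 2, 3), c(4, 5, 6)), 0.1)

  # identical multisets -> p = 1 under the approximate (tied) path
  same <- mwuTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  # fully degenerate sample (all values equal) -> p = 1, not NaN
  expect_equal(mwuTest(rep(2, 5), rep(2, 4))$p, 1)

  # two-sided p is symmetric in the group order
  set.seed(61)
  a <- rnorm(5); b <- rnorm(7) + 1
  expect_equal(mwuTest(a, b)$p, mwuTest(b, a)$p)

  expect_error(mwuTest(c(NA, NA), c(1, 2)), "two non-missing")
})

test_that("exact MWU agrees with full enumeration for random no-tie inputs", {
  set.seed(62)
  for (i in 1:40) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    x <- sample(100, na + nb)  # distinct integers: no ties
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    expect_equal(mwuTest(a, b)$p, enum_mwu_p(a, b),
                 info = paste("case", i))
  }
})

test_that("Fisher combination matches the closed form and its boundaries", {
  fc <- fisherCombine(c(0.05, 0.05))
  expect_equal(fc$chi2, -2 * (log(0.05) + log(0.05)))
  expect_equal(fc$df, 4L)
  # independent check: upper-tail mass by numerical integration
  byint <- integrate(function(x) dchisq(x, df = 4), fc$chi2, Inf)$value
  expect_equal(fc$p, byint, tolerance = 1e-6)
  expect_equal(fc$p, 0.0175, tolerance = 2e-3)

  p1 <- runif(1)
  expect_equal(fisherCombine(p1)$p, p1)            # k = 1 identity
  expect_equal(fisherCombine(c(1, 1))$chi2, 0)
  expect_equal(fisherCombine(c(1, 1))$p, 1)
  expect_error(fisherCombine(c(0.5, 0)), "\\(0, 1\\]")
})

make_features <- function(vals, divs = 10L, conditions = NULL) {
  n <- length(vals)
  if (is.null(conditions))
    conditions <- rep(c("control", "treatment"), length.out = n)
  do.call(rbind, lapply(divs, function(d)
    data.frame(div = d, well = sprintf("W%02d", seq_len(n)),
               condition = conditions, mfr_hz = vals,
               stringsAsFactors = FALSE)))
}

test_that("permutation p is deterministic in the seed and bounded below", {
  set.seed(63)
  feats <- make_features(rlnorm(20, 0, 0.3))
  p1 <- permutationTest(feats, feature = "mfr_hz", window = 10L,
                        nPerm = 500, seed = 7)
  p2 <- permutationTest(feats, feature = "mfr_hz", window = 10L,
                        nPerm = 500, seed = 7)
  p3 <- permutationTest(feats, feature = "mfr_hz", window = 10L,
                        nPerm = 500, seed = 8)
  expect_identical(p1$perm_p, p2$perm_p)
  expect_gte(p1$perm_p, 1 / 501)
  expect_lt(abs(p3$perm_p - p1$perm_p), 10 / sqrt(500))
})

test_that("complete separation attains the 1/(nPerm+1) floor", {
  feats <- make_features(c(seq(1, 1.64, length.out = 17),
                           seq(2, 2.6, length.out = 16)),
                         conditions = rep(c("control", "treatment"),
                                          c(17, 16)))
  pt <- permutationTest(feats, feature = "mfr_hz", window = 10L,
                        nPerm = 2000, seed = 1)
  expect_equal(pt$perm_p, 1 / 2001)  # reportable as p < 1/2000
})

test_that("perm_p is invariant under strictly monotone transforms", {
  set.seed(64)
  base <- make_features(rlnorm(14, 0, 0.4), divs = c(9L, 10L))
  for (trans in list(function(x) 3 * x + 2, log, function(x) x^3)) {
    tr <- base; tr$mfr_hz <- trans(tr$mfr_hz)
    for (red in c("mean", "concat")) {
      # with "mean" a monotone transform commutes with the reduction only
      # for single-day windows; test each day separately plus concat
      win <- if (red == "mean") 10L else c(9L, 10L)
      p0 <- permutationTest(base, feature = "mfr_hz", window = win,
                            nPerm = 300, seed = 5, reducer = red)
      p1 <- permutationTest(tr, feature = "mfr_hz", window = win,
                            nPerm = 300, seed = 5, reducer = red)
      expect_equal(p1$perm_p, p0$perm_p)
      expect_equal(p1$observed_mwu_p, p0$observed_mwu_p)
    }
  }
})

test_that("the approximate path matches wilcox.test with ties", {
  set.seed(65)
  for (i in 1:20) {
    a <- sample(1:6, 9, replace = TRUE)
    b <- sample(1:6, 11, replace = TRUE)
    got <- mwuTest(a, b)
    want <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                                correct = TRUE))
    expect_equal(got$p, want$p.value)
    expect_false(got$exact)
  }
})

test_that("per-DIV series combine across days and skip thin days", {
  set.seed(66)
  vals <- rlnorm(10, 0, 0.3)
  feats <- rbind(make_features(vals, divs = c(8L, 9L, 10L)),
                 # DIV 11 has a single well per group: must be skipped
                 make_features(vals[1:4], divs = 11L)[1:2, ])
  pd <- perDivSeries(feats, feature = "mfr_hz", window = 8:11)
  expect_equal(names(pd$per_div_p), c("8", "9", "10"))
  expect_equal(pd$skipped_divs, 11L)
  expect_equal(pd$fisher_df, 6L)
  expect_equal(pd$fisher_p, fisherCombine(pd$per_div_p)$p)

  # single-day window: combined p equals that day's p
  pd1 <- perDivSeries(feats, feature = "mfr_hz", window = 9L)
  expect_equal(pd1$fisher_p, unname(pd1$per_div_p))
})

test_that("compareFeature assembles both tiers consistently", {
  set.seed(67)
  feats <- make_features(rlnorm(12, 0, 0.3), divs = 8:10)
  g <- compareFeature(feats, feature = "mfr_hz", window = 8:10,
                      nPerm = 200, seed = 2)
  expect_s4_class(g, "GroupComparison")
  expect_equal(g@fisherDf, 2L * length(g@perDivP))
  expect_true(all(g@perDivP > 0 & g@perDivP <= 1))
  expect_gte(g@permP, 1 / 201)
  tab <- comparisonTable(g)
  expect_equal(tab$perm_p, g@permP)
  expect_equal(tab$fisher_p, g@fisherP)
})
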