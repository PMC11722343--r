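test_that("signed-rank p-values equal exhaustive sign-permutation enumeration", {
  set.seed(19)
  fixtures <- list(
    list(x = c(1.2, 3.1, 0.5, 2.2, 4.0, 1.1),
         y = c(0.8, 2.0, 1.5, 2.9, 1.0, 0.4)),
    list(x = rnorm(8), y = rnorm(8)),
    list(x = rnorm(10, 0.5), y = rnorm(10)),
    list(x = c(1, 2, 3, 4, 5), y = c(2, 1, 5, 3, 7)),      # tied |d|
    list(x = c(3, 3, 3, 1, 9, 2, 5), y = c(1, 1, 1, 3, 2, 7, 5)) # ties+zero
  )
  for (f in fixtures) {
    expect_equal(pValue(pairedSignedRank(f$x, f$y)),
                 enumSignedRankP(f$x, f$y), tolerance = 1e-12)
  }
  # agreement with the reference implementation on a tie-free fixture
  x <- c(1.3, 2.7, 0.2, 5.5, 4.1, 3.3, 2.2, 6.6)
  y <- c(0.9, 3.1, 1.1, 2.0, 4.9, 1.2, 2.9, 4.4)
  expect_equal(pValue(pairedSignedRank(x, y)),
               wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("a constant positive shift at n = 10 gives the extreme exact p", {
  x <- 1:10
  expect_equal(pValue(pairedSignedRank(x + 3, x)), 2 / 2^10,
               tolerance = 1e-12)
})

test_that("all-zero differences carry no evidence and zeros are dropped", {
  r <- pairedSignedRank(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(pValue(r), 1)
  r2 <- pairedSignedRank(c(1, 2, 5, 7, 9), c(1, 2, 3, 4, 5))
  expect_equal(r2@details$n_zero_dropped, 2)
  expect_equal(r2@details$n_used, 3)
  expect_error(pairedSignedRank(c(1, 2), c(3, 4)), "fewer than 3")
})

test_that("signed-rank type-I error is nominal under the null", {
  set.seed(2024)
  reps <- 10000
  rejected <- 0L
  for (i in seq_len(reps)) {
    x <- rnorm(12)
    y <- rnorm(12)
    if (pValue(pairedSignedRank(x, y)) < 0.05) rejected <- rejected + 1L
  }
  rate <- rejected / reps
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("rank-based tests are invariant to rank-preserving transforms", {
  set.seed(55)
  # signed rank: positive affine transforms preserve difference ranks
  x <- rexp(9); y <- rexp(9) * 2
  expect_equal(pValue(pairedSignedRank(x, y)),
               pValue(pairedSignedRank(3 * x + 1, 3 * y + 1)))
  # rank-based group tests: any monotone transform of the pooled values
  g1 <- rexp(7); g2 <- rexp(7) + 1; g3 <- rexp(7)
  expect_equal(pValue(multigroupCompare(list(g1, g2, g3))),
               pValue(multigroupCompare(list(g1^3, g2^3, g3^3))))
  a <- rexp(8); b <- rexp(8) * 1.5
  mwA <- gatedUnpairedCompare(a, b)@details$mann_whitney$p.value
  mwB <- gatedUnpairedCompare(log(a), log(b))@details$mann_whitney$p.value
  expect_equal(mwA, mwB)
})

test_that("the variance gate routes to Mann-Whitney or t-test as stated", {
  set.seed(9)
  # identical groups: gate stays parametric, p in the no-evidence region
  x <- c(1.1, 2.3, 0.8, 1.9, 2.8)
  same <- gatedUnpairedCompare(x, x)
  expect_equal(same@gate, "parametric")
  expect_equal(same@method, "student_t")
  expect_gt(pValue(same), 0.99)
  # strong heteroscedasticity selects the rank test
  a <- rnorm(30, 0, 1)
  b <- rnorm(30, 0, 5)
  het <- gatedUnpairedCompare(a, b)
  expect_equal(het@gate, "nonparametric")
  expect_equal(het@method, "mann_whitney_u")
  # both branch results are always retained
  expect_s3_class(het@details$t_test, "htest")
  expect_s3_class(het@details$mann_whitney, "htest")
})

test_that("the Mann-Whitney branch agrees with rank-permutation enumeration", {
  x <- c(1.2, 5.5, 2.2, 8.8)
  y <- c(0.3, 0.9, 1.1, 6.1)
  oracle <- enumRankSumP(x, y)
  mw <- wilcox.test(x, y, exact = TRUE)
  res <- gatedUnpairedCompare(x, y)
  expect_equal(mw$p.value, oracle, tolerance = 1e-12)
  # the retained branch result matches the exact test decision-wise
  expect_equal(res@details$mann_whitney$p.value > 0.05, oracle > 0.05)
})

test_that("Kruskal-Wallis matches the hand-computed rank formula", {
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  # ranks 1..6, no ties: H = 12/(N(N+1)) * sum n_i (Rbar_i - Rbar)^2
  rbar <- c(1.5, 3.5, 5.5)
  H <- 12 / (6 * 7) * sum(2 * (rbar - 3.5)^2)
  res <- multigroupCompare(g)
  expect_equal(unname(res@statistic), H, tolerance = 1e-12)
  # all-constant groups
  res0 <- multigroupCompare(list(c(2, 2), c(2, 2)))
  expect_equal(unname(res0@statistic), 0)
  expect_equal(pValue(res0), 1)
})

test_that("two-group Kruskal-Wallis agrees in decision with Mann-Whitney", {
  set.seed(77)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(12, ifelse(i %% 2 == 0, 2, 0))
    kw <- pValue(multigroupCompare(list(x, y)))
    mw <- wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
    expect_equal(kw < 0.05, mw < 0.05)
  }
})

test_that("significance stars follow the printed convention", {
  expect_equal(significanceStars(c(0.04, 0.009, 0.0009, 0.00009, 0.2)),
               c("*", "**", "***", "****", "ns"))
})
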