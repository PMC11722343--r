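makeSpotFixture <- function(values) {
  n <- length(values)
  SpotTable(matrix(values, nrow = 1,
                   dimnames = list("g1", paste0("s", seq_len(n)))),
            data.frame(spot_id = paste0("s", seq_len(n)),
                       x = seq_len(n), y = 1))
}

test_that("spatial significance is the across-spot unbiased sd", {
  expect_equal(spatialSignificance(makeSpotFixture(rep(3, 5)))$score, 0)
  expect_equal(spatialSignificance(makeSpotFixture(c(0, 0, 2, 2)))$score,
               sqrt(4 / 3), tolerance = 1e-9)
})

test_that("candidate selection takes per-sample top sets and intersects", {
  mk <- function(genes, scores) data.frame(gene = genes, score = scores,
                                           rank = rank(-scores))
  s1 <- mk(letters[1:8], 8:1)
  s2 <- mk(letters[1:8], c(8, 7, 6, 1, 2, 3, 4, 5))
  sel <- selectCandidateGenes(list(s1, s2), nTop = 5)
  expect_equal(sel$perSample[[1]], letters[1:5])
  expect_setequal(sel$intersection, c("a", "b", "c"))
  # single sample returns its own top set; disjoint tops intersect empty
  expect_equal(selectCandidateGenes(list(s1), nTop = 3)$intersection,
               c("a", "b", "c"))
  s3 <- mk(letters[1:8], 1:8)
  expect_length(selectCandidateGenes(list(s1, s3), nTop = 3)$intersection,
                0)
})

test_that("rank-recovery score hits its 0 and 1 extremes", {
  genes <- sprintf("g%02d", 1:100)
  sig <- GeneSignature("s", c("g01", "g02", "g03"))
  top <- matrix(c(rep(10, 3), rep(1, 97)), ncol = 1,
                dimnames = list(genes, "s1"))
  expect_equal(unname(rankRecoveryScore(top, sig, topFraction = 0.05)), 1)
  bottom <- matrix(c(rep(1, 3), rep(10, 97)), ncol = 1,
                   dimnames = list(genes, "s1"))
  expect_equal(unname(rankRecoveryScore(bottom, sig, topFraction = 0.05)), 0)
})

test_that("rank-recovery is invariant to monotone transforms", {
  set.seed(3)
  genes <- sprintf("g%02d", 1:60)
  m <- matrix(rexp(120), nrow = 60, dimnames = list(genes, c("s1", "s2")))
  sig <- GeneSignature("s", c("g05", "g17", "g33"))
  base <- rankRecoveryScore(m, sig, topFraction = 0.2)
  expect_equal(rankRecoveryScore(log1p(m) * 3, sig, topFraction = 0.2),
               base)
  expect_equal(rankRecoveryScore(m^2, sig, topFraction = 0.2), base)
})

test_that("random rankings score at the Monte-Carlo expectation", {
  nGenes <- 200
  genes <- sprintf("g%03d", seq_len(nGenes))
  sig <- GeneSignature("s", genes[1:10])
  w <- ceiling(0.05 * nGenes)
  # analytic-by-simulation oracle: direct enumeration of random orderings
  set.seed(61)
  oracle <- vapply(1:1000, function(i) {
    rk <- sample(nGenes)[1:10]           # ranks of the 10 signature genes
    rk <- rk[rk <= w]
    if (length(rk) == 0) return(0)
    auc <- sum(w - rk + 1)
    m <- min(10, w)
    auc / (m * (m + 1) / 2 + (w - m) * m)
  }, numeric(1))
  set.seed(62)
  scores <- vapply(1:1000, function(i) {
    m <- matrix(sample(nGenes), ncol = 1, dimnames = list(genes, "s"))
    unname(rankRecoveryScore(m, sig, topFraction = 0.05))
  }, numeric(1))
  se <- sqrt(var(oracle) / 1000 + var(scores) / 1000)
  expect_lt(abs(mean(scores) - mean(oracle)), 2 * se)
})

test_that("coexistence is Pearson correlation with guarded degeneracies", {
  tc <- cbind(t1 = c(1, 2, 3, 4), t2 = c(2, 4, 6, 8),
              t3 = c(4, 3, 2, 1))
  cc <- coexistenceMatrix(tc)
  expect_equal(cc["t1", "t2"], 1)
  expect_equal(cc["t1", "t3"], -1)
  expect_true(isSymmetric(cc))
  expect_true(all(abs(cc[!is.na(cc)]) <= 1))
  flat <- cbind(t1 = c(1, 2, 3), t2 = c(5, 5, 5))
  expect_warning(cc2 <- coexistenceMatrix(flat), "zero-variance")
  expect_true(is.na(cc2["t1", "t2"]))
  expect_equal(diag(cc2), c(t1 = 1, t2 = 1))
})

test_that("the planted coexisting pair is the off-diagonal maximum", {
  hits <- vapply(1:10, function(s) {
    sp <- simulateSpots(simConfig(seed = s), gridDim = c(12, 12),
                        nGenes = 30)
    cc <- coexistenceMatrix(sp$spots)
    diag(cc) <- NA
    mx <- which(cc == max(cc, na.rm = TRUE), arr.ind = TRUE)[1, ]
    setequal(rownames(cc)[mx], sp$truth$coexist_pair)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
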