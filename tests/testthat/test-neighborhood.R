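test_that("neighbor edges respect the inclusive 100-um boundary", {
  ct <- makeCells(x = c(0, 150), y = c(0, 0), phenotype = c("Tumor", "B"))
  g <- buildNeighborGraph(ct)
  expect_equal(nrow(graphEdges(g)), 0)
  ct2 <- makeCells(x = c(0, 100), y = c(0, 0), phenotype = c("Tumor", "B"))
  g2 <- buildNeighborGraph(ct2)
  expect_equal(nrow(graphEdges(g2)), 1)
  expect_equal(graphEdges(g2)$dist_um, 100)
  expect_error(buildNeighborGraph(ct, radiusUm = 0), "radius")
})

test_that("the neighbor graph equals the brute-force all-pairs computation", {
  set.seed(42)
  n <- 50
  ct <- makeCells(runif(n, 0, 400), runif(n, 0, 400),
                  sample(c("Tumor", "B", "CD8T"), n, replace = TRUE))
  g <- buildNeighborGraph(ct, radiusUm = 80)
  df <- cellData(ct)
  expected <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt((df$x_um[i] - df$x_um[j])^2 + (df$y_um[i] - df$y_um[j])^2)
    if (d <= 80) expected <- expected + 1
  }
  expect_equal(nrow(graphEdges(g)), expected)
  expect_true(all(graphEdges(g)$dist_um <= 80))
})

test_that("anchored densities match direct arithmetic and the brute-force oracle", {
  # 3 targets inside r = 100 um -> 3 / (pi * 0.01 mm^2)
  ct <- makeCells(x = c(0, 10, 50, -40, 120), y = c(0, 0, 0, 30, 0),
                  phenotype = c("Tumor", "CD8T", "CD8T", "CD8T", "CD8T"))
  res <- densityAround(ct, "Tumor", "CD8T", radiusUm = 100)
  expect_equal(res$perAnchor$count, 3)
  expect_equal(res$perAnchor$density_mm2, 3 / (pi * 0.01), tolerance = 1e-4)
  expect_equal(round(res$perAnchor$density_mm2, 2), 95.49)

  # randomized fixture vs oracle
  set.seed(7)
  n <- 120
  ct2 <- makeCells(runif(n, 0, 500), runif(n, 0, 500),
                   sample(c("Tumor", "CD4T_exh", "B"), n, replace = TRUE))
  res2 <- densityAround(ct2, "Tumor", "CD4T_exh", radiusUm = 100)
  df2 <- cellData(ct2)
  for (k in seq_len(nrow(res2$perAnchor))) {
    idx <- which(df2$cell_id == res2$perAnchor$anchor_id[k])
    expect_equal(res2$perAnchor$count[k],
                 bruteForceCount(ct2, idx, "CD4T_exh", 100))
  }
  # zero targets
  res3 <- densityAround(ct, "Tumor", "DC")
  expect_equal(res3$perAnchor$count, 0)
  expect_equal(res3$perAnchor$density_mm2, 0)
})

test_that("densities are invariant under rotation and translation", {
  set.seed(12)
  n <- 60
  ct <- makeCells(runif(n, 0, 300), runif(n, 0, 300),
                  sample(c("Tumor", "CD8T_exh"), n, replace = TRUE))
  base <- densityAround(ct, "Tumor", "CD8T_exh")$perAnchor$count
  for (s in 1:5) {
    tr <- transformCells(ct, runif(1, 0, 2 * pi), runif(1, -50, 50),
                         runif(1, -50, 50))
    expect_equal(densityAround(tr, "Tumor", "CD8T_exh")$perAnchor$count,
                 base)
  }
})

test_that("doubling the radius keeps expected density constant under CSR", {
  set.seed(30)
  dens <- matrix(NA_real_, 20, 2)
  for (s in 1:20) {
    n <- 600
    ct <- makeCells(runif(n, 0, 1000), runif(n, 0, 1000),
                    c("Tumor", rep("B", n - 1)))
    for (ri in 1:2) {
      r <- c(100, 200)[ri]
      res <- densityAround(ct, "Tumor", "B", radiusUm = r)
      dens[s, ri] <- res$perAnchor$density_mm2
    }
  }
  # expectation ~ 599 cells/mm^2 at either radius
  expect_lt(abs(mean(dens[, 1]) - mean(dens[, 2])) / mean(dens[, 2]), 0.15)
})

test_that("TLS densities use membership and area, and partition the ROI", {
  # 10 cells in a TLS whose hull area is 0.05 mm^2:
  # square of side sqrt(5e4) um holds the members
  side <- sqrt(5e4)
  xs <- c(0, side, side, 0, rep(side / 2, 6))
  ys <- c(0, 0, side, side, seq(10, side - 10, length.out = 6))
  ct <- makeCells(c(xs, 500, 600), c(ys, 500, 600),
                  phenotype = c(rep("CD8T_act", 10), "CD8T_act", "B"),
                  tls = c(rep("t1", 10), NA, NA))
  td <- tlsDensity(ct, phenotypes = c("CD8T_act", "B"), roiAreaMm2 = 1)
  inT <- td[td$tls_id == "t1" & td$phenotype == "CD8T_act", ]
  expect_equal(inT$area_mm2, 0.05, tolerance = 1e-9)
  expect_equal(inT$density_mm2, 200, tolerance = 1e-9)
  # inside + outside counts partition the phenotype total
  out <- td[td$tls_id == "outside", ]
  expect_equal(inT$count + out$count[out$phenotype == "CD8T_act"], 11)
  # empty TLS phenotypes score zero
  expect_equal(td$density_mm2[td$tls_id == "t1" & td$phenotype == "B"], 0)
  # disk override
  td2 <- tlsDensity(ct, phenotypes = "CD8T_act", area = "disk",
                    diskRadiusUm = 100)
  expect_equal(td2$area_mm2[1], pi * 0.01)
})

test_that("activation/exhaustion ratios divide densities and flag zeros", {
  dens <- data.frame(tls_id = rep("t1", 4),
                     phenotype = c("CD4T_act", "CD4T_exh",
                                   "CD8T_act", "CD8T_exh"),
                     count = c(4, 2, 3, 0), area_mm2 = 0.1,
                     density_mm2 = c(40, 20, 30, 0))
  rr <- activationExhaustionRatio(dens)
  expect_equal(rr$ratio[rr$lineage == "CD4"], 2.0)
  expect_true(is.na(rr$ratio[rr$lineage == "CD8"]))
  expect_true(rr$undefined[rr$lineage == "CD8"])
  # equal densities give ratio 1
  dens$density_mm2 <- 25
  expect_equal(activationExhaustionRatio(dens)$ratio, c(1, 1))
})

test_that("suppressive cells planted near tumor nests raise anchored density", {
  # tumor nest at the centre with exhausted T enriched around it
  set.seed(5)
  nest <- makeCells(
    x = c(rnorm(20, 500, 30), rnorm(40, 500, 60), runif(40, 0, 1000)),
    y = c(rnorm(20, 500, 30), rnorm(40, 500, 60), runif(40, 0, 1000)),
    phenotype = c(rep("Tumor", 20), rep("CD8T_exh", 40), rep("other", 40)))
  tumorAnch <- densityAround(nest, "Tumor", "CD8T_exh")
  bgAnch <- densityAround(nest, "other", "CD8T_exh")
  expect_gt(mean(tumorAnch$perAnchor$density_mm2),
            mean(bgAnch$perAnchor$density_mm2))
})
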