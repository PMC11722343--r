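test_that("ROI generator respects configuration and records exact truth", {
  cfg <- simConfig(seed = 5, nTriadsPlanted = 7L, nDistractors = 5L)
  r <- simulateROI(cfg)
  expect_s4_class(r$cells, "CellTable")
  expect_length(r$truth$triad_ec_ids, 7)
  expect_length(r$truth$distractor_ec_ids, 5)
  df <- cellData(r$cells)
  expect_true(all(is.finite(df$x_um)))
  # planted contact geometry honors the 2x-axis rule on both sides
  pc <- r$truth$planted_contacts
  ec <- df[match(pc$ec_id, df$cell_id), ]
  ly <- df[match(pc$cell_id, df$cell_id), ]
  d <- sqrt((ec$x_um - ly$x_um)^2 + (ec$y_um - ly$y_um)^2)
  expect_true(all(d[pc$contact] <= 2 * ec$major_axis_um[pc$contact]))
  expect_true(all(d[!pc$contact] > 2 * ec$major_axis_um[!pc$contact]))
})

test_that("ROI generator is deterministic and honors degenerate configs", {
  cfg <- simConfig(seed = 9)
  a <- simulateROI(cfg)
  b <- simulateROI(cfg)
  expect_identical(cellData(a$cells), cellData(b$cells))
  expect_identical(a$truth$triad_ec_ids, b$truth$triad_ec_ids)

  # no triads, no B/T background, no TLS -> no lymphocytes at all
  dens <- simConfig(seed = 2)@params$densities
  dens[c("B", "CD4T", "CD8T", "CD4T_act", "CD8T_act", "CD4T_exh",
         "CD8T_exh", "Treg")] <- 0
  cfg0 <- simConfig(seed = 2, densities = dens, nTriadsPlanted = 0L,
                    nDistractors = 0L, tlsN = 0L)
  r0 <- simulateROI(cfg0)
  ph <- cellData(r0$cells)$phenotype
  expect_false(any(ph %in% c("B", "CD4T", "CD8T", "CD4T_act", "CD8T_act",
                             "CD4T_exh", "CD8T_exh", "Treg")))
})

test_that("impossible planting requests raise capacity errors", {
  cfg <- simConfig(seed = 1, roiSizeUm = c(120, 120), tlsN = 4L,
                   tlsRadiusUm = 120)
  expect_error(simulateROI(cfg), "capacity")
})

test_that("expression generator is deterministic and null when delta = 0", {
  cfg <- simConfig(seed = 13, programDelta = 0)
  a <- simulateExpression(cfg, nCells = 300, nGenes = 1200)
  b <- simulateExpression(cfg, nCells = 300, nGenes = 1200)
  expect_identical(as.matrix(SummarizedExperiment::assay(a$sce, "counts")),
                   as.matrix(SummarizedExperiment::assay(b$sce, "counts")))
  s <- moduleScore(a$sce, a$signatures$AT2)
  g <- a$truth$group
  d <- mean(s[g == "AT2"]) - mean(s[g == "club"])
  se <- sqrt(var(s[g == "AT2"]) / sum(g == "AT2") +
               var(s[g == "club"]) / sum(g == "club"))
  expect_lt(abs(d), 3 * se)
})

test_that("doublet-free config yields no marker doublets", {
  cfg <- simConfig(seed = 4, doubletRate = 0)
  ex <- simulateExpression(cfg, nCells = 150, nGenes = 800)
  expect_length(flagMarkerDoublets(ex$sce), 0)
})

test_that("CNV generator matches its closed-form expectations", {
  # no shift: E[cell score] = sigma^2
  cfg <- simConfig(seed = 3, cnvArmShifts = setNames(numeric(0), character(0)),
                   cnvNoiseSd = 0.08, cnvTumorFrac = 0)
  cv <- simulateCNV(cfg, nCells = 4000, arms = c("1p", "1q", "2p", "2q"))
  sc <- cellCNVScore(armScores(cv$cnv))
  expect_lt(abs(mean(sc) - 0.08^2) / 0.08^2, 0.05)
  # single shifted arm, zero noise: score exactly a^2 / k
  cfg2 <- simConfig(seed = 3, cnvArmShifts = c(`5q` = 0.4), cnvNoiseSd = 0,
                    cnvTumorFrac = 1)
  cv2 <- simulateCNV(cfg2, nCells = 8, arms = c("5q", "6p", "6q", "7p"))
  sc2 <- cellCNVScore(armScores(cv2$cnv))
  expect_equal(unname(sc2), rep(0.4^2 / 4, 8))
  # determinism
  cv3 <- simulateCNV(cfg2, nCells = 8, arms = c("5q", "6p", "6q", "7p"))
  expect_identical(cnvValues(cv2$cnv), cnvValues(cv3$cnv))
})

test_that("spot generator plants recoverable spatially variable genes", {
  cfg <- simConfig(seed = 21, svAmplitude = 3, svNoiseSd = 0.2)
  sp <- simulateSpots(cfg, gridDim = c(12, 12), nGenes = 50, nSVGenes = 4)
  ss <- spatialSignificance(sp$spots)
  top4 <- ss$gene[ss$rank <= 4]
  expect_setequal(top4, sp$truth$sv_genes)
  # determinism
  sp2 <- simulateSpots(cfg, gridDim = c(12, 12), nGenes = 50, nSVGenes = 4)
  expect_identical(spotExpr(sp$spots), spotExpr(sp2$spots))
})

test_that("without planted SV genes no gene is systematically top-ranked", {
  firstRank <- vapply(1:12, function(s) {
    cfg <- simConfig(seed = s)
    sp <- simulateSpots(cfg, gridDim = c(8, 8), nGenes = 30, nSVGenes = 0)
    spatialSignificance(sp$spots)$gene[1]
  }, character(1))
  expect_gt(length(unique(firstRank)), 6)
})
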