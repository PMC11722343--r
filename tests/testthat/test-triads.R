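test_that("contact classification applies the 2x major-axis rule inclusively", {
  ct <- makeCells(x = c(0, 0, 0, 0), y = c(0, 15, 25, 20),
                  phenotype = c("EC", "B", "B", "CD4T"),
                  axis = c(10, NA, NA, NA))
  co <- classifyContacts(ct)
  # B at 15 and T at exactly 20 um are contacts; B at 25 is not
  expect_setequal(co$lymphocyte_id, c("c002", "c004"))
  expect_equal(co$boundary_um, rep(20, 2))
  tr <- detectTriads(co)
  expect_equal(triadROI(tr)$n_triads, 1)
  expect_equal(triadROI(tr)$n_triples, 1)
})

test_that("an EC missing its major axis is a hard error", {
  ct <- makeCells(x = c(0, 5), y = c(0, 0), phenotype = c("EC", "B"),
                  axis = c(NA, NA))
  expect_error(classifyContacts(ct), "major_axis_um")
})

test_that("cross-EC contacts never merge into a triad", {
  # B touches EC1 only, T touches EC2 only
  ct <- makeCells(x = c(0, 500, 10, 510), y = c(0, 0, 0, 0),
                  phenotype = c("EC", "EC", "B", "CD8T"),
                  axis = c(10, 10, NA, NA))
  tr <- detectTriads(classifyContacts(ct))
  expect_equal(sum(triadROI(tr)$n_triads), 0)
  # no lymphocytes at all -> empty contact set
  ec <- makeCells(0, 0, "EC", axis = 10)
  expect_equal(nrow(classifyContacts(ec)), 0)
})

test_that("triple counting multiplies B and T contacts per triad EC", {
  ct <- makeCells(x = c(0, 5, -5, 8, -8, 0), y = c(0, 5, 5, -3, -3, 12),
                  phenotype = c("EC", "B", "B", "CD4T", "CD8T", "CD8T"),
                  axis = c(10, rep(NA, 5)))
  tr <- detectTriads(classifyContacts(ct))
  expect_equal(triadROI(tr)$n_triads, 1)
  expect_equal(triadROI(tr)$n_triples, 2 * 3)
})

test_that("detection equals exhaustive brute force on random fixtures", {
  set.seed(14)
  for (rep in 1:100) {
    n <- sample(30:200, 1)
    ph <- sample(c("EC", "B", "CD4T", "CD8T", "Tumor", "other"), n,
                 replace = TRUE, prob = c(0.15, 0.2, 0.15, 0.15, 0.2, 0.15))
    ct <- makeCells(runif(n, 0, 300), runif(n, 0, 300), ph,
                    axis = ifelse(ph == "EC", runif(n, 5, 20), NA))
    found <- sort(triadEC(detectTriads(classifyContacts(ct)))$ec_id)
    expect_identical(found, bruteForceTriads(ct))
  }
})

test_that("planted triads are recovered exactly across seeds", {
  for (s in 1:50) {
    r <- simulateROI(simConfig(seed = s, nTriadsPlanted = 7L,
                               nDistractors = 5L))
    found <- triadEC(detectTriads(classifyContacts(r$cells)))$ec_id
    truth <- r$truth$triad_ec_ids
    expect_setequal(found, truth)
  }
})

test_that("triad detection is invariant to rotation and translation", {
  for (s in 1:20) {
    r <- simulateROI(simConfig(seed = 100 + s))
    base <- sort(triadEC(detectTriads(classifyContacts(r$cells)))$ec_id)
    set.seed(s)
    tr <- transformCells(r$cells, runif(1, 0, 2 * pi),
                         runif(1, -200, 200), runif(1, -200, 200))
    moved <- sort(triadEC(detectTriads(classifyContacts(tr)))$ec_id)
    expect_identical(moved, base)
  }
})

test_that("permuting lymphocyte positions destroys the planted excess", {
  # TLS-free, sparse-background ROI: under complete spatial randomness
  # dense backgrounds produce EC-lymphocyte coincidences at a rate similar
  # to the planted count, so the planted excess is only identifiable where
  # the chance-coincidence rate is low
  dens <- simConfig()@params$densities
  dens[c("B", "CD4T", "CD8T", "CD4T_act", "CD8T_act", "CD4T_exh",
         "CD8T_exh", "Treg")] <-
    dens[c("B", "CD4T", "CD8T", "CD4T_act", "CD8T_act", "CD4T_exh",
           "CD8T_exh", "Treg")] / 3
  dens["EC"] <- 25
  r <- simulateROI(simConfig(seed = 77, tlsN = 0L, densities = dens))
  df <- cellData(r$cells)
  observed <- sum(triadROI(detectTriads(classifyContacts(r$cells)))$n_triads)
  lymph <- df$phenotype %in% c("B", "CD4T", "CD8T", "CD4T_act", "CD8T_act",
                               "CD4T_exh", "CD8T_exh", "Treg")
  set.seed(123)
  nullCounts <- vapply(1:200, function(i) {
    shuf <- df
    shuf$x_um[lymph] <- runif(sum(lymph), 0, 1000)
    shuf$y_um[lymph] <- runif(sum(lymph), 0, 1000)
    sum(triadROI(detectTriads(classifyContacts(CellTable(shuf))))$n_triads)
  }, numeric(1))
  expect_gt(observed, quantile(nullCounts, 0.95))
})

test_that("triad rates scale with ROI area", {
  perROI <- data.frame(roi_id = c("r1", "r2"), n_triads = c(4L, 0L),
                       n_triples = c(6L, 0L))
  tr <- new("TriadResult", perEC = data.frame(), perROI = perROI)
  rate <- triadRate(tr, c(r1 = 2, r2 = 1))
  expect_equal(rate$triads_per_mm2, c(2, 0))
  half <- triadRate(tr, c(r1 = 1, r2 = 0.5))
  expect_equal(half$triads_per_mm2[1], 2 * rate$triads_per_mm2[1])
  expect_error(triadRate(tr, c(r1 = 2)), "missing")
})

test_that("the boundary multiplier is configurable", {
  ct <- makeCells(x = c(0, 15), y = c(0, 0), phenotype = c("EC", "B"),
                  axis = c(10, NA))
  expect_equal(nrow(classifyContacts(ct)), 1)
  expect_equal(nrow(classifyContacts(ct, boundaryMultiplier = 1)), 0)
})
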