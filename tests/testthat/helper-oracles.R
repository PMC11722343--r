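# Independent brute-force oracles and tiny fixture builders used across the
# suite. The oracles deliberately re-derive each quantity from first
# principles (all-pairs loops, exhaustive enumeration) and never call the
# implementation under test.

# minimal valid cell table
makeCells <- function(x, y, phenotype, axis = NA_real_, roi = "r1",
                      tls = NA_character_, compartment = "NS",
                      patient = "P1") {
  CellTable(data.frame(
    roi_id = roi, cell_id = sprintf("c%03d", seq_along(x)),
    x_um = x, y_um = y, phenotype = phenotype, major_axis_um = axis,
    compartment = compartment, tls_id = tls, patient_id = patient,
    stringsAsFactors = FALSE))
}

# O(n^2) all-pairs triad oracle: returns sorted triad EC cell ids
bruteForceTriads <- function(cells, multiplier = 2,
                             bClasses = "B",
                             tClasses = c("CD4T", "CD8T", "CD4T_act",
                                          "CD8T_act", "CD4T_exh",
                                          "CD8T_exh", "Treg")) {
  df <- cellData(cells)
  out <- character(0)
  for (i in which(df$phenotype == "EC")) {
    hasB <- FALSE; hasT <- FALSE
    for (j in seq_len(nrow(df))) {
      if (i == j) next
      d <- sqrt((df$x_um[i] - df$x_um[j])^2 + (df$y_um[i] - df$y_um[j])^2)
      if (d <= multiplier * df$major_axis_um[i]) {
        if (df$phenotype[j] %in% bClasses) hasB <- TRUE
        if (df$phenotype[j] %in% tClasses) hasT <- TRUE
      }
    }
    if (hasB && hasT) out <- c(out, df$cell_id[i])
  }
  sort(out)
}

# brute-force neighbor count around one anchor index
bruteForceCount <- function(cells, anchorIdx, targets, radius) {
  df <- cellData(cells)
  n <- 0
  for (j in seq_len(nrow(df))) {
    if (j == anchorIdx) next
    if (!df$phenotype[j] %in% targets) next
    d <- sqrt((df$x_um[anchorIdx] - df$x_um[j])^2 +
                (df$y_um[anchorIdx] - df$y_um[j])^2)
    if (d <= radius) n <- n + 1
  }
  n
}

# exhaustive 2^n sign-permutation two-sided p for the signed-rank test
# (ties handled through midranks, zero differences dropped)
enumSignedRankP <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  stats <- signs %*% r
  lower <- mean(stats <= V + 1e-12)
  upper <- mean(stats >= V - 1e-12)
  min(1, 2 * min(lower, upper))
}

# exhaustive rank-sum permutation two-sided p (Mann-Whitney oracle)
enumRankSumP <- function(x, y) {
  vals <- c(x, y)
  r <- rank(vals)
  nx <- length(x)
  W <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(length(vals), nx)
  stats <- apply(combs, 2, function(idx)
    sum(r[idx]) - nx * (nx + 1) / 2)
  lower <- mean(stats <= W + 1e-12)
  upper <- mean(stats >= W - 1e-12)
  min(1, 2 * min(lower, upper))
}

# random rotation+translation of a cell table's coordinates
transformCells <- function(cells, angle, dx, dy) {
  df <- cellData(cells)
  x <- df$x_um * cos(angle) - df$y_um * sin(angle) + dx
  y <- df$x_um * sin(angle) + df$y_um * cos(angle) + dy
  df$x_um <- x
  df$y_um <- y
  CellTable(df)
}

# small QC fixture: 6 cells, 2 planted violations (cell5 low genes,
# cell6 high mito); boundary cells cell1 (exactly 200 genes) and
# cell2 (exactly 15% mito) must survive
makeQCFixture <- function() {
  nGenes <- 300
  genes <- c(sprintf("G%03d", seq_len(nGenes - 2)), "MT-1", "MT-2")
  counts <- matrix(0, nrow = nGenes, ncol = 6,
                   dimnames = list(genes, paste0("cell", 1:6)))
  counts[1:200, 1] <- 1   # exactly 200 detected genes, no mito -> kept
  counts[1:204, 2] <- 1   # 204 non-mito counts ...
  counts["MT-1", 2] <- 36 # ... + 36 mito = 240; 36/240 = 15.0% -> kept
  counts[1:220, 3] <- 2   # ordinary cell
  counts[1:260, 4] <- 1   # ordinary cell
  counts[1:199, 5] <- 3   # 199 detected genes -> removed (low_genes)
  counts[1:240, 6] <- 1   # 240 non-mito ...
  counts["MT-2", 6] <- 60 # ... + 60 mito = 300; 20% -> removed (high_mito)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
    rowData = S4Vectors::DataFrame(gene_id = genes,
                                   mito = grepl("^MT-", genes),
                                   row.names = genes))
}
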