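## Single-cell QC: gene-detection and mitochondrial-fraction filters plus
## the marker-co-expression doublet rule.

#' QC thresholds and lineage marker sets
#'
#' Removal criteria: fewer than `minGenes` or more than `maxGenes` detected
#' genes, or a mitochondrial fraction above `maxMitoFraction`. Boundary
#' values (exactly 200 genes, exactly 6500 genes, exactly 15% mitochondrial
#' reads) are kept, since the removal phrasing is strict ("less than",
#' "more than"). Lineage marker sets drive [flagMarkerDoublets()]; the
#' pan-immune set (PTPRC) is listed but excluded from the multi-lineage
#' rule, because its co-expression with any immune lineage is universal.
#'
#' @param minGenes,maxGenes detected-gene bounds (defaults 200 and 6500).
#' @param maxMitoFraction maximum mitochondrial fraction (default 0.15).
#' @param lineageMarkers named list of marker sets.
#' @return list of class `QCThresholds`.
#' @export
qcThresholds <- function(minGenes = 200, maxGenes = 6500,
                         maxMitoFraction = 0.15,
                         lineageMarkers = list(
                           epithelial = c("SFTPC", "SCGB3A1"),
                           T = "CD3D",
                           B = c("CD79A", "JCHAIN", "MZB1"),
                           myeloid = c("MARCO", "CD163"),
                           pan_immune = "PTPRC")) {
  stopifnot(minGenes < maxGenes,
            maxMitoFraction >= 0, maxMitoFraction <= 1)
  structure(list(minGenes = minGenes, maxGenes = maxGenes,
                 maxMitoFraction = maxMitoFraction,
                 lineageMarkers = lineageMarkers),
            class = "QCThresholds")
}

.detectedGenes <- function(counts) Matrix::colSums(counts > 0)

.mitoFraction <- function(counts, mito) {
  tot <- Matrix::colSums(counts)
  mt <- Matrix::colSums(counts[mito, , drop = FALSE])
  fr <- ifelse(tot > 0, mt / tot, 0)
  fr
}

#' Filter low-quality cells
#'
#' Keeps a cell iff its detected-gene count lies in
#' `[minGenes, maxGenes]` and its mitochondrial fraction is at most
#' `maxMitoFraction` (boundaries inclusive). When no gene carries a
#' mitochondrial flag the mito criterion is skipped with a warning. A cell
#' can violate several criteria; the report assigns one primary reason with
#' priority `low_genes` > `high_genes` > `high_mito`.
#'
#' @param sce SingleCellExperiment with a `counts` assay;
#'   `rowData(sce)$mito` flags mitochondrial genes.
#' @param thresholds a [qcThresholds()] list.
#' @return list with `sce` (kept cells), `report` (data.frame `cell_id`,
#'   `reason` for removed cells) and `summary` (named removal counts,
#'   including `kept`).
#' @export
qcFilter <- function(sce, thresholds = qcThresholds()) {
  counts <- assay(sce, "counts")
  th <- thresholds
  det <- .detectedGenes(counts)
  mito <- rowData(sce)$mito
  if (is.null(mito) || !any(mito, na.rm = TRUE)) {
    warning("no mitochondrial genes flagged; mito criterion skipped")
    mf <- rep(0, ncol(counts))
  } else {
    mf <- .mitoFraction(counts, which(mito))
  }
  low <- det < th$minGenes
  high <- det > th$maxGenes
  hiMito <- mf > th$maxMitoFraction
  remove <- low | high | hiMito
  reason <- rep(NA_character_, ncol(counts))
  reason[hiMito] <- "high_mito"
  reason[high] <- "high_genes"
  reason[low] <- "low_genes"
  report <- data.frame(cell_id = colnames(counts)[remove],
                       reason = reason[remove], stringsAsFactors = FALSE)
  summary <- c(table(factor(report$reason,
                            levels = c("low_genes", "high_genes",
                                       "high_mito"))),
               kept = sum(!remove))
  list(sce = sce[, !remove], report = report, summary = summary)
}

#' Flag marker-co-expression doublets
#'
#' A cell is flagged when markers from two or more distinct lineage sets
#' (pan-immune excluded) each exceed the detection threshold. "Expressing"
#' defaults to raw count > 0.
#'
#' @param sce SingleCellExperiment with a `counts` assay.
#' @param thresholds a [qcThresholds()] list.
#' @param detectionThreshold a marker is expressed when its count is
#'   strictly above this value (default 0).
#' @return character vector of flagged cell ids.
#' @export
flagMarkerDoublets <- function(sce, thresholds = qcThresholds(),
                               detectionThreshold = 0) {
  counts <- assay(sce, "counts")
  sets <- thresholds$lineageMarkers
  sets <- sets[setdiff(names(sets), "pan_immune")]
  missing <- setdiff(unlist(sets), rownames(counts))
  if (length(missing) > 0)
    warning(sprintf("marker gene(s) absent from matrix: %s",
                    paste(missing, collapse = ", ")))
  lineageOn <- vapply(sets, function(g) {
    g <- intersect(g, rownames(counts))
    if (length(g) == 0) return(rep(FALSE, ncol(counts)))
    Matrix::colSums(counts[g, , drop = FALSE] > detectionThreshold) > 0
  }, logical(ncol(counts)))
  if (is.null(dim(lineageOn)))
    lineageOn <- matrix(lineageOn, nrow = 1)
  colnames(counts)[rowSums(lineageOn) >= 2]
}
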