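## Readers/writers for the plain-text interchange formats: cell tables as
## CSV, expression as MatrixMarket + TSV sidecars, signatures as gene lists
## or two-column TSV, CNV as TSV matrix + arm map, spots as TSV.

#' Read a segmented-cell table from CSV
#'
#' CSV dialect: UTF-8, comma-separated, header mandatory. Mandatory columns:
#' `roi_id`, `cell_id`, `x_um`, `y_um`, `phenotype`, `compartment`,
#' `patient_id`; optional `major_axis_um`, `tls_id`. Unknown extra columns
#' are preserved. Rows violating the CellTable invariants (non-finite
#' coordinates, non-positive major axis, duplicate ids, unknown compartment)
#' raise an error naming the offending rows.
#'
#' @param path path to the CSV file.
#' @return A validated [CellTable-class].
#' @export
readCellTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(.cellTableRequired, names(df))
  if (length(miss) > 0)
    stop(sprintf("cell table %s is missing mandatory column(s): %s",
                 path, paste(miss, collapse = ", ")))
  for (cc in c("x_um", "y_um", "major_axis_um")) {
    if (!cc %in% names(df)) next
    raw <- df[[cc]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw) & nzchar(trimws(as.character(raw))))
    if (length(bad) > 0)
      stop(sprintf("non-numeric %s at row(s) %s of %s", cc,
                   paste(head(bad, 5), collapse = ", "), path))
    df[[cc]] <- num
  }
  CellTable(df)
}

#' Write a CellTable to CSV
#' @param x a [CellTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCellTable <- function(x, path) {
  stopifnot(is(x, "CellTable"))
  write.csv(cellData(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a single-cell expression matrix (MatrixMarket + TSV sidecars)
#'
#' @param mtx path to a MatrixMarket sparse count matrix, genes x cells.
#' @param genes path to a TSV with column `gene_id` and optionally `mito`
#'   (logical mitochondrial flag; if absent, genes named `MT-*` are flagged).
#' @param cells path to a TSV with column `cell_id` and optional per-cell
#'   metadata (`patient_id`, `compartment`, `cluster`).
#' @return A [SingleCellExperiment::SingleCellExperiment] with assay
#'   `counts`, `rowData(x)$mito` and the per-cell metadata in `colData`.
#' @export
readExpression <- function(mtx, genes, cells) {
  m <- readMM(mtx)
  if (is(m, "nMatrix")) m <- as(m, "dMatrix")  # pattern matrices: 0/1
  m <- as(as(m, "dMatrix"), "CsparseMatrix")
  gdf <- read.delim(genes, stringsAsFactors = FALSE)
  cdf <- read.delim(cells, stringsAsFactors = FALSE)
  if (nrow(gdf) != nrow(m))
    stop(sprintf("matrix has %d genes but gene file has %d rows",
                 nrow(m), nrow(gdf)))
  if (nrow(cdf) != ncol(m))
    stop(sprintf("matrix has %d cells but cell file has %d rows",
                 ncol(m), nrow(cdf)))
  if (length(m@x) > 0 && any(m@x < 0))
    stop("counts must be non-negative")
  if (anyDuplicated(gdf$gene_id)) stop("gene ids not unique")
  rownames(m) <- gdf$gene_id
  colnames(m) <- cdf$cell_id
  if (!"mito" %in% names(gdf)) gdf$mito <- grepl("^MT-", gdf$gene_id)
  gdf$mito <- as.logical(gdf$mito)
  SingleCellExperiment(assays = list(counts = m),
                       rowData = DataFrame(gdf, row.names = gdf$gene_id),
                       colData = DataFrame(cdf, row.names = cdf$cell_id))
}

#' Write a single-cell expression matrix (MatrixMarket + TSV sidecars)
#' @param sce a SingleCellExperiment with a `counts` assay.
#' @param mtx,genes,cells output paths.
#' @return `mtx`, invisibly.
#' @export
writeExpression <- function(sce, mtx, genes, cells) {
  m <- assay(sce, "counts")
  writeMM(as(as(m, "dMatrix"), "CsparseMatrix"), mtx)
  gdf <- as.data.frame(rowData(sce))
  if (!"gene_id" %in% names(gdf)) gdf$gene_id <- rownames(sce)
  write.table(gdf, genes, sep = "\t", row.names = FALSE, quote = FALSE)
  cdf <- as.data.frame(colData(sce))
  if (!"cell_id" %in% names(cdf)) cdf$cell_id <- colnames(sce)
  write.table(cdf, cells, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(mtx)
}

#' Read gene signatures
#'
#' Two layouts are accepted: a two-column TSV with header `signature`,
#' `gene` (several signatures per file), or a plain one-gene-per-line list
#' (one signature, named after the file).
#'
#' @param path path to the signature file.
#' @param role role tag applied to every signature read (default `""`).
#' @return A named list of [GeneSignature-class] objects.
#' @export
readSignatures <- function(path, role = "") {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("signature", "gene") %in% names(df)))
      stop("two-column signature TSV must have columns 'signature' and 'gene'")
    sp <- split(df$gene, df$signature)
    mapply(function(nm, g) GeneSignature(nm, g, role = role),
           names(sp), sp, SIMPLIFY = FALSE)
  } else {
    genes <- readLines(path)
    genes <- trimws(genes[nzchar(trimws(genes))])
    nm <- sub("\\.[^.]*$", "", basename(path))
    setNames(list(GeneSignature(nm, genes, role = role)), nm)
  }
}

#' Read a CNV matrix and arm map from TSV
#'
#' @param values path to a TSV matrix, cells in rows (first column
#'   `cell_id`), genes in columns.
#' @param arms path to a two-column TSV with header `gene`, `arm`.
#' @param center subtract 1 from all values (1-centred input scale).
#' @return A [CNVMatrix-class].
#' @export
readCNVMatrix <- function(values, arms, center = FALSE) {
  vdf <- read.delim(values, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"cell_id" %in% names(vdf)) stop("CNV matrix TSV needs a cell_id column")
  m <- as.matrix(vdf[, setdiff(names(vdf), "cell_id"), drop = FALSE])
  rownames(m) <- vdf$cell_id
  adf <- read.delim(arms, stringsAsFactors = FALSE)
  if (!all(c("gene", "arm") %in% names(adf)))
    stop("arm map must have columns 'gene' and 'arm'")
  CNVMatrix(m, setNames(adf$arm, adf$gene), center = center)
}

#' Write a CNV matrix and arm map to TSV
#' @param x a [CNVMatrix-class].
#' @param values,arms output paths.
#' @return `values`, invisibly.
#' @export
writeCNVMatrix <- function(x, values, arms) {
  df <- data.frame(cell_id = rownames(cnvValues(x)),
                   as.data.frame(cnvValues(x)), check.names = FALSE)
  write.table(df, values, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(data.frame(gene = names(armMap(x)), arm = unname(armMap(x))),
              arms, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(values)
}

#' Read a spot table from TSV
#'
#' @param expr TSV matrix, genes in rows (first column `gene_id`), spots in
#'   columns.
#' @param coords TSV with columns `spot_id`, `x`, `y`.
#' @param typeCounts optional TSV, spots in rows (first column `spot_id`),
#'   cell types in columns.
#' @return A [SpotTable-class].
#' @export
readSpotTable <- function(expr, coords, typeCounts = NULL) {
  edf <- read.delim(expr, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(edf)) stop("spot expression TSV needs gene_id")
  m <- as.matrix(edf[, setdiff(names(edf), "gene_id"), drop = FALSE])
  rownames(m) <- edf$gene_id
  cdf <- read.delim(coords, stringsAsFactors = FALSE)
  tc <- NULL
  if (!is.null(typeCounts)) {
    tdf <- read.delim(typeCounts, stringsAsFactors = FALSE, check.names = FALSE)
    tc <- as.matrix(tdf[, setdiff(names(tdf), "spot_id"), drop = FALSE])
    rownames(tc) <- tdf$spot_id
    tc <- tc[cdf$spot_id, , drop = FALSE]
  }
  SpotTable(m[, cdf$spot_id, drop = FALSE], cdf, tc)
}

#' Write a spot table to TSV
#' @param x a [SpotTable-class].
#' @param expr,coords output paths; `typeCounts` optional.
#' @param typeCounts optional output path for the cell-type count matrix.
#' @return `expr`, invisibly.
#' @export
writeSpotTable <- function(x, expr, coords, typeCounts = NULL) {
  edf <- data.frame(gene_id = rownames(spotExpr(x)),
                    as.data.frame(spotExpr(x)), check.names = FALSE)
  write.table(edf, expr, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(spotCoords(x), coords, sep = "\t", row.names = FALSE,
              quote = FALSE)
  if (!is.null(typeCounts) && nrow(spotTypeCounts(x)) > 0) {
    tdf <- data.frame(spot_id = rownames(spotTypeCounts(x)),
                      as.data.frame(spotTypeCounts(x)), check.names = FALSE)
    write.table(tdf, typeCounts, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(expr)
}

## round half away from zero, the printed-table convention
.roundHalfUp <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Summarize a cohort attribute as counts and percentages
#'
#' Percentages use half-up rounding to one decimal, matching the convention
#' of printed clinical tables; levels are ordered by descending count (ties
#' broken alphabetically).
#'
#' @param cohort either a data.frame with one row per patient (the attribute
#'   is then tabulated from column `category`), or a named numeric vector of
#'   per-level counts.
#' @param category column name to tabulate when `cohort` is a data.frame.
#' @return data.frame with columns `level`, `count`, `percent`. A zero
#'   total yields an empty table.
#' @examples
#' summarizeCohort(c(female = 25, male = 12))
#' @export
summarizeCohort <- function(cohort, category = NULL) {
  if (is.data.frame(cohort)) {
    if (is.null(category) || !category %in% names(cohort))
      stop("category column not found in cohort table")
    counts <- table(cohort[[category]])
    counts <- setNames(as.numeric(counts), names(counts))
  } else {
    counts <- cohort
  }
  if (any(counts < 0)) stop("counts must be >= 0")
  total <- sum(counts)
  if (total == 0)
    return(data.frame(level = character(0), count = numeric(0),
                      percent = numeric(0)))
  ord <- order(-counts, names(counts))
  counts <- counts[ord]
  data.frame(level = names(counts), count = unname(counts),
             percent = .roundHalfUp(100 * unname(counts) / total, 1),
             stringsAsFactors = FALSE)
}
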