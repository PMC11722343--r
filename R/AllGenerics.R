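## Accessors and show methods.

#' Number of cells in a CellTable
#' @param x a [CellTable-class].
#' @return integer cell count.
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname nCells
#' @export
setMethod("nCells", "CellTable", function(x) nrow(x@cells))

#' Extract the per-cell data.frame of a CellTable
#' @param x a [CellTable-class].
#' @return the underlying data.frame (one row per cell).
#' @export
setGeneric("cellData", function(x) standardGeneric("cellData"))

#' @rdname cellData
#' @export
setMethod("cellData", "CellTable", function(x) x@cells)

#' Subset a CellTable by row
#' @param x a [CellTable-class].
#' @param i row index.
#' @param j unused.
#' @param ... unused.
#' @param drop unused.
#' @export
setMethod("[", "CellTable", function(x, i, j, ..., drop = FALSE) {
  CellTable(x@cells[i, , drop = FALSE])
})

#' Signature genes
#' @param x a [GeneSignature-class].
#' @return character vector of gene ids.
#' @export
setGeneric("sigGenes", function(x) standardGeneric("sigGenes"))

#' @rdname sigGenes
#' @export
setMethod("sigGenes", "GeneSignature", function(x) x@genes)

#' Signature name
#' @param x a [GeneSignature-class].
#' @export
setGeneric("sigName", function(x) standardGeneric("sigName"))

#' @rdname sigName
#' @export
setMethod("sigName", "GeneSignature", function(x) x@name)

#' CNV value matrix (cells x genes)
#' @param x a [CNVMatrix-class].
#' @export
setGeneric("cnvValues", function(x) standardGeneric("cnvValues"))

#' @rdname cnvValues
#' @export
setMethod("cnvValues", "CNVMatrix", function(x) x@values)

#' Gene-to-arm map
#' @param x a [CNVMatrix-class].
#' @return named character vector, gene -> chromosome arm.
#' @export
setGeneric("armMap", function(x) standardGeneric("armMap"))

#' @rdname armMap
#' @export
setMethod("armMap", "CNVMatrix", function(x) x@armMap)

#' Spot expression matrix (genes x spots)
#' @param x a [SpotTable-class].
#' @export
setGeneric("spotExpr", function(x) standardGeneric("spotExpr"))

#' @rdname spotExpr
#' @export
setMethod("spotExpr", "SpotTable", function(x) x@expr)

#' Spot coordinates
#' @param x a [SpotTable-class].
#' @export
setGeneric("spotCoords", function(x) standardGeneric("spotCoords"))

#' @rdname spotCoords
#' @export
setMethod("spotCoords", "SpotTable", function(x) x@coords)

#' Per-spot cell-type counts
#' @param x a [SpotTable-class].
#' @return spots x cell-types matrix (0 x 0 when absent).
#' @export
setGeneric("spotTypeCounts", function(x) standardGeneric("spotTypeCounts"))

#' @rdname spotTypeCounts
#' @export
setMethod("spotTypeCounts", "SpotTable", function(x) x@typeCounts)

#' Edge table of a neighbor graph
#' @param x a [NeighborGraph-class].
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname graphEdges
#' @export
setMethod("graphEdges", "NeighborGraph", function(x) x@edges)

#' Per-EC triad records
#' @param x a [TriadResult-class].
#' @export
setGeneric("triadEC", function(x) standardGeneric("triadEC"))

#' @rdname triadEC
#' @export
setMethod("triadEC", "TriadResult", function(x) x@perEC)

#' Per-ROI triad counts
#' @param x a [TriadResult-class].
#' @export
setGeneric("triadROI", function(x) standardGeneric("triadROI"))

#' @rdname triadROI
#' @export
setMethod("triadROI", "TriadResult", function(x) x@perROI)

#' p-value of a comparison
#' @param x a [ComparisonResult-class].
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname pValue
#' @export
setMethod("pValue", "ComparisonResult", function(x) x@pValue)

#' Simulation parameters as a list
#' @param x a [SimConfig-class].
#' @export
setGeneric("simParams", function(x) standardGeneric("simParams"))

#' @rdname simParams
#' @export
setMethod("simParams", "SimConfig", function(x) x@params)

setMethod("show", "CellTable", function(object) {
  df <- object@cells
  cat(sprintf("CellTable: %d cells, %d ROI(s), %d phenotype(s)\n",
              nrow(df), length(unique(df$roi_id)),
              length(unique(df$phenotype))))
  if (nrow(df) > 0)
    cat("  compartments:",
        paste(sort(unique(df$compartment)), collapse = ", "), "\n")
})

setMethod("show", "GeneSignature", function(object) {
  cat(sprintf("GeneSignature '%s' (%s): %d genes\n", object@name,
              if (nzchar(object@role)) object@role else "unspecified role",
              length(object@genes)))
})

setMethod("show", "CNVMatrix", function(object) {
  cat(sprintf("CNVMatrix: %d cells x %d genes, %d arm(s) mapped\n",
              nrow(object@values), ncol(object@values),
              length(unique(object@armMap))))
})

setMethod("show", "SpotTable", function(object) {
  cat(sprintf("SpotTable: %d genes x %d spots%s\n",
              nrow(object@expr), ncol(object@expr),
              if (nrow(object@typeCounts) > 0)
                sprintf(", %d cell types deconvolved", ncol(object@typeCounts))
              else ""))
})

setMethod("show", "NeighborGraph", function(object) {
  cat(sprintf("NeighborGraph: %d cells, %d edges (radius %.1f um)\n",
              length(object@cellIds), nrow(object@edges), object@radiusUm))
})

setMethod("show", "TriadResult", function(object) {
  cat(sprintf("TriadResult: %d triad EC(s), %d triple(s) across %d ROI(s)\n",
              sum(object@perROI$n_triads), sum(object@perROI$n_triples),
              nrow(object@perROI)))
})

setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf("%s comparison [%s]: statistic = %.4g, p = %.4g %s\n",
              object@design, object@method, object@statistic,
              object@pValue, object@stars))
  if (!is.na(object@gate)) cat("  gate:", object@gate, "\n")
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig (seed %d): ROI %g x %g um, %d planted triads, %d TLS\n",
              as.integer(object@params$seed), object@params$roiSizeUm[1],
              object@params$roiSizeUm[2], object@params$nTriadsPlanted,
              object@params$tlsN))
})
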