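## S4 classes for the core substrates. Expression matrices use
## SingleCellExperiment directly (counts assay + rowData/colData metadata)
## rather than a bespoke class.

.COMPARTMENTS <- c("NL", "NS", "S")

#' CellTable: segmented cells from one or more multiplexed-imaging ROIs
#'
#' One row per segmented cell: centroid coordinates in micrometres (image
#' convention, origin top-left, y increasing downward; all downstream
#' geometry uses distances only, so the convention never enters any
#' computation), phenotype label, optional major-axis length (the longest
#' cell diameter, required for endothelial cells before triad analysis),
#' nodule compartment (`NL` adjacent normal lung, `NS` non-solid/preinvasive,
#' `S` solid/invasive), optional tertiary-lymphoid-structure membership and
#' patient identifier. Extra columns are preserved untouched.
#'
#' @slot cells data.frame with at least the columns `roi_id`, `cell_id`,
#'   `x_um`, `y_um`, `phenotype`, `compartment`, `patient_id`; optionally
#'   `major_axis_um` and `tls_id`.
#' @export
setClass("CellTable", representation(cells = "data.frame"))

.cellTableRequired <- c("roi_id", "cell_id", "x_um", "y_um", "phenotype",
                        "compartment", "patient_id")

setValidity("CellTable", function(object) {
  df <- object@cells
  miss <- setdiff(.cellTableRequired, names(df))
  if (length(miss) > 0)
    return(sprintf("missing mandatory column(s): %s",
                   paste(miss, collapse = ", ")))
  msgs <- character(0)
  if (nrow(df) == 0) return(TRUE)
  for (cc in c("x_um", "y_um")) {
    bad <- which(!is.finite(df[[cc]]))
    if (length(bad) > 0)
      msgs <- c(msgs, sprintf("non-finite %s at row(s) %s", cc,
                              paste(head(bad, 5), collapse = ", ")))
  }
  if ("major_axis_um" %in% names(df)) {
    bad <- which(!is.na(df$major_axis_um) & df$major_axis_um <= 0)
    if (length(bad) > 0)
      msgs <- c(msgs, sprintf("major_axis_um must be > 0 where present; row(s) %s",
                              paste(head(bad, 5), collapse = ", ")))
  }
  key <- paste(df$roi_id, df$cell_id, sep = "\r")
  if (anyDuplicated(key))
    msgs <- c(msgs, sprintf("(roi_id, cell_id) not unique; first duplicate at row %d",
                            which(duplicated(key))[1]))
  badComp <- which(!df$compartment %in% .COMPARTMENTS)
  if (length(badComp) > 0)
    msgs <- c(msgs, sprintf("compartment must be one of %s; row(s) %s",
                            paste(.COMPARTMENTS, collapse = "/"),
                            paste(head(badComp, 5), collapse = ", ")))
  if (length(msgs) > 0) msgs else TRUE
})

#' Construct a CellTable from a data.frame
#'
#' @param cells data.frame of segmented cells; see [CellTable-class] for the
#'   required columns.
#' @return A validated [CellTable-class] object.
#' @examples
#' ct <- CellTable(data.frame(
#'   roi_id = "r1", cell_id = c("c1", "c2"), x_um = c(0, 50), y_um = c(0, 0),
#'   phenotype = c("EC", "B"), major_axis_um = c(10, NA),
#'   compartment = "NS", patient_id = "P1"))
#' nCells(ct)
#' @export
CellTable <- function(cells) {
  cells <- as.data.frame(cells)
  if (!"major_axis_um" %in% names(cells)) cells$major_axis_um <- NA_real_
  if (!"tls_id" %in% names(cells)) cells$tls_id <- NA_character_
  for (cc in intersect(c("roi_id", "cell_id", "phenotype", "compartment",
                         "patient_id", "tls_id"), names(cells)))
    cells[[cc]] <- as.character(cells[[cc]])
  new("CellTable", cells = cells)
}

#' GeneSignature: a named gene list used for scoring
#'
#' @slot name signature name.
#' @slot genes character vector of gene identifiers, no duplicates.
#' @slot role free-text tag describing what the signature captures
#'   (e.g. "AT2", "club", "exhaustion").
#' @export
setClass("GeneSignature",
         representation(name = "character", genes = "character",
                        role = "character"))

setValidity("GeneSignature", function(object) {
  if (length(object@genes) == 0) return("signature has no genes")
  if (anyDuplicated(object@genes)) return("duplicate genes within signature")
  TRUE
})

#' Construct a GeneSignature
#' @param name signature name.
#' @param genes character vector of gene ids.
#' @param role free-text role tag (default `""`).
#' @return A [GeneSignature-class].
#' @examples
#' exhaustedT <- GeneSignature("exhausted_T",
#'   c("LAG3", "PDCD1", "CTLA4", "HAVCR2", "TIGIT", "TOX", "LAYN", "CXCL13"),
#'   role = "exhaustion")
#' @export
GeneSignature <- function(name, genes, role = "") {
  new("GeneSignature", name = as.character(name),
      genes = as.character(genes), role = as.character(role))
}

#' CNVMatrix: per-cell per-gene copy-number values with an arm map
#'
#' Values are deviations from copy-number-neutral (0 = neutral); a
#' 1-centred matrix can be recentred at construction with `center = TRUE`.
#'
#' @slot values numeric matrix, cells x genes, with dimnames.
#' @slot armMap named character vector mapping gene id to chromosome-arm
#'   label (e.g. `"1p"`, `"7q"`).
#' @export
setClass("CNVMatrix",
         representation(values = "matrix", armMap = "character"))

setValidity("CNVMatrix", function(object) {
  v <- object@values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must carry cell rownames and gene colnames")
  if (!all(is.finite(v))) return("CNV values must be finite")
  if (anyDuplicated(colnames(v))) return("gene ids not unique")
  if (anyDuplicated(names(object@armMap))) return("arm map has duplicate genes")
  TRUE
})

#' Construct a CNVMatrix
#' @param values numeric matrix cells x genes (dimnames mandatory).
#' @param armMap named character vector gene -> arm.
#' @param center if `TRUE`, subtract 1 from all values (for matrices on a
#'   1 = neutral scale).
#' @return A [CNVMatrix-class].
#' @export
CNVMatrix <- function(values, armMap, center = FALSE) {
  values <- as.matrix(values)
  if (isTRUE(center)) values <- values - 1
  new("CNVMatrix", values = values,
      armMap = setNames(as.character(armMap), names(armMap)))
}

#' SpotTable: spot-level spatial transcriptomics expression
#'
#' Expression is expected on a normalized scale (log1p of depth-scaled
#' counts); the synthetic generator emits it directly on that scale.
#'
#' @slot expr numeric matrix, genes x spots, finite and >= 0.
#' @slot coords data.frame with columns `spot_id`, `x`, `y`.
#' @slot typeCounts numeric matrix spots x cell-types (0-column matrix when
#'   no deconvolution counts are attached).
#' @export
setClass("SpotTable",
         representation(expr = "matrix", coords = "data.frame",
                        typeCounts = "matrix"))

setValidity("SpotTable", function(object) {
  if (anyDuplicated(object@coords$spot_id)) return("spot ids not unique")
  if (ncol(object@expr) != nrow(object@coords))
    return(sprintf("expr has %d spots but coords has %d rows",
                   ncol(object@expr), nrow(object@coords)))
  if (!all(is.finite(object@expr)) || any(object@expr < 0))
    return("expression must be finite and >= 0")
  if (nrow(object@typeCounts) > 0 &&
      nrow(object@typeCounts) != ncol(object@expr))
    return("typeCounts rows must match number of spots")
  TRUE
})

#' Construct a SpotTable
#' @param expr genes x spots numeric matrix (rownames = genes,
#'   colnames = spot ids).
#' @param coords data.frame with `spot_id`, `x`, `y`.
#' @param typeCounts optional spots x cell-type count matrix.
#' @return A [SpotTable-class].
#' @export
SpotTable <- function(expr, coords, typeCounts = NULL) {
  expr <- as.matrix(expr)
  coords <- as.data.frame(coords)
  coords$spot_id <- as.character(coords$spot_id)
  if (is.null(typeCounts))
    typeCounts <- matrix(0, nrow = 0, ncol = 0)
  new("SpotTable", expr = expr, coords = coords,
      typeCounts = as.matrix(typeCounts))
}

#' NeighborGraph: cell-cell proximity graph of one ROI
#'
#' Undirected edges connect cells whose centroid distance is at most the
#' radius (inclusive), following the 100-micrometre neighborhood convention.
#'
#' @slot cellIds character vector of node ids.
#' @slot edges data.frame with columns `from`, `to`, `dist_um`
#'   (each undirected pair listed once, `from` < `to` in table order).
#' @slot radiusUm the neighborhood radius in micrometres.
#' @export
setClass("NeighborGraph",
         representation(cellIds = "character", edges = "data.frame",
                        radiusUm = "numeric"))

setValidity("NeighborGraph", function(object) {
  e <- object@edges
  if (nrow(e) > 0) {
    if (any(e$from == e$to)) return("self-edges not allowed")
    if (any(e$dist_um > object@radiusUm + 1e-9))
      return("edge distance exceeds radius")
  }
  TRUE
})

#' TriadResult: BET-triad detection output
#'
#' A triad endothelial cell (EC) has at least one B-cell and one T-cell
#' contact; `n_triads` counts qualifying ECs (EC-centric convention) and
#' `n_triples` counts distinct (B, EC, T) combinations.
#'
#' @slot perEC data.frame, one row per triad EC: `roi_id`, `ec_id`,
#'   `n_b_contacts`, `n_t_contacts`, `n_triples`.
#' @slot perROI data.frame, one row per ROI: `roi_id`, `n_triads`,
#'   `n_triples`.
#' @export
setClass("TriadResult",
         representation(perEC = "data.frame", perROI = "data.frame"))

#' ComparisonResult: outcome of one statistical comparison
#'
#' @slot design one of `"paired"`, `"unpaired"`, `"multigroup"`.
#' @slot method test actually used for the headline p-value.
#' @slot statistic named test statistic.
#' @slot pValue two-sided p-value.
#' @slot nPerGroup sample sizes.
#' @slot gate gate outcome for the gated unpaired design
#'   (`"nonparametric"`/`"parametric"`), `NA` otherwise.
#' @slot stars significance stars: `*` < 0.05, `**` < 0.01, `***` < 0.001,
#'   `****` < 0.0001.
#' @slot details list with branch results and diagnostics.
#' @export
setClass("ComparisonResult",
         representation(design = "character", method = "character",
                        statistic = "numeric", pValue = "numeric",
                        nPerGroup = "integer", gate = "character",
                        stars = "character", details = "list"))

setValidity("ComparisonResult", function(object) {
  p <- object@pValue
  if (length(p) != 1 || is.na(p) || p < 0 || p > 1)
    return("pValue must be a single value in [0, 1]")
  TRUE
})

#' SimConfig: parameters of the synthetic-data generator
#'
#' Holds every knob of the generators; see [simConfig()] for defaults and
#' units. The seed fixes all generator output bit-for-bit.
#'
#' @slot params named list of generator parameters.
#' @export
setClass("SimConfig", representation(params = "list"))

setValidity("SimConfig", function(object) {
  p <- object@params
  if (!is.numeric(p$seed) || length(p$seed) != 1)
    return("seed must be a single number")
  if (any(p$densities < 0)) return("densities must be >= 0")
  fr <- c(p$tlsBCoreFrac, p$doubletRate, p$programFrac, p$mitoMean)
  if (any(fr < 0 | fr > 1)) return("fractions must lie in [0, 1]")
  TRUE
})
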