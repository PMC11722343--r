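## Proximity graph and neighborhood densities: edges connect centroids
## within 100 um (inclusive); anchored densities are counts within the
## radius divided by the disc area, reported per mm^2.

.singleROI <- function(df) {
  if (length(unique(df$roi_id)) > 1)
    stop("one ROI at a time; subset the CellTable first")
  invisible(df)
}

#' Build the cell-cell neighbor graph of one ROI
#'
#' Undirected edge between two cells iff their centroid Euclidean distance
#' is at most `radiusUm` (inclusive boundary).
#'
#' @param cells a [CellTable-class] restricted to one ROI.
#' @param radiusUm neighborhood radius in micrometres (default 100).
#' @return A [NeighborGraph-class].
#' @export
buildNeighborGraph <- function(cells, radiusUm = 100) {
  if (radiusUm <= 0) stop("radiusUm must be > 0")
  df <- cellData(cells)
  .singleROI(df)
  n <- nrow(df)
  if (n < 2) {
    return(new("NeighborGraph", cellIds = df$cell_id,
               edges = data.frame(from = character(0), to = character(0),
                                  dist_um = numeric(0)),
               radiusUm = radiusUm))
  }
  d <- as.matrix(dist(cbind(df$x_um, df$y_um)))
  idx <- which(upper.tri(d) & d <= radiusUm, arr.ind = TRUE)
  edges <- data.frame(from = df$cell_id[idx[, 1]],
                      to = df$cell_id[idx[, 2]],
                      dist_um = d[idx], stringsAsFactors = FALSE)
  new("NeighborGraph", cellIds = df$cell_id, edges = edges,
      radiusUm = radiusUm)
}

#' Target-cell density around anchor cells
#'
#' For every anchor cell, counts target-phenotype cells within `radiusUm`
#' (anchor itself excluded; inclusive boundary) and converts the count to a
#' density in cells/mm^2 by dividing by the disc area. ROIs without anchor
#' cells are omitted with a note.
#'
#' @param cells a [CellTable-class] (one or several ROIs).
#' @param anchors anchor phenotype(s), e.g. `"Tumor"`.
#' @param targets target phenotype(s).
#' @param radiusUm neighborhood radius in micrometres (default 100).
#' @return list with `perAnchor` (data.frame `roi_id`, `anchor_id`,
#'   `count`, `density_mm2`) and `perROI` (data.frame `roi_id`,
#'   `n_anchors`, `mean_count`, `mean_density_mm2`, `pooled_density_mm2`;
#'   the per-ROI aggregate is the mean over anchors, with the pooled
#'   count-over-total-area variant alongside).
#' @export
densityAround <- function(cells, anchors, targets, radiusUm = 100) {
  if (radiusUm <= 0) stop("radiusUm must be > 0")
  df <- cellData(cells)
  areaMm2 <- pi * radiusUm^2 / 1e6
  perAnchor <- list()
  perROI <- list()
  for (roi in unique(df$roi_id)) {
    sub <- df[df$roi_id == roi, , drop = FALSE]
    anc <- sub[sub$phenotype %in% anchors, , drop = FALSE]
    if (nrow(anc) == 0) {
      message(sprintf("ROI %s has no anchor cells; omitted", roi))
      next
    }
    tgt <- sub[sub$phenotype %in% targets, , drop = FALSE]
    cnt <- vapply(seq_len(nrow(anc)), function(i) {
      if (nrow(tgt) == 0) return(0L)
      d <- sqrt((tgt$x_um - anc$x_um[i])^2 + (tgt$y_um - anc$y_um[i])^2)
      sum(d <= radiusUm & tgt$cell_id != anc$cell_id[i])
    }, integer(1))
    perAnchor[[roi]] <- data.frame(roi_id = roi, anchor_id = anc$cell_id,
                                   count = cnt,
                                   density_mm2 = cnt / areaMm2,
                                   stringsAsFactors = FALSE)
    perROI[[roi]] <- data.frame(roi_id = roi, n_anchors = nrow(anc),
                                mean_count = mean(cnt),
                                mean_density_mm2 = mean(cnt / areaMm2),
                                pooled_density_mm2 =
                                  sum(cnt) / (nrow(anc) * areaMm2),
                                stringsAsFactors = FALSE)
  }
  list(perAnchor = if (length(perAnchor) > 0)
         do.call(rbind, c(perAnchor, make.row.names = FALSE)) else
           data.frame(),
       perROI = if (length(perROI) > 0)
         do.call(rbind, c(perROI, make.row.names = FALSE)) else data.frame())
}

## polygon area of the convex hull of a point set (shoelace), in um^2
.hullAreaUm2 <- function(x, y) {
  if (length(x) < 3) return(0)
  h <- chull(x, y)
  hx <- x[h]; hy <- y[h]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

#' Phenotype densities inside (and outside) tertiary lymphoid structures
#'
#' TLS membership comes from the `tls_id` column. The TLS area is the
#' convex hull of its member cells by default; a fixed disk radius can be
#' supplied instead. When `roiAreaMm2` is given, the outside-TLS
#' counterpart is computed on the ROI complement (`tls_id = "outside"`).
#'
#' @param cells a [CellTable-class] restricted to one ROI.
#' @param phenotypes phenotypes to quantify.
#' @param area `"hull"` (default) or `"disk"`.
#' @param diskRadiusUm disk radius when `area = "disk"`.
#' @param roiAreaMm2 optional total ROI area for the outside complement.
#' @return data.frame: `tls_id`, `phenotype`, `count`, `area_mm2`,
#'   `density_mm2`.
#' @export
tlsDensity <- function(cells, phenotypes, area = c("hull", "disk"),
                       diskRadiusUm = NULL, roiAreaMm2 = NULL) {
  area <- match.arg(area)
  df <- cellData(cells)
  .singleROI(df)
  inTls <- !is.na(df$tls_id) & nzchar(df$tls_id)
  ids <- unique(df$tls_id[inTls])
  out <- list()
  totalTlsArea <- 0
  for (tid in ids) {
    mem <- df[inTls & df$tls_id == tid, , drop = FALSE]
    aMm2 <- if (area == "disk") {
      if (is.null(diskRadiusUm)) stop("diskRadiusUm required for area='disk'")
      pi * diskRadiusUm^2 / 1e6
    } else {
      .hullAreaUm2(mem$x_um, mem$y_um) / 1e6
    }
    if (aMm2 <= 0) stop(sprintf("TLS %s has zero area", tid))
    totalTlsArea <- totalTlsArea + aMm2
    cnt <- vapply(phenotypes, function(ph) sum(mem$phenotype == ph),
                  integer(1))
    out[[tid]] <- data.frame(tls_id = tid, phenotype = phenotypes,
                             count = cnt, area_mm2 = aMm2,
                             density_mm2 = cnt / aMm2,
                             stringsAsFactors = FALSE)
  }
  if (!is.null(roiAreaMm2)) {
    outsideArea <- roiAreaMm2 - totalTlsArea
    if (outsideArea <= 0) stop("outside-TLS area is not positive")
    outs <- df[!inTls, , drop = FALSE]
    cnt <- vapply(phenotypes, function(ph) sum(outs$phenotype == ph),
                  integer(1))
    out[["outside"]] <- data.frame(tls_id = "outside",
                                   phenotype = phenotypes, count = cnt,
                                   area_mm2 = outsideArea,
                                   density_mm2 = cnt / outsideArea,
                                   stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Activation/exhaustion density ratios per TLS and lineage
#'
#' Ratio of activated to exhausted T-cell density within each TLS, per
#' lineage (CD4, CD8 by default). A zero exhausted density yields a missing
#' ratio flagged in `undefined`, never an infinity.
#'
#' @param tlsDensities data.frame from [tlsDensity()].
#' @param lineages named list mapping lineage to
#'   `c(activated = ..., exhausted = ...)` phenotype labels.
#' @return data.frame: `tls_id`, `lineage`, `activated_density`,
#'   `exhausted_density`, `ratio`, `undefined`.
#' @export
activationExhaustionRatio <- function(tlsDensities,
                                      lineages = list(
                                        CD4 = c(activated = "CD4T_act",
                                                exhausted = "CD4T_exh"),
                                        CD8 = c(activated = "CD8T_act",
                                                exhausted = "CD8T_exh"))) {
  out <- list()
  for (tid in unique(tlsDensities$tls_id)) {
    sub <- tlsDensities[tlsDensities$tls_id == tid, , drop = FALSE]
    for (lin in names(lineages)) {
      act <- sub$density_mm2[sub$phenotype == lineages[[lin]]["activated"]]
      exh <- sub$density_mm2[sub$phenotype == lineages[[lin]]["exhausted"]]
      if (length(act) == 0 || length(exh) == 0) next
      undef <- exh == 0
      out[[length(out) + 1]] <- data.frame(
        tls_id = tid, lineage = lin, activated_density = act,
        exhausted_density = exh,
        ratio = if (undef) NA_real_ else act / exh,
        undefined = undef, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(tls_id = character(0), lineage = character(0),
                      activated_density = numeric(0),
                      exhausted_density = numeric(0), ratio = numeric(0),
                      undefined = logical(0)))
  do.call(rbind, c(out, make.row.names = FALSE))
}
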