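## BET (B cell - endothelium - T cell) triad detection. An endothelial
## cell's contact boundary is twice its major-axis length (the longest cell
## diameter); a lymphocyte is in contact when its centroid falls within
## that boundary (inclusive). A triad EC has at least one B and one T
## contact simultaneously.

.DEFAULT_T_CLASSES <- c("CD4T", "CD8T", "CD4T_act", "CD8T_act",
                        "CD4T_exh", "CD8T_exh", "Treg")

#' Classify EC-lymphocyte contacts
#'
#' Computes, per ROI, the Euclidean distance between every endothelial cell
#' and every B or T cell and flags contact when the distance is at most
#' `boundaryMultiplier` x that EC's major axis. Pairs beyond the boundary
#' are dropped; single-contact and no-contact ECs are pruned later, at the
#' triad-detection step.
#'
#' @param cells a [CellTable-class].
#' @param ecClass phenotype label of endothelial cells (default `"EC"`).
#' @param bClasses,tClasses phenotype labels counted as B and T cells.
#' @param boundaryMultiplier boundary in units of the EC major axis
#'   (default 2).
#' @return data.frame of contact records: `roi_id`, `ec_id`,
#'   `lymphocyte_id`, `class` (`"B"`/`"T"`), `distance_um`, `boundary_um`.
#' @export
classifyContacts <- function(cells, ecClass = "EC", bClasses = "B",
                             tClasses = .DEFAULT_T_CLASSES,
                             boundaryMultiplier = 2) {
  df <- cellData(cells)
  ec <- df[df$phenotype %in% ecClass, , drop = FALSE]
  noAxis <- ec$cell_id[is.na(ec$major_axis_um)]
  if (length(noAxis) > 0)
    stop(sprintf("EC(s) missing major_axis_um: %s",
                 paste(head(noAxis, 10), collapse = ", ")))
  lym <- df[df$phenotype %in% c(bClasses, tClasses), , drop = FALSE]
  empty <- data.frame(roi_id = character(0), ec_id = character(0),
                      lymphocyte_id = character(0), class = character(0),
                      distance_um = numeric(0), boundary_um = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(ec) == 0 || nrow(lym) == 0) return(empty)
  out <- list()
  for (roi in unique(ec$roi_id)) {
    e <- ec[ec$roi_id == roi, , drop = FALSE]
    l <- lym[lym$roi_id == roi, , drop = FALSE]
    if (nrow(l) == 0) next
    cls <- ifelse(l$phenotype %in% bClasses, "B", "T")
    for (i in seq_len(nrow(e))) {
      bnd <- boundaryMultiplier * e$major_axis_um[i]
      d <- sqrt((l$x_um - e$x_um[i])^2 + (l$y_um - e$y_um[i])^2)
      hit <- d <= bnd
      if (!any(hit)) next
      out[[length(out) + 1]] <- data.frame(
        roi_id = roi, ec_id = e$cell_id[i],
        lymphocyte_id = l$cell_id[hit], class = cls[hit],
        distance_um = d[hit], boundary_um = bnd, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty)
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Detect BET triads from contact records
#'
#' An EC is a triad iff it has at least one B contact and at least one T
#' contact; ECs with contacts of only one class ("single contact") are
#' removed. `n_triads` counts qualifying ECs (EC-centric convention);
#' `n_triples` additionally counts distinct (B, EC, T) combinations
#' (#B contacts x #T contacts per triad EC).
#'
#' @param contacts data.frame from [classifyContacts()].
#' @param roiIds optional character vector of ROI ids to report even when
#'   they carry no contact (rows with zero counts).
#' @return A [TriadResult-class].
#' @export
detectTriads <- function(contacts, roiIds = NULL) {
  rois <- unique(c(as.character(contacts$roi_id), roiIds))
  perEC <- list()
  perROI <- list()
  for (roi in rois) {
    sub <- contacts[contacts$roi_id == roi, , drop = FALSE]
    if (nrow(sub) > 0) {
      nB <- tapply(sub$class == "B", sub$ec_id, sum)
      nT <- tapply(sub$class == "T", sub$ec_id, sum)
      keep <- nB > 0 & nT > 0
      if (any(keep)) {
        perEC[[roi]] <- data.frame(
          roi_id = roi, ec_id = names(nB)[keep],
          n_b_contacts = as.integer(nB[keep]),
          n_t_contacts = as.integer(nT[keep]),
          n_triples = as.integer(nB[keep] * nT[keep]),
          stringsAsFactors = FALSE)
      }
    }
    nTriads <- if (is.null(perEC[[roi]])) 0L else nrow(perEC[[roi]])
    nTriples <- if (is.null(perEC[[roi]])) 0L else
      sum(perEC[[roi]]$n_triples)
    perROI[[roi]] <- data.frame(roi_id = roi, n_triads = nTriads,
                                n_triples = nTriples,
                                stringsAsFactors = FALSE)
  }
  emptyEC <- data.frame(roi_id = character(0), ec_id = character(0),
                        n_b_contacts = integer(0), n_t_contacts = integer(0),
                        n_triples = integer(0), stringsAsFactors = FALSE)
  new("TriadResult",
      perEC = if (length(perEC) > 0)
        do.call(rbind, c(perEC, make.row.names = FALSE)) else emptyEC,
      perROI = if (length(perROI) > 0)
        do.call(rbind, c(perROI, make.row.names = FALSE)) else
          data.frame(roi_id = character(0), n_triads = integer(0),
                     n_triples = integer(0)))
}

#' Triad rate per mm^2
#'
#' @param result a [TriadResult-class].
#' @param roiAreaMm2 named numeric vector of ROI areas in mm^2 (names =
#'   roi ids), or a single value recycled to all ROIs.
#' @return the per-ROI data.frame with an added `triads_per_mm2` column.
#' @export
triadRate <- function(result, roiAreaMm2) {
  df <- triadROI(result)
  if (is.null(names(roiAreaMm2)))
    area <- rep_len(roiAreaMm2, nrow(df))
  else {
    area <- roiAreaMm2[df$roi_id]
    if (any(is.na(area)))
      stop("roiAreaMm2 missing for some ROI(s)")
  }
  if (any(area <= 0)) stop("ROI area must be > 0")
  df$area_mm2 <- as.numeric(area)
  df$triads_per_mm2 <- df$n_triads / df$area_mm2
  df
}
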