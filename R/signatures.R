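## Bin-matched gene-module scoring and AT2-like vs club-like cell-of-origin
## assignment.

#' Normalize counts for scoring
#'
#' log1p of counts scaled to 10,000 per cell, the standard single-cell
#' normalization assumed by the module score.
#'
#' @param counts genes x cells count matrix (dense or sparse).
#' @param scale target library size (default 1e4).
#' @return matrix of normalized log expression.
#' @export
normalizeForScoring <- function(counts, scale = 1e4) {
  lib <- Matrix::colSums(counts)
  lib[lib == 0] <- 1
  out <- log1p(Matrix::t(Matrix::t(counts) / lib) * scale)
  as.matrix(out)
}

#' Module-score parameters
#'
#' The canonical bin-matched control scheme: genes are binned into `nBins`
#' equal-frequency bins of gene-wise average expression, and `nCtrl`
#' control genes are sampled per signature gene from its bin (signature
#' genes themselves are never used as controls).
#'
#' @param nBins number of expression bins (default 24).
#' @param nCtrl control genes sampled per signature gene (default 100).
#' @param seed seed for the control draw (default 1).
#' @return list of class `ModuleScoreParams`.
#' @export
moduleScoreParams <- function(nBins = 24, nCtrl = 100, seed = 1L) {
  stopifnot(nBins >= 1, nCtrl >= 1)
  structure(list(nBins = nBins, nCtrl = nCtrl, seed = seed),
            class = "ModuleScoreParams")
}

## accept an SCE (normalizing its counts) or an already-normalized matrix
.scoringMatrix <- function(x) {
  if (is(x, "SingleCellExperiment") || is(x, "SummarizedExperiment")) {
    if ("logcounts" %in% assayNames(x)) as.matrix(assay(x, "logcounts"))
    else normalizeForScoring(assay(x, "counts"))
  } else {
    as.matrix(x)
  }
}

#' Bin-matched gene-module score
#'
#' Per cell: mean normalized expression of the signature genes minus the
#' mean over control genes sampled (seeded) from expression bins matched on
#' gene-wise average expression. A matrix input is used as-is and must
#' already be on a normalized log scale; a SingleCellExperiment is
#' normalized with [normalizeForScoring()] unless it carries a `logcounts`
#' assay.
#'
#' @param x SingleCellExperiment or normalized genes x cells matrix.
#' @param sig a [GeneSignature-class].
#' @param params a [moduleScoreParams()] list.
#' @return named numeric vector, one score per cell.
#' @export
moduleScore <- function(x, sig, params = moduleScoreParams()) {
  m <- .scoringMatrix(x)
  sigGenes <- intersect(sigGenes(sig), rownames(m))
  if (length(sigGenes) == 0)
    stop(sprintf("no gene of signature '%s' is present in the matrix",
                 sigName(sig)))
  sigExpr <- m[sigGenes, , drop = FALSE]
  if (all(sigExpr == 0))
    warning(sprintf("signature '%s' genes are constant zero", sigName(sig)))

  avg <- rowMeans(m)
  ## cap the bin count so bins hold a handful of genes even on tiny
  ## matrices (a signature gene needs non-signature bin mates as controls)
  nBins <- max(1, min(params$nBins, floor(nrow(m) / 4)))
  bin <- if (nBins == 1) rep(1L, nrow(m)) else
    as.integer(cut(rank(avg, ties.method = "first"), breaks = nBins))
  names(bin) <- rownames(m)

  ctrl <- character(0)
  allSig <- sigGenes(sig)
  .withSeed(params$seed, {
    for (g in sigGenes) {
      cand <- setdiff(names(bin)[bin == bin[g]], allSig)
      if (length(cand) == 0) next
      ctrl <- c(ctrl, sample(cand, min(params$nCtrl, length(cand))))
    }
  })
  ctrl <- unique(ctrl)
  if (length(ctrl) == 0)
    stop("no control genes available outside the signature")
  colMeans(m[sigGenes, , drop = FALSE]) - colMeans(m[ctrl, , drop = FALSE])
}

#' Label cells from a pair of scores
#'
#' Argmax rule: `AT2-like` when the AT2 score is higher, `club-like` when
#' the club score is higher, `tied` on exact equality.
#'
#' @param scoreAT2,scoreClub numeric vectors of equal length.
#' @return character vector of labels.
#' @export
originLabels <- function(scoreAT2, scoreClub) {
  stopifnot(length(scoreAT2) == length(scoreClub))
  ifelse(scoreAT2 > scoreClub, "AT2-like",
         ifelse(scoreClub > scoreAT2, "club-like", "tied"))
}

#' Classify tumor cells as AT2-like or club-like
#'
#' Computes the AT2 and club module scores per cell and assigns the label
#' with the higher score (exact tie -> `tied`).
#'
#' @param x SingleCellExperiment or normalized matrix (see [moduleScore()]).
#' @param sigAT2,sigClub AT2 and club [GeneSignature-class] objects.
#' @param params a [moduleScoreParams()] list.
#' @return data.frame: `cell_id`, `score_AT2`, `score_club`, `label`.
#' @export
classifyTumorCells <- function(x, sigAT2, sigClub,
                               params = moduleScoreParams()) {
  sAT2 <- moduleScore(x, sigAT2, params)
  sClub <- moduleScore(x, sigClub, params)
  data.frame(cell_id = names(sAT2), score_AT2 = unname(sAT2),
             score_club = unname(sClub),
             label = originLabels(sAT2, sClub),
             stringsAsFactors = FALSE)
}

#' Assign a per-patient tumor cell-of-origin call
#'
#' A patient is `unassigned` when fewer than `minCells` tumor cells are
#' available, when no label reaches the `minMajority` fraction (majority
#' method), or when the winning score's patient mean is below `minScore`
#' (positive enrichment required by default). Otherwise the patient is
#' called by the majority cell label, or — with `method = "mean"` — by
#' comparing the patient-level mean AT2 and club scores.
#'
#' @param cellCalls data.frame as returned by [classifyTumorCells()], plus
#'   a `patient_id` column; restrict rows to tumor cells beforehand.
#' @param minCells minimum tumor cells per patient (default 20).
#' @param minMajority minimum winning-label fraction (default 0.6).
#' @param minScore minimum patient-mean winning score (default 0).
#' @param method `"majority"` (default) or `"mean"`.
#' @return data.frame, one row per patient: `patient_id`, `n_tumor_cells`,
#'   `fraction_AT2_like`, `mean_score_AT2`, `mean_score_club`, `label`.
#' @export
assignPatientOrigin <- function(cellCalls, minCells = 20, minMajority = 0.6,
                                minScore = 0,
                                method = c("majority", "mean")) {
  method <- match.arg(method)
  if (nrow(cellCalls) == 0)
    return(data.frame(patient_id = character(0), n_tumor_cells = integer(0),
                      fraction_AT2_like = numeric(0),
                      mean_score_AT2 = numeric(0),
                      mean_score_club = numeric(0), label = character(0)))
  if (!"patient_id" %in% names(cellCalls))
    cellCalls$patient_id <- "P1"
  sp <- split(cellCalls, cellCalls$patient_id)
  out <- lapply(names(sp), function(pid) {
    df <- sp[[pid]]
    n <- nrow(df)
    fAT2 <- mean(df$label == "AT2-like")
    mAT2 <- mean(df$score_AT2)
    mClub <- mean(df$score_club)
    label <- "unassigned"
    if (n >= minCells) {
      if (method == "majority") {
        fClub <- mean(df$label == "club-like")
        winFrac <- max(fAT2, fClub)
        win <- if (fAT2 >= fClub) "AT2-like" else "club-like"
        winScore <- if (win == "AT2-like") mAT2 else mClub
        if (winFrac >= minMajority && fAT2 != fClub && winScore >= minScore)
          label <- win
      } else {
        if (mAT2 != mClub) {
          win <- if (mAT2 > mClub) "AT2-like" else "club-like"
          winScore <- max(mAT2, mClub)
          if (winScore >= minScore) label <- win
        }
      }
    }
    data.frame(patient_id = pid, n_tumor_cells = n,
               fraction_AT2_like = fAT2, mean_score_AT2 = mAT2,
               mean_score_club = mClub, label = label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
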