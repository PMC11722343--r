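## Spot-level analyses: spatial-significance gene ranking (across-spot
## standard deviation of normalized expression), candidate-gene selection
## with cross-sample intersection, AUCell-style rank-recovery signature
## scoring and cell-type coexistence correlation.

#' Spatial significance scores
#'
#' Per gene, the unbiased (n-1) standard deviation of its normalized
#' expression across all spots of one sample. Constant genes score 0.
#'
#' @param spots a [SpotTable-class] (expression already normalized).
#' @return data.frame: `gene`, `score`, `rank` (1 = most variable; ties
#'   broken by gene id so ranks are deterministic).
#' @export
spatialSignificance <- function(spots) {
  m <- spotExpr(spots)
  score <- apply(m, 1, sd)
  ord <- order(-score, rownames(m))
  out <- data.frame(gene = rownames(m), score = unname(score),
                    stringsAsFactors = FALSE)
  out$rank <- match(seq_len(nrow(out)), ord)
  out[order(out$rank), , drop = FALSE]
}

#' Select candidate spatial genes and their cross-sample intersection
#'
#' Takes the `nTop` genes by spatial-significance score in every sample
#' (ties broken lexicographically by gene id) and intersects the per-sample
#' sets.
#'
#' @param scoreList list of data.frames from [spatialSignificance()], one
#'   per sample.
#' @param nTop genes kept per sample (default 5000).
#' @return list with `perSample` (list of character vectors) and
#'   `intersection` (character vector).
#' @export
selectCandidateGenes <- function(scoreList, nTop = 5000) {
  if (is.data.frame(scoreList)) scoreList <- list(scoreList)
  perSample <- lapply(scoreList, function(df) {
    ord <- order(-df$score, df$gene)
    df$gene[ord][seq_len(min(nTop, nrow(df)))]
  })
  list(perSample = perSample,
       intersection = Reduce(intersect, perSample))
}

## recovery-curve AUC of one ranked gene list, window of w ranks
.rankRecoveryAUC <- function(hitRanks, w, m) {
  hitRanks <- hitRanks[hitRanks <= w]
  if (length(hitRanks) == 0) return(0)
  ## y(x) = number of hits at rank <= x; AUC = sum_{x=1..w} y(x)
  auc <- sum(w - hitRanks + 1)
  mEff <- min(m, w)
  maxAuc <- mEff * (mEff + 1) / 2 + (w - mEff) * mEff
  auc / maxAuc
}

#' Rank-recovery (AUCell-style) signature score per spot
#'
#' Per spot, genes are ranked by expression descending (ties broken by gene
#' id); the score is the area under the cumulative signature-recovery curve
#' restricted to the top `ceiling(topFraction * nGenes)` ranks, normalized
#' by the maximal achievable area. Scores lie in \[0, 1\]: 1 when all
#' signature genes occupy the top ranks, 0 when none enters the window.
#' Because only ranks are used, the score is invariant to any monotone
#' transform of a spot's expression profile.
#'
#' @param spots a [SpotTable-class] or genes x spots matrix.
#' @param sig a [GeneSignature-class].
#' @param topFraction fraction of genes forming the ranking window
#'   (default 0.05).
#' @return named numeric vector, one score per spot.
#' @export
rankRecoveryScore <- function(spots, sig, topFraction = 0.05) {
  m <- if (is(spots, "SpotTable")) spotExpr(spots) else as.matrix(spots)
  genes <- rownames(m)
  sigIn <- intersect(sigGenes(sig), genes)
  if (length(sigIn) == 0)
    stop(sprintf("no gene of signature '%s' present", sigName(sig)))
  w <- ceiling(topFraction * nrow(m))
  tieBreak <- match(genes, sort(genes))
  sc <- vapply(seq_len(ncol(m)), function(s) {
    ord <- order(-m[, s], tieBreak)
    rk <- match(match(sigIn, genes), ord)
    .rankRecoveryAUC(rk, w, length(sigIn))
  }, numeric(1))
  names(sc) <- colnames(m)
  sc
}

#' Cell-type coexistence matrix
#'
#' Pearson correlation across spots between every pair of cell-type count
#' vectors. Zero-variance types yield missing entries (flagged with a
#' warning); the diagonal is 1.
#'
#' @param typeCounts spots x cell-types count matrix, or a
#'   [SpotTable-class] carrying one.
#' @return symmetric correlation matrix with entries in \[-1, 1\].
#' @export
coexistenceMatrix <- function(typeCounts) {
  tc <- if (is(typeCounts, "SpotTable")) spotTypeCounts(typeCounts)
        else as.matrix(typeCounts)
  if (nrow(tc) == 0) stop("no per-spot cell-type counts available")
  v <- apply(tc, 2, sd)
  flat <- colnames(tc)[v == 0]
  if (length(flat) > 0)
    warning(sprintf("zero-variance type(s): %s; entries set to NA",
                    paste(flat, collapse = ", ")))
  cc <- suppressWarnings(cor(tc))
  diag(cc) <- 1
  cc
}
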