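## Arm-level squared-CNV cell scores and tumor-cluster calling. Per cell,
## the arm score is the mean of squared CNV values over the arm's genes;
## the cell score is the unweighted arithmetic mean over arms. For i.i.d.
## Normal(0, sigma) values the expected cell score is sigma^2.

#' Per-cell per-arm squared-CNV scores
#'
#' `S_a(c) = mean over genes g of arm a of cnv(c, g)^2`. Genes without an
#' arm assignment are dropped with a warning; arms that end up with no
#' mapped gene are omitted with a warning.
#'
#' @param cnv a [CNVMatrix-class].
#' @return numeric matrix, cells x arms.
#' @export
armScores <- function(cnv) {
  v <- cnvValues(cnv)
  amap <- armMap(cnv)
  unmapped <- setdiff(colnames(v), names(amap))
  if (length(unmapped) > 0) {
    warning(sprintf("%d gene(s) without arm assignment dropped: %s%s",
                    length(unmapped),
                    paste(head(unmapped, 3), collapse = ", "),
                    if (length(unmapped) > 3) ", ..." else ""))
    v <- v[, setdiff(colnames(v), unmapped), drop = FALSE]
  }
  arms <- unique(unname(amap[colnames(v)]))
  empty <- setdiff(unique(unname(amap)), arms)
  if (length(empty) > 0)
    warning(sprintf("arm(s) with no mapped genes omitted: %s",
                    paste(empty, collapse = ", ")))
  sq <- v^2
  out <- vapply(arms, function(a) {
    rowMeans(sq[, amap[colnames(v)] == a, drop = FALSE])
  }, numeric(nrow(v)))
  if (is.null(dim(out)))
    out <- matrix(out, nrow = nrow(v), dimnames = list(rownames(v), arms))
  out
}

#' Per-cell overall CNV score
#'
#' Unweighted arithmetic mean of the arm scores present.
#'
#' @param armScoreMatrix cells x arms matrix from [armScores()].
#' @return named numeric vector, one score per cell.
#' @export
cellCNVScore <- function(armScoreMatrix) {
  rowMeans(armScoreMatrix)
}

#' Call tumor clusters from CNV cell scores
#'
#' A cluster is flagged as tumor when its mean cell score exceeds the
#' reference mean by more than `kSigma` reference standard deviations.
#' The reference set (normal-tissue cells) must hold at least 10 cells for
#' a usable baseline.
#'
#' @param scores named per-cell scores (from [cellCNVScore()]).
#' @param clusters cluster label per cell (same order as `scores`).
#' @param referenceCells cell ids forming the normal reference.
#' @param kSigma z-threshold on the reference distribution (default 2).
#' @return data.frame: `cluster`, `n`, `mean_score`, `tumor` flag, plus the
#'   reference mean/sd in attributes `ref_mean` and `ref_sd`.
#' @export
callTumorClusters <- function(scores, clusters, referenceCells, kSigma = 2) {
  stopifnot(length(scores) == length(clusters))
  ref <- scores[names(scores) %in% referenceCells]
  if (length(ref) < 10)
    stop(sprintf("only %d reference cells; at least 10 needed for a baseline",
                 length(ref)))
  refMean <- mean(ref)
  refSd <- sd(ref)
  cm <- tapply(scores, clusters, mean)
  cn <- tapply(scores, clusters, length)
  out <- data.frame(cluster = names(cm), n = as.integer(cn),
                    mean_score = as.numeric(cm),
                    tumor = as.numeric(cm) > refMean + kSigma * refSd,
                    stringsAsFactors = FALSE)
  attr(out, "ref_mean") <- refMean
  attr(out, "ref_sd") <- refSd
  out
}
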