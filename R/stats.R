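## Comparison layer: matched-pairs Wilcoxon signed rank (exact, tie-aware),
## the Levene-gated unpaired test, and the Kruskal-Wallis multi-group test.
## Two-sided p < 0.05 is the significance convention throughout; stars:
## * < 0.05, ** < 0.01, *** < 0.001, **** < 0.0001.

#' Significance stars
#' @param p p-value(s).
#' @return character vector: `****` < 0.0001, `***` < 0.001, `**` < 0.01,
#'   `*` < 0.05, `ns` otherwise.
#' @export
significanceStars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_character_)
    if (pp < 1e-4) "****" else if (pp < 1e-3) "***"
    else if (pp < 0.01) "**" else if (pp < 0.05) "*" else "ns"
  }, character(1))
}

## exact distribution of the signed-rank statistic V = sum of ranks of
## positive differences, tie-aware: dynamic programming over doubled
## midranks (integers). Returns P(V <= v) and P(V >= v).
.signedRankTails <- function(ranks, v) {
  w <- as.integer(round(2 * ranks))
  total <- sum(w)
  f <- numeric(total + 1)
  f[1] <- 1
  for (wi in w) {
    g <- f
    g[(wi + 1):(total + 1)] <- g[(wi + 1):(total + 1)] +
      f[1:(total + 1 - wi)]
    f <- g
  }
  f <- f / 2^length(w)
  v2 <- round(2 * v)
  lower <- sum(f[seq_len(v2 + 1)])
  upper <- sum(f[(v2 + 1):(total + 1)])
  c(lower = lower, upper = upper)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided test on paired samples (matched by patient). Zero differences
#' are dropped (classical convention); all-zero differences give p = 1 (no
#' evidence). For n <= `exactMax` pairs after zero removal the exact,
#' tie-aware sign-flip distribution is used (p = 2 min of the two tails,
#' capped at 1); above that, the normal approximation with continuity and
#' tie correction.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exactMax largest n for the exact distribution (default 25).
#' @return A [ComparisonResult-class]; `details` holds n dropped as zeros
#'   and whether the exact distribution was used.
#' @export
pairedSignedRank <- function(x, y, exactMax = 25) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  d <- x[ok] - y[ok]
  nZero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(new("ComparisonResult", design = "paired",
               method = "wilcoxon_signed_rank",
               statistic = c(V = 0), pValue = 1,
               nPerGroup = c(sum(ok), sum(ok)), gate = NA_character_,
               stars = "ns",
               details = list(n_zero_dropped = nZero, exact = TRUE)))
  }
  if (n < 3)
    stop("fewer than 3 non-zero paired differences")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  exact <- n <= exactMax
  if (exact) {
    tails <- .signedRankTails(r, V)
    p <- min(1, 2 * min(tails["lower"], tails["upper"]))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (abs(V - mu) - 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-max(z, 0)))
  }
  new("ComparisonResult", design = "paired",
      method = "wilcoxon_signed_rank", statistic = c(V = V),
      pValue = unname(p), nPerGroup = c(sum(ok), sum(ok)),
      gate = NA_character_, stars = significanceStars(p),
      details = list(n_zero_dropped = nZero, n_used = n, exact = exact))
}

#' Levene-gated unpaired two-group comparison
#'
#' Reproduces the gate as stated for the imaging comparisons: Levene's test
#' is applied first; when its p-value is below 0.05 the groups are treated
#' as non-parametric and compared with a Mann-Whitney U (Wilcoxon rank-sum)
#' test, otherwise with a Student's t-test. Both branch results are always
#' retained in `details`. (The gate tests equality of variance, not
#' normality; it is reproduced as stated. A Shapiro-Wilk gate is available
#' with `gateTest = "shapiro"`.)
#'
#' @param x,y numeric vectors.
#' @param gateAlpha gate threshold (default 0.05).
#' @param gateTest `"levene"` (default, classical mean-centred) or
#'   `"shapiro"`.
#' @return A [ComparisonResult-class]; `details$levene_p`,
#'   `details$t_test`, `details$mann_whitney` hold the full branch results.
#' @export
gatedUnpairedCompare <- function(x, y, gateAlpha = 0.05,
                                 gateTest = c("levene", "shapiro")) {
  gateTest <- match.arg(gateTest)
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  vals <- c(x, y)
  gateP <- if (gateTest == "levene") {
    lt <- car::leveneTest(vals ~ g, center = "mean")
    lt[["Pr(>F)"]][1]
  } else {
    min(stats::shapiro.test(x)$p.value, stats::shapiro.test(y)$p.value)
  }
  tt <- tryCatch(t.test(x, y, var.equal = TRUE),
                 error = function(e) NULL)
  mw <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  nonparam <- !is.na(gateP) && gateP < gateAlpha
  if (nonparam) {
    p <- mw$p.value; stat <- c(U = unname(mw$statistic))
    method <- "mann_whitney_u"
  } else {
    if (is.null(tt)) { # degenerate constant groups
      p <- 1; stat <- c(t = 0)
    } else {
      p <- tt$p.value; stat <- c(t = unname(tt$statistic))
    }
    method <- "student_t"
  }
  new("ComparisonResult", design = "unpaired", method = method,
      statistic = stat, pValue = unname(p),
      nPerGroup = c(length(x), length(y)),
      gate = if (nonparam) "nonparametric" else "parametric",
      stars = significanceStars(p),
      details = list(gate_test = gateTest, gate_p = gateP,
                     t_test = tt, mann_whitney = mw))
}

#' Kruskal-Wallis multi-group comparison
#'
#' Kruskal-Wallis H with tie correction and the chi-squared approximation.
#'
#' @param groups list of numeric vectors (>= 2 groups).
#' @return A [ComparisonResult-class].
#' @export
multigroupCompare <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (length(unique(unlist(groups))) == 1) {
    ## fully tied data: no rank variation, H is 0 by definition
    return(new("ComparisonResult", design = "multigroup",
               method = "kruskal_wallis", statistic = c(H = 0), pValue = 1,
               nPerGroup = vapply(groups, length, integer(1)),
               gate = NA_character_, stars = "ns",
               details = list(df = length(groups) - 1)))
  }
  kw <- kruskal.test(groups)
  new("ComparisonResult", design = "multigroup",
      method = "kruskal_wallis",
      statistic = c(H = unname(kw$statistic)),
      pValue = unname(kw$p.value),
      nPerGroup = vapply(groups, length, integer(1)),
      gate = NA_character_, stars = significanceStars(kw$p.value),
      details = list(df = unname(kw$parameter)))
}
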