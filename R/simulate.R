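## Synthetic-data generators. Every generator is reproducible bit-for-bit
## from the config seed and returns, next to the data object, a `truth`
## record sufficient to score any downstream detector (precision/recall).

## evaluate `code` under `seed`, restoring the caller's RNG state afterwards
.withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Build a synthetic-data configuration
#'
#' Defaults describe one imaging ROI of 1 mm^2 with cell densities in the
#' range of dense lung-nodule tissue, seven planted BET triads with five
#' single-contact distractor endothelial cells, two tertiary lymphoid
#' structures, paired AT2/club expression programs of effect size
#' `programDelta` on the log scale, negative-binomial counts, and one
#' shifted chromosome arm against a low-noise background.
#'
#' @param seed integer; fixes all generator output.
#' @param roiSizeUm ROI width and height in micrometres.
#' @param densities named numeric, background cells/mm^2 per phenotype.
#' @param nTriadsPlanted,nDistractors planted triad ECs and single-contact
#'   distractor ECs per ROI.
#' @param triadAxisMedianUm,triadAxisSdlog lognormal EC major-axis
#'   distribution (median in micrometres, sdlog).
#' @param tlsN,tlsRadiusUm,tlsCellDensity number of TLS disks, their radius
#'   (micrometres) and within-TLS cell density (cells/mm^2).
#' @param tlsBCoreFrac fraction of TLS cells that are B cells, placed in the
#'   inner core (radius 0.6 R); the remainder are T cells in the outer ring.
#' @param tlsTMix named numeric, mix of T phenotypes in the TLS ring.
#' @param programDelta log-scale mean shift of the planted AT2/club
#'   expression programs.
#' @param programFrac fraction of cells carrying the AT2 program (the rest
#'   carry the club program).
#' @param nProgramGenes genes per planted program.
#' @param programBaseExpr baseline expression of program genes, in
#'   counts-per-10k units.
#' @param nbDispersion negative-binomial size (inverse overdispersion).
#' @param libSizeMeanlog,libSizeSdlog lognormal library-size distribution.
#' @param doubletRate fraction of cells co-expressing a second lineage's
#'   markers.
#' @param mitoMean,mitoConc Beta-distributed per-cell mitochondrial fraction
#'   with mean `mitoMean` and concentration `mitoConc`.
#' @param cnvArmShifts named numeric, additive CNV shift per affected arm in
#'   tumor cells.
#' @param cnvNoiseSd Gaussian CNV noise s.d. around neutral.
#' @param cnvTumorFrac fraction of CNV-simulated cells that are tumor.
#' @param cnvGenesPerArm genes simulated per chromosome arm.
#' @param svAmplitude,svNoiseSd planted spatially-variable-gene gradient
#'   amplitude and flat-gene noise s.d. (normalized-expression units).
#' @param coexistStrength latent-field scale controlling the planted
#'   positive correlation between the first two cell types on the spot grid.
#' @return A [SimConfig-class].
#' @export
simConfig <- function(seed = 1L,
                      roiSizeUm = c(1000, 1000),
                      densities = c(Tumor = 400, EC = 50, B = 80,
                                    CD4T = 120, CD8T = 100,
                                    CD4T_act = 30, CD8T_act = 30,
                                    CD4T_exh = 30, CD8T_exh = 30,
                                    Treg = 25, M1 = 50, M2 = 60, DC = 25,
                                    other = 150),
                      nTriadsPlanted = 7L, nDistractors = 5L,
                      triadAxisMedianUm = 10, triadAxisSdlog = 0.25,
                      tlsN = 2L, tlsRadiusUm = 120, tlsCellDensity = 3000,
                      tlsBCoreFrac = 0.6,
                      tlsTMix = c(CD4T = 0.2, CD8T = 0.2,
                                  CD4T_act = 0.175, CD8T_act = 0.175,
                                  CD4T_exh = 0.125, CD8T_exh = 0.125),
                      programDelta = 1, programFrac = 0.5,
                      nProgramGenes = 10L, programBaseExpr = 20,
                      nbDispersion = 10,
                      libSizeMeanlog = log(5000), libSizeSdlog = 0.3,
                      doubletRate = 0,
                      mitoMean = 0.05, mitoConc = 40,
                      cnvArmShifts = c(`1q` = 0.3, `7p` = 0.2),
                      cnvNoiseSd = 0.05, cnvTumorFrac = 0.5,
                      cnvGenesPerArm = 25L,
                      svAmplitude = 2, svNoiseSd = 0.2,
                      coexistStrength = 2) {
  p <- list(seed = seed, roiSizeUm = roiSizeUm, densities = densities,
            nTriadsPlanted = as.integer(nTriadsPlanted),
            nDistractors = as.integer(nDistractors),
            triadAxisMedianUm = triadAxisMedianUm,
            triadAxisSdlog = triadAxisSdlog,
            tlsN = as.integer(tlsN), tlsRadiusUm = tlsRadiusUm,
            tlsCellDensity = tlsCellDensity, tlsBCoreFrac = tlsBCoreFrac,
            tlsTMix = tlsTMix, programDelta = programDelta,
            programFrac = programFrac,
            nProgramGenes = as.integer(nProgramGenes),
            programBaseExpr = programBaseExpr,
            nbDispersion = nbDispersion,
            libSizeMeanlog = libSizeMeanlog, libSizeSdlog = libSizeSdlog,
            doubletRate = doubletRate, mitoMean = mitoMean,
            mitoConc = mitoConc, cnvArmShifts = cnvArmShifts,
            cnvNoiseSd = cnvNoiseSd, cnvTumorFrac = cnvTumorFrac,
            cnvGenesPerArm = as.integer(cnvGenesPerArm),
            svAmplitude = svAmplitude, svNoiseSd = svNoiseSd,
            coexistStrength = coexistStrength)
  new("SimConfig", params = p)
}

.BCLASS <- "B"
.TCLASSES <- c("CD4T", "CD8T", "CD4T_act", "CD8T_act", "CD4T_exh",
               "CD8T_exh", "Treg")

## uniform point in the ROI rectangle
.unifPoint <- function(w, h) c(runif(1, 0, w), runif(1, 0, h))

.distToAll <- function(pt, xs, ys) sqrt((xs - pt[1])^2 + (ys - pt[2])^2)

#' Simulate one imaging ROI with planted BET triads and TLS disks
#'
#' Background cells follow a homogeneous Poisson process per phenotype, with
#' one deliberate departure that makes the planted truth exact: every
#' lymphocyte (B or T) is kept at more than 2x the major-axis length away
#' from every endothelial cell unless it was planted as a contact, so the
#' set of triad ECs is exactly the planted set. Planted triad ECs receive
#' one B and one T contact at radius in (0, 2a]; distractor ECs receive one
#' contact lymphocyte plus one near-miss of the other class at radius in
#' (2a, 4a]. TLS disks hold a B-cell core (inner 0.6 R) surrounded by a
#' T-cell ring.
#'
#' @param config a [SimConfig-class].
#' @param roiId,compartment,patientId identifiers stamped on every cell.
#' @param seed optional seed override (defaults to the config seed).
#' @return list with elements `cells` (a [CellTable-class]) and `truth`
#'   (list: `triad_ec_ids`, `distractor_ec_ids`, `planted_contacts`
#'   data.frame, `tls` data.frame with centre/radius, per-TLS phenotype
#'   counts in `tls_counts`, `area_mm2`).
#' @export
simulateROI <- function(config, roiId = "ROI1", compartment = "NS",
                        patientId = "P1", seed = NULL) {
  stopifnot(is(config, "SimConfig"))
  p <- simParams(config)
  if (!compartment %in% .COMPARTMENTS)
    stop("compartment must be one of NL/NS/S")
  .withSeed(if (is.null(seed)) p$seed else seed, {
    w <- p$roiSizeUm[1]; h <- p$roiSizeUm[2]
    areaMm2 <- w * h / 1e6
    nSpecial <- p$nTriadsPlanted + p$nDistractors

    ## TLS centres, pairwise separation >= 2R, kept off the border
    tlsC <- matrix(numeric(0), ncol = 2)
    R <- p$tlsRadiusUm
    if (p$tlsN > 0) {
      if (2 * R > min(w, h))
        stop("capacity error: TLS radius exceeds ROI size")
      tries <- 0
      while (nrow(tlsC) < p$tlsN) {
        cand <- c(runif(1, R, w - R), runif(1, R, h - R))
        ok <- nrow(tlsC) == 0 ||
          all(.distToAll(cand, tlsC[, 1], tlsC[, 2]) >= 2 * R)
        if (ok) tlsC <- rbind(tlsC, cand)
        tries <- tries + 1
        if (tries > 5000)
          stop("capacity error: cannot place requested TLS disks in ROI")
      }
    }

    ## special (planted triad + distractor) ECs
    axes <- rlnorm(nSpecial, log(p$triadAxisMedianUm), p$triadAxisSdlog)
    amax <- if (nSpecial > 0) max(axes) else p$triadAxisMedianUm
    ecX <- ecY <- numeric(0)
    tries <- 0
    while (length(ecX) < nSpecial) {
      i <- length(ecX) + 1
      m <- 4 * axes[i]
      if (2 * m >= min(w, h))
        stop("capacity error: EC axis too large for ROI")
      cand <- c(runif(1, m, w - m), runif(1, m, h - m))
      okTLS <- nrow(tlsC) == 0 ||
        all(.distToAll(cand, tlsC[, 1], tlsC[, 2]) > R + 4 * amax)
      okSep <- length(ecX) == 0 ||
        all(.distToAll(cand, ecX, ecY) > 8 * amax)
      if (okTLS && okSep) { ecX <- c(ecX, cand[1]); ecY <- c(ecY, cand[2]) }
      tries <- tries + 1
      if (tries > 20000)
        stop("capacity error: cannot place planted ECs with required separation")
    }

    rows <- list()
    cellN <- 0
    newId <- function() { cellN <<- cellN + 1; sprintf("c%05d", cellN) }
    addCell <- function(x, y, phen, axis = NA_real_, tls = NA_character_) {
      id <- newId()
      rows[[length(rows) + 1]] <<- data.frame(
        roi_id = roiId, cell_id = id, x_um = x, y_um = y, phenotype = phen,
        major_axis_um = axis, compartment = compartment, tls_id = tls,
        patient_id = patientId, stringsAsFactors = FALSE)
      id
    }

    specialIds <- character(nSpecial)
    for (i in seq_len(nSpecial))
      specialIds[i] <- addCell(ecX[i], ecY[i], "EC", axis = axes[i])
    triadIds <- specialIds[seq_len(p$nTriadsPlanted)]
    distractorIds <- if (p$nDistractors > 0)
      specialIds[p$nTriadsPlanted + seq_len(p$nDistractors)] else character(0)

    plantAt <- function(cx, cy, rmin, rmax) {
      ang <- runif(1, 0, 2 * pi)
      r <- runif(1, rmin, rmax)
      c(cx + r * cos(ang), cy + r * sin(ang))
    }

    planted <- list()
    for (i in seq_len(p$nTriadsPlanted)) {
      a <- axes[i]
      for (cls in c(.BCLASS, sample(c("CD4T", "CD8T"), 1))) {
        pt <- plantAt(ecX[i], ecY[i], 1e-6, 2 * a)
        id <- addCell(pt[1], pt[2], cls)
        planted[[length(planted) + 1]] <- data.frame(
          ec_id = specialIds[i], cell_id = id, class = cls,
          contact = TRUE, stringsAsFactors = FALSE)
      }
    }
    for (j in seq_len(p$nDistractors)) {
      i <- p$nTriadsPlanted + j
      a <- axes[i]
      contactCls <- if (j %% 2 == 1) .BCLASS else sample(c("CD4T", "CD8T"), 1)
      missCls <- if (contactCls == .BCLASS)
        sample(c("CD4T", "CD8T"), 1) else .BCLASS
      pt <- plantAt(ecX[i], ecY[i], 1e-6, 2 * a)
      id <- addCell(pt[1], pt[2], contactCls)
      planted[[length(planted) + 1]] <- data.frame(
        ec_id = specialIds[i], cell_id = id, class = contactCls,
        contact = TRUE, stringsAsFactors = FALSE)
      u <- runif(1, 1e-6, 1)
      ang <- runif(1, 0, 2 * pi)
      r <- 2 * a + 2 * a * u
      id <- addCell(ecX[i] + r * cos(ang), ecY[i] + r * sin(ang), missCls)
      planted[[length(planted) + 1]] <- data.frame(
        ec_id = specialIds[i], cell_id = id, class = missCls,
        contact = FALSE, stringsAsFactors = FALSE)
    }

    ## background cells; background ECs stay clear of special ECs and TLS
    bgEC <- data.frame(x = numeric(0), y = numeric(0), axis = numeric(0))
    isLymph <- function(ph) ph %in% c(.BCLASS, .TCLASSES)
    nBg <- rpois(length(p$densities), p$densities * areaMm2)
    names(nBg) <- names(p$densities)
    if (nBg["EC"] > 0) {
      k <- 0; tries <- 0
      while (k < nBg[["EC"]]) {
        ax <- rlnorm(1, log(p$triadAxisMedianUm), p$triadAxisSdlog)
        cand <- .unifPoint(w, h)
        okSpec <- nSpecial == 0 ||
          all(.distToAll(cand, ecX, ecY) > 6 * amax + 2 * ax)
        okTLS <- nrow(tlsC) == 0 ||
          all(.distToAll(cand, tlsC[, 1], tlsC[, 2]) > R + 4 * ax)
        if (okSpec && okTLS) {
          bgEC <- rbind(bgEC, data.frame(x = cand[1], y = cand[2], axis = ax))
          k <- k + 1
        }
        tries <- tries + 1
        if (tries > 200 * nBg[["EC"]] + 1000)
          stop("capacity error: cannot place background ECs")
      }
      for (k in seq_len(nrow(bgEC)))
        addCell(bgEC$x[k], bgEC$y[k], "EC", axis = bgEC$axis[k])
    }
    allEcX <- c(ecX, bgEC$x); allEcY <- c(ecY, bgEC$y)
    allEcAx <- c(axes, bgEC$axis)
    clearOfECs <- function(pt) {
      length(allEcX) == 0 ||
        all(.distToAll(pt, allEcX, allEcY) > 2 * allEcAx)
    }
    for (ph in setdiff(names(p$densities), "EC")) {
      n <- nBg[[ph]]
      if (n == 0) next
      for (k in seq_len(n)) {
        pt <- .unifPoint(w, h)
        if (isLymph(ph)) {
          tries <- 0
          while (!clearOfECs(pt)) {
            pt <- .unifPoint(w, h)
            tries <- tries + 1
            if (tries > 500)
              stop("capacity error: cannot place background lymphocytes clear of ECs")
          }
        }
        addCell(pt[1], pt[2], ph)
      }
    }

    ## TLS disks: B core, T ring
    tlsDf <- data.frame(tls_id = character(0), cx = numeric(0),
                        cy = numeric(0), radius_um = numeric(0))
    tlsCounts <- list()
    if (p$tlsN > 0) {
      tmix <- p$tlsTMix / sum(p$tlsTMix)
      for (k in seq_len(p$tlsN)) {
        tid <- sprintf("%s_TLS%d", roiId, k)
        nTls <- rpois(1, p$tlsCellDensity * pi * R^2 / 1e6)
        cnt <- setNames(numeric(length(tmix) + 1), c(.BCLASS, names(tmix)))
        for (cc in seq_len(nTls)) {
          isB <- runif(1) < p$tlsBCoreFrac
          if (isB) {
            r <- 0.6 * R * sqrt(runif(1)); cls <- .BCLASS
          } else {
            r <- R * sqrt(runif(1, 0.36, 1))
            cls <- sample(names(tmix), 1, prob = tmix)
          }
          ang <- runif(1, 0, 2 * pi)
          pt <- c(tlsC[k, 1] + r * cos(ang), tlsC[k, 2] + r * sin(ang))
          addCell(pt[1], pt[2], cls, tls = tid)
          cnt[cls] <- cnt[cls] + 1
        }
        tlsDf <- rbind(tlsDf, data.frame(tls_id = tid, cx = tlsC[k, 1],
                                         cy = tlsC[k, 2], radius_um = R))
        tlsCounts[[tid]] <- cnt
      }
    }

    cells <- CellTable(do.call(rbind, rows))
    list(cells = cells,
         truth = list(triad_ec_ids = triadIds,
                      distractor_ec_ids = distractorIds,
                      planted_contacts = if (length(planted) > 0)
                        do.call(rbind, planted) else NULL,
                      tls = tlsDf, tls_counts = tlsCounts,
                      area_mm2 = areaMm2))
  })
}

#' Simulate a single-cell expression matrix with planted programs
#'
#' Counts are negative binomial (Gamma-Poisson) with lognormal library
#' sizes. Cells are split into an AT2-program and a club-program group; the
#' respective signature genes get a multiplicative `exp(programDelta)` shift
#' of their expected expression. All cells express the epithelial lineage
#' markers and PTPRC; planted doublets additionally express one other
#' lineage's markers. Mitochondrial genes (`MT-1` ...) carry a
#' Beta-distributed per-cell fraction of the library.
#'
#' @param config a [SimConfig-class].
#' @param nCells,nGenes matrix dimensions (nGenes is the total including
#'   program, marker and mitochondrial genes).
#' @param patientIds optional character vector; cells are split evenly
#'   across patients (default single patient `"P1"`).
#' @param seed optional seed override.
#' @return list with `sce` (SingleCellExperiment, assay `counts`), `truth`
#'   (data.frame: cell_id, group, doublet, doublet_lineage, mito_fraction)
#'   and `signatures` (list of AT2/club [GeneSignature-class]).
#' @export
simulateExpression <- function(config, nCells = 1000, nGenes = 5000,
                               patientIds = "P1", seed = NULL) {
  stopifnot(is(config, "SimConfig"))
  p <- simParams(config)
  .withSeed(if (is.null(seed)) p$seed else seed, {
    nProg <- p$nProgramGenes
    at2Genes <- sprintf("AT2G%02d", seq_len(nProg))
    clubGenes <- sprintf("CLUBG%02d", seq_len(nProg))
    markerSets <- list(epithelial = c("SFTPC", "SCGB3A1"),
                       T = "CD3D",
                       B = c("CD79A", "JCHAIN", "MZB1"),
                       myeloid = c("MARCO", "CD163"))
    markers <- unlist(markerSets, use.names = FALSE)
    mitoGenes <- sprintf("MT-%d", 1:10)
    nFiller <- nGenes - length(at2Genes) - length(clubGenes) -
      length(markers) - 1 - length(mitoGenes)
    if (nFiller < 10) stop("nGenes too small for the planted structure")
    filler <- sprintf("G%05d", seq_len(nFiller))
    genes <- c(at2Genes, clubGenes, markers, "PTPRC", mitoGenes, filler)

    ## baseline relative expression (non-mito mass sums to 1)
    base <- setNames(numeric(length(genes)), genes)
    base[filler] <- rlnorm(nFiller, meanlog = 0, sdlog = 1)
    base[c(at2Genes, clubGenes)] <- p$programBaseExpr / 1e4
    base[markerSets$epithelial] <- 2e-4
    base["PTPRC"] <- 1e-4
    base[c(markerSets$T, markerSets$B, markerSets$myeloid)] <- 2e-4
    base[filler] <- base[filler] / sum(base[filler]) *
      (1 - sum(base[setdiff(genes, c(filler, mitoGenes))]))

    grp <- ifelse(runif(nCells) < p$programFrac, "AT2", "club")
    doublet <- runif(nCells) < p$doubletRate
    otherLin <- sample(c("T", "B", "myeloid"), nCells, replace = TRUE)
    mitoFrac <- rbeta(nCells, p$mitoMean * p$mitoConc,
                      (1 - p$mitoMean) * p$mitoConc)
    lib <- rlnorm(nCells, p$libSizeMeanlog, p$libSizeSdlog)

    pc <- matrix(base, nrow = length(genes), ncol = nCells,
                 dimnames = list(genes, sprintf("cell%05d", seq_len(nCells))))
    isAT2 <- grp == "AT2"
    pc[at2Genes, isAT2] <- pc[at2Genes, isAT2] * exp(p$programDelta)
    pc[clubGenes, !isAT2] <- pc[clubGenes, !isAT2] * exp(p$programDelta)
    for (lin in c("T", "B", "myeloid")) {
      off <- !doublet | otherLin != lin
      pc[markerSets[[lin]], off] <- 0
    }
    pc[mitoGenes, ] <- 0
    pc <- sweep(pc, 2, colSums(pc) / (1 - mitoFrac), "/")
    pc[mitoGenes, ] <- rep(mitoFrac / length(mitoGenes),
                           each = length(mitoGenes))
    mu <- sweep(pc, 2, lib, "*")
    counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                             size = p$nbDispersion),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    counts <- as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")

    cellIds <- colnames(counts)
    pat <- rep(patientIds, each = ceiling(nCells / length(patientIds)))[seq_len(nCells)]
    cd <- DataFrame(cell_id = cellIds, patient_id = pat,
                    compartment = rep("S", nCells),
                    cluster = grp, row.names = cellIds)
    rd <- DataFrame(gene_id = genes, mito = genes %in% mitoGenes,
                    row.names = genes)
    sce <- SingleCellExperiment(assays = list(counts = counts),
                                rowData = rd, colData = cd)
    truth <- data.frame(cell_id = cellIds, group = grp, doublet = doublet,
                        doublet_lineage = ifelse(doublet, otherLin, NA),
                        mito_fraction = mitoFrac, stringsAsFactors = FALSE)
    list(sce = sce, truth = truth,
         signatures = list(
           AT2 = GeneSignature("AT2", at2Genes, role = "AT2"),
           club = GeneSignature("club", clubGenes, role = "club")))
  })
}

#' Simulate a per-cell CNV value matrix with arm-level shifts
#'
#' Reference cells draw all values from Normal(0, `cnvNoiseSd`); tumor cells
#' additionally receive the additive shift of `cnvArmShifts` on every gene
#' of the affected arm(s).
#'
#' @param config a [SimConfig-class].
#' @param nCells number of cells.
#' @param arms character vector of arm labels to simulate; defaults to the
#'   shifted arms plus neutral arms `10p`, `10q`, filled to at least 4 arms.
#' @param seed optional seed override.
#' @return list with `cnv` (a [CNVMatrix-class]) and `truth` (data.frame:
#'   cell_id, tumor flag).
#' @export
simulateCNV <- function(config, nCells = 200, arms = NULL, seed = NULL) {
  stopifnot(is(config, "SimConfig"))
  p <- simParams(config)
  .withSeed(if (is.null(seed)) p$seed else seed, {
    if (is.null(arms))
      arms <- unique(c(names(p$cnvArmShifts), "10p", "10q", "3p", "3q"))
    gpa <- p$cnvGenesPerArm
    genes <- unlist(lapply(arms, function(a) sprintf("%s_g%02d", a, 1:gpa)))
    amap <- setNames(rep(arms, each = gpa), genes)
    tumor <- seq_len(nCells) <= round(p$cnvTumorFrac * nCells)
    tumor <- sample(tumor)
    vals <- matrix(rnorm(nCells * length(genes), 0, p$cnvNoiseSd),
                   nrow = nCells,
                   dimnames = list(sprintf("cell%04d", seq_len(nCells)), genes))
    for (a in names(p$cnvArmShifts)) {
      if (!a %in% arms) next
      vals[tumor, amap == a] <- vals[tumor, amap == a] + p$cnvArmShifts[[a]]
    }
    list(cnv = CNVMatrix(vals, amap),
         truth = data.frame(cell_id = rownames(vals), tumor = tumor,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a spatial-transcriptomics spot grid
#'
#' Most genes are spatially flat (baseline plus Gaussian noise, truncated at
#' zero); `nSVGenes` planted spatially-variable genes follow a smooth linear
#' gradient of amplitude `svAmplitude` in a random direction. Per-spot
#' cell-type counts are Poisson, with the first two types sharing a latent
#' Gamma field so they coexist (positive Pearson correlation).
#'
#' @param config a [SimConfig-class].
#' @param gridDim spots grid (columns, rows).
#' @param nGenes total genes.
#' @param nSVGenes planted spatially-variable genes.
#' @param nTypes number of deconvolved cell types.
#' @param seed optional seed override.
#' @return list with `spots` (a [SpotTable-class]) and `truth` (list:
#'   `sv_genes`, `coexist_pair`).
#' @export
simulateSpots <- function(config, gridDim = c(15, 15), nGenes = 60,
                          nSVGenes = 5, nTypes = 5, seed = NULL) {
  stopifnot(is(config, "SimConfig"))
  p <- simParams(config)
  .withSeed(if (is.null(seed)) p$seed else seed, {
    gx <- gridDim[1]; gy <- gridDim[2]
    coords <- expand.grid(x = seq_len(gx), y = seq_len(gy))
    coords <- data.frame(spot_id = sprintf("spot%04d", seq_len(nrow(coords))),
                         coords)
    nSpots <- nrow(coords)
    genes <- sprintf("SG%04d", seq_len(nGenes))
    svGenes <- if (nSVGenes > 0) genes[seq_len(nSVGenes)] else character(0)
    expr <- matrix(0, nrow = nGenes, ncol = nSpots,
                   dimnames = list(genes, coords$spot_id))
    baseLevel <- runif(nGenes, 0.5, 2)
    for (g in seq_len(nGenes)) {
      v <- baseLevel[g] + rnorm(nSpots, 0, p$svNoiseSd)
      if (genes[g] %in% svGenes) {
        th <- runif(1, 0, 2 * pi)
        proj <- coords$x * cos(th) + coords$y * sin(th)
        proj <- (proj - min(proj)) / max(1e-9, diff(range(proj)))
        v <- v + p$svAmplitude * proj
      }
      expr[g, ] <- pmax(v, 0)
    }
    types <- sprintf("type%d", seq_len(nTypes))
    tc <- matrix(rpois(nSpots * nTypes, 5), nrow = nSpots,
                 dimnames = list(coords$spot_id, types))
    lam <- rgamma(nSpots, shape = 2, rate = 2)
    tc[, 1] <- rpois(nSpots, 5 * lam * p$coexistStrength / 2)
    tc[, 2] <- rpois(nSpots, 5 * lam * p$coexistStrength / 2)
    list(spots = SpotTable(expr, coords, tc),
         truth = list(sv_genes = svGenes,
                      coexist_pair = types[1:2]))
  })
}
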