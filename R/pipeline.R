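## End-to-end orchestration on synthetic data: simulate -> qc -> score ->
## cnv -> density/TLS -> triads -> spots -> compare, with TSV outputs and a
## deterministic JSON summary.

#' Build a pipeline configuration
#'
#' The defaults emulate the study design at desk scale: each patient
#' contributes one non-solid (NS) and one solid (S) ROI; non-solid ROIs
#' carry more planted triads and an activation-skewed TLS T-cell mix,
#' solid ROIs fewer triads and an exhaustion-skewed mix, so the paired
#' comparisons run in the direction the biology dictates.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param outDir output directory for TSVs, summary JSON and log.
#' @param nPatients patients with matched NS/S ROIs (>= 3 so paired tests
#'   are defined).
#' @param nsTriads,sTriads planted triads per NS / S ROI.
#' @param nCells,nGenes expression-matrix dimensions.
#' @param programDelta planted program effect size.
#' @param doubletRate planted doublet fraction.
#' @param nTopSpatial top spatial genes kept per sample.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(seed = 1L, outDir = tempfile("noduleTME_run_"),
                           nPatients = 4L, nsTriads = 7L, sTriads = 3L,
                           nCells = 600L, nGenes = 1500L,
                           programDelta = 2, doubletRate = 0.05,
                           nTopSpatial = 10L) {
  if (nPatients < 3)
    stop("nPatients must be >= 3 so paired comparisons are defined")
  structure(list(seed = as.integer(seed), outDir = outDir,
                 nPatients = as.integer(nPatients),
                 nsTriads = as.integer(nsTriads),
                 sTriads = as.integer(sTriads),
                 nCells = as.integer(nCells), nGenes = as.integer(nGenes),
                 programDelta = programDelta, doubletRate = doubletRate,
                 nTopSpatial = as.integer(nTopSpatial)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match the [pipelineConfig()] arguments.
#' @return list of class `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  args <- yaml::read_yaml(path)
  do.call(pipelineConfig, args)
}

.logLine <- function(con, stage, msg) {
  writeLines(sprintf("[%s] %s: %s",
                     format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, msg),
             con)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Deterministic given the configuration: reruns write a byte-identical
#' summary JSON. Outputs per-module TSVs, `summary.json` and
#' `pipeline.log` under `config$outDir`.
#'
#' @param config a [pipelineConfig()] list.
#' @return the summary list, invisibly; side effect: files in
#'   `config$outDir`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  log <- file(file.path(config$outDir, "pipeline.log"), "w")
  on.exit(close(log))
  summary <- list(seed = config$seed, n_patients = config$nPatients)
  stage <- "init"
  result <- tryCatch({
    ## ---- imaging: ROIs, triads, densities, TLS ----
    stage <- "simulate_roi"
    nsMix <- c(CD4T = 0.15, CD8T = 0.15, CD4T_act = 0.22, CD8T_act = 0.22,
               CD4T_exh = 0.13, CD8T_exh = 0.13)
    sMix <- c(CD4T = 0.15, CD8T = 0.15, CD4T_act = 0.13, CD8T_act = 0.13,
              CD4T_exh = 0.22, CD8T_exh = 0.22)
    rois <- list()
    k <- 0
    for (i in seq_len(config$nPatients)) {
      for (comp in c("NS", "S")) {
        k <- k + 1
        cfg <- simConfig(
          seed = config$seed,
          nTriadsPlanted = if (comp == "NS") config$nsTriads
                           else config$sTriads,
          tlsTMix = if (comp == "NS") nsMix else sMix)
        roiId <- sprintf("P%02d_%s", i, comp)
        rois[[roiId]] <- simulateROI(cfg, roiId = roiId, compartment = comp,
                                     patientId = sprintf("P%02d", i),
                                     seed = config$seed * 1000 + k)
      }
    }
    allCells <- CellTable(do.call(rbind, lapply(rois, function(r)
      cellData(r$cells))))
    .logLine(log, stage, sprintf("%d ROIs, %d cells", length(rois),
                                 nCells(allCells)))

    stage <- "triads"
    contacts <- classifyContacts(allCells)
    triads <- detectTriads(contacts, roiIds = names(rois))
    rates <- triadRate(triads, setNames(
      vapply(rois, function(r) r$truth$area_mm2, numeric(1)), names(rois)))
    write.table(rates, file.path(config$outDir, "triads.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    plantedAll <- unlist(lapply(rois, function(r) r$truth$triad_ec_ids))
    found <- triadEC(triads)$ec_id
    summary$triads <- list(
      n_detected = sum(triadROI(triads)$n_triads),
      n_planted = length(plantedAll),
      precision = if (length(found) > 0)
        mean(found %in% plantedAll) else NA,
      recall = mean(plantedAll %in% found))
    .logLine(log, stage, sprintf("recall %.3f", summary$triads$recall))

    stage <- "densities"
    dens <- densityAround(allCells, anchors = "Tumor",
                          targets = c("CD4T_exh", "CD8T_exh", "Treg", "M2"))
    write.table(dens$perROI, file.path(config$outDir, "density.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    summary$density <- list(
      mean_suppressive_density_mm2 = mean(dens$perROI$mean_density_mm2))

    stage <- "tls"
    ratios <- list()
    for (roiId in names(rois)) {
      sub <- allCells[cellData(allCells)$roi_id == roiId]
      td <- tlsDensity(sub, phenotypes = c("CD4T_act", "CD4T_exh",
                                           "CD8T_act", "CD8T_exh", "B"))
      rr <- activationExhaustionRatio(td)
      rr$roi_id <- roiId
      rr$compartment <- cellData(sub)$compartment[1]
      rr$patient_id <- cellData(sub)$patient_id[1]
      ratios[[roiId]] <- rr
    }
    ratios <- do.call(rbind, c(ratios, make.row.names = FALSE))
    write.table(ratios, file.path(config$outDir, "tls_ratios.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)

    stage <- "compare"
    agg <- aggregate(ratio ~ patient_id + compartment + lineage,
                     data = ratios[!ratios$undefined, ], FUN = mean)
    cmp <- list()
    for (lin in c("CD4", "CD8")) {
      a <- agg[agg$lineage == lin, ]
      wide <- merge(a[a$compartment == "NS", c("patient_id", "ratio")],
                    a[a$compartment == "S", c("patient_id", "ratio")],
                    by = "patient_id", suffixes = c("_NS", "_S"))
      cmp[[lin]] <- pairedSignedRank(wide$ratio_NS, wide$ratio_S)
    }
    nsRate <- rates$triads_per_mm2[grepl("_NS$", rates$roi_id)]
    sRate <- rates$triads_per_mm2[grepl("_S$", rates$roi_id)]
    triadCmp <- pairedSignedRank(nsRate, sRate)
    summary$comparisons <- list(
      cd4_act_exh_ratio_NS_vs_S_p = pValue(cmp$CD4),
      cd8_act_exh_ratio_NS_vs_S_p = pValue(cmp$CD8),
      triad_rate_NS_vs_S_p = pValue(triadCmp),
      mean_ratio_NS_CD8 = mean(agg$ratio[agg$lineage == "CD8" &
                                           agg$compartment == "NS"]),
      mean_ratio_S_CD8 = mean(agg$ratio[agg$lineage == "CD8" &
                                          agg$compartment == "S"]))

    ## ---- expression: qc, doublets, scores, origin ----
    stage <- "expression"
    ecfg <- simConfig(seed = config$seed,
                      programDelta = config$programDelta,
                      doubletRate = config$doubletRate)
    ex <- simulateExpression(ecfg, nCells = config$nCells,
                             nGenes = config$nGenes,
                             patientIds = sprintf("P%02d",
                                                  seq_len(config$nPatients)),
                             seed = config$seed * 1000 + 101)
    qc <- qcFilter(ex$sce)
    doublets <- flagMarkerDoublets(ex$sce)
    truthD <- ex$truth$cell_id[ex$truth$doublet]
    summary$qc <- list(
      n_input = ncol(ex$sce), n_kept = as.integer(qc$summary[["kept"]]),
      removed = as.list(qc$summary[names(qc$summary) != "kept"]),
      n_doublets_flagged = length(doublets),
      doublet_recall = if (length(truthD) > 0)
        mean(truthD %in% doublets) else NA)

    stage <- "scoring"
    calls <- classifyTumorCells(qc$sce, ex$signatures$AT2,
                                ex$signatures$club)
    calls$patient_id <- colData(qc$sce)$patient_id
    truthG <- setNames(ex$truth$group, ex$truth$cell_id)
    agree <- mean((calls$label == "AT2-like") ==
                    (truthG[calls$cell_id] == "AT2"))
    origin <- assignPatientOrigin(calls)
    write.table(calls, file.path(config$outDir, "cell_scores.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(origin, file.path(config$outDir, "patient_origin.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    summary$origin <- list(label_recovery = agree,
                           calls = as.list(table(origin$label)))

    ## ---- cnv ----
    stage <- "cnv"
    ccfg <- simConfig(seed = config$seed)
    cv <- simulateCNV(ccfg, nCells = 300,
                      seed = config$seed * 1000 + 202)
    sc <- cellCNVScore(armScores(cv$cnv))
    clusters <- ifelse(cv$truth$tumor, "tumor_cluster", "reference")
    flags <- callTumorClusters(sc, clusters,
                               cv$truth$cell_id[!cv$truth$tumor])
    write.table(flags, file.path(config$outDir, "cnv_clusters.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    summary$cnv <- list(
      tumor_cluster_flagged =
        flags$tumor[flags$cluster == "tumor_cluster"],
      reference_flagged = flags$tumor[flags$cluster == "reference"],
      mean_tumor_score = mean(sc[cv$truth$tumor]),
      mean_reference_score = mean(sc[!cv$truth$tumor]))

    ## ---- spots ----
    stage <- "spots"
    scfg <- simConfig(seed = config$seed)
    sp <- simulateSpots(scfg, seed = config$seed * 1000 + 303)
    ss <- spatialSignificance(sp$spots)
    top <- selectCandidateGenes(list(ss), nTop = config$nTopSpatial)
    svSig <- GeneSignature("planted_sv", sp$truth$sv_genes, role = "sv")
    rec <- rankRecoveryScore(sp$spots, svSig)
    cx <- coexistenceMatrix(sp$spots)
    offdiag <- cx; diag(offdiag) <- NA
    maxPair <- which(offdiag == max(offdiag, na.rm = TRUE), arr.ind = TRUE)[1, ]
    write.table(ss, file.path(config$outDir, "spatial_scores.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    summary$spots <- list(
      sv_recovered_in_top = mean(sp$truth$sv_genes %in%
                                   top$perSample[[1]]),
      mean_rank_recovery = mean(rec),
      coexist_max_pair = sort(rownames(cx)[maxPair]),
      coexist_max_r = max(offdiag, na.rm = TRUE),
      coexist_pair_correct = setequal(rownames(cx)[maxPair],
                                      sp$truth$coexist_pair))

    summary
  }, error = function(e) {
    .logLine(log, stage, sprintf("FAILED: %s", conditionMessage(e)))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  jsonlite::write_json(result,
                       file.path(config$outDir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  .logLine(log, "done", "summary.json written")
  invisible(result)
}
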