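# End-to-end orchestration: decontamination, isoform collapsing,
# expression and differential-expression calling, duplicate-cluster
# detection, association statistics, and LGT screening.

#' Pipeline run configuration
#'
#' Bundles every stage threshold with its standard default: shared stretch
#' >= 50 nt; contaminant region > 100 bp at > 90\% identity; abundance
#' evidence at 10 and 600 TPM; low-count filter at the 75th percentile / 10
#' reads; DE at adjusted p < 0.05 (or posterior > 0.95) with FC < 0.5 or
#' > 2; homologs at > 30\% identity covering > 2/3 of the shorter sequence;
#' clades at > 50\% support from 100 bootstrap replicates; randomization
#' null with 1,000 replicates.
#'
#' @param minShared,minContamLen,minContamIdentity decontamination and
#'   collapsing thresholds.
#' @param contaminantTpmCeiling,confidentEukaryoticTpm abundance-evidence
#'   thresholds (TPM).
#' @param filterQuantile,filterThreshold low-count filter.
#' @param alpha,fcLow,fcHigh,posteriorCut DE-calling thresholds.
#' @param minIdentity,minCoverage homolog-gathering thresholds.
#' @param minSupport,nBootstrap tree-support settings.
#' @param nReps randomization-null replicates.
#' @param seed master seed; each stochastic stage derives its own stream.
#' @return list of class \code{runConfig}.
#' @export
runConfig <- function(minShared = 50L, minContamLen = 100L,
                      minContamIdentity = 0.90,
                      contaminantTpmCeiling = 10,
                      confidentEukaryoticTpm = 600,
                      filterQuantile = 0.75, filterThreshold = 10,
                      alpha = 0.05, fcLow = 0.5, fcHigh = 2.0,
                      posteriorCut = 0.95,
                      minIdentity = 0.30, minCoverage = 2/3,
                      minSupport = 50, nBootstrap = 100L,
                      nReps = 1000L, seed = 1L) {
  structure(as.list(environment()), class = "runConfig")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: prokaryotic decontamination, isoform collapsing,
#' expression summarization and DE calling (reduced to gene level),
#' duplicate-cluster detection, the duplication x DE association statistics
#' (overlap test, mixed-direction fraction, randomization null with cluster
#' sizes taken from the detected clusters), COG enrichment of DE genes, and
#' LGT screening of genes with prokaryotic affinity. Fully deterministic
#' given the configuration seed.
#'
#' @param input a \code{\linkS4class{SimulatedData}} object or a directory
#'   readable by \code{\link{readDatasetDir}}.
#' @param config a \code{\link{runConfig}} list.
#' @param outDir optional directory; when given, per-stage tables and
#'   \code{report.json} are written there.
#' @return A run-report list (counts per stage, association statistics,
#'   LGT verdict counts, seed, config echo, wall-clock seconds per stage)
#'   plus the per-stage result objects in its \code{results} element.
#' @export
runAll <- function(input, config = runConfig(), outDir = NULL) {
  if (is.character(input)) input <- readDatasetDir(input)
  if (methods::is(input, "SimulatedData"))
    input <- list(orfs = input@orfs, counts = input@counts,
                  panelEukAa = input@panelEukAa,
                  panelProkNt = input@panelProkNt,
                  panelProkAa = input@panelProkAa,
                  cog = input@cog, introns = input@introns,
                  truth = input@truth)
  timing <- list()
  clock <- function(stage, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    timing[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }

  ## 1. decontamination ------------------------------------------------------
  contam <- clock("decontaminate",
                  screenContaminants(input$orfs, input$panelProkNt,
                                     config$minContamLen,
                                     config$minContamIdentity))
  discardIds <- contam$orf_id[contam$decision == "discard"]
  keepIds <- setdiff(orfIds(input$orfs), discardIds)

  ## 2. isoform collapsing ---------------------------------------------------
  nt <- ntSeqs(input$orfs)[keepIds]
  catalog <- clock("collapse", collapseOrfs(as.character(nt),
                                            config$minShared))

  ## 3. expression and DE ----------------------------------------------------
  se <- input$counts[intersect(rownames(input$counts), keepIds), ]
  expr <- clock("expression", summarizeExpression(
    se, config$filterQuantile, config$filterThreshold,
    config$alpha, config$fcLow, config$fcHigh))
  o2g <- orfToGene(catalog)
  geneDe <- geneLevelDE(expr, o2g)
  tpm <- computeTPM(se[expr$orf_id, ])
  maxTpmOrf <- apply(tpm, 1, max)
  maxTpmGene <- tapply(maxTpmOrf, o2g[expr$orf_id], max)
  deDir <- stats::setNames(geneDe$direction, geneDe$gene_id)
  nUp <- sum(geneDe$direction == "up"); nDown <- sum(geneDe$direction == "down")

  ## 4. duplicate clusters ---------------------------------------------------
  gt <- geneTable(catalog)
  reps <- stats::setNames(gt$representative, gt$gene_id)
  focalAa <- stats::setNames(
    as.character(aaSeqs(input$orfs)[unname(reps)]), names(reps))
  panel <- c(as.character(input$panelEukAa), as.character(input$panelProkAa))
  panelOrigins <- c(
    stats::setNames(rep("other_eukaryote", length(input$panelEukAa)),
                    names(input$panelEukAa)),
    stats::setNames(rep("prokaryote", length(input$panelProkAa)),
                    names(input$panelProkAa)))
  dup <- clock("duplication", detectDuplicateClusters(
    focalAa, panel, panelOrigins, config$minIdentity, config$minCoverage,
    config$minSupport, config$nBootstrap,
    seed = .deriveSeed(config$seed, 4L)))
  clTab <- clusterTable(dup)
  accepted <- clTab[clTab$category %in% c("exclusive_clade", "species_only"), ,
                    drop = FALSE]
  clusterMembers <- strsplit(accepted$members, ",", fixed = TRUE)
  genesInClusters <- unlist(clusterMembers)

  ## 5. association statistics ----------------------------------------------
  assoc <- clock("association", {
    universe <- unique(unname(o2g[expr$orf_id]))
    dupGenes <- intersect(genesInClusters, universe)
    overlap <- if (length(dupGenes) > 0 && (nUp + nDown) > 0)
      dupDeOverlapTest(dupGenes,
                       geneDe$gene_id[geneDe$de_flag &
                                        geneDe$gene_id %in% universe],
                       universe)
    else list(fraction = NA_real_, p_value = NA_real_, n_overlap = NA,
              n_duplicated = length(dupGenes), n_de = nUp + nDown,
              n_universe = length(universe))
    dirAll <- stats::setNames(rep("none", length(universe)), universe)
    dirAll[names(deDir)[names(deDir) %in% universe]] <-
      deDir[names(deDir) %in% universe]
    scorable <- clusterMembers[vapply(clusterMembers,
                                      function(g) all(g %in% universe), TRUE)]
    mixed <- if (length(scorable) > 0)
      mixedDirectionFraction(scorable, dirAll) else NA_real_
    rnd <- if (length(scorable) > 0)
      randomizationNull(unname(dirAll), sum(lengths(scorable)),
                        lengths(scorable), config$nReps,
                        seed = .deriveSeed(config$seed, 5L),
                        observed = mixed)
    else list(null_mean = NA_real_, null_sd = NA_real_,
              empirical_p = NA_real_, n_reps = config$nReps)
    enrich <- if ((nUp + nDown) > 0)
      classEnrichment(input$cog[input$cog$gene_id %in% universe, ],
                      geneDe$gene_id[geneDe$de_flag &
                                       geneDe$gene_id %in% universe],
                      universe)
    else data.frame()
    list(overlap = overlap, mixed = mixed, rnd = rnd, enrich = enrich)
  })

  ## 6. LGT screening ---------------------------------------------------------
  lgt <- clock("lgt", {
    gc <- geneCategories(dup)
    bestOrigin <- stats::setNames(gc$best_hit_origin, gc$gene_id)
    intron <- stats::setNames(input$introns$intron == 1,
                              input$introns$gene_id)
    verdicts <- lapply(gt$gene_id, function(g) {
      ## prokaryotic affinity: the best passing panel hit is prokaryotic
      prokAff <- identical(unname(bestOrigin[g]), "prokaryote")
      tpmG <- if (g %in% names(maxTpmGene)) maxTpmGene[[g]] else 0
      screenLgtCandidate(g, prokAff, tpmG,
                         isTRUE(intron[g]),
                         tpmHigh = config$confidentEukaryoticTpm,
                         tpmLow = config$contaminantTpmCeiling)
    })
    do.call(rbind, verdicts)
  })

  report <- list(
    n_orfs_in = length(input$orfs),
    n_discarded_contaminant = length(discardIds),
    n_orfs_retained = length(keepIds),
    n_genes = length(catalog),
    n_orfs_after_filter = nrow(expr),
    n_de_orfs = sum(expr$de_flag),
    n_de_genes_up = nUp, n_de_genes_down = nDown,
    clusters_by_category = as.list(table(clTab$category)),
    n_clusters_accepted = nrow(accepted),
    n_genes_in_clusters = length(genesInClusters),
    overlap_fraction = assoc$overlap$fraction,
    overlap_p = assoc$overlap$p_value,
    mixed_direction_fraction = assoc$mixed,
    null_mean = assoc$rnd$null_mean,
    null_sd = assoc$rnd$null_sd,
    randomization_p = assoc$rnd$empirical_p,
    lgt_verdicts = as.list(table(lgt$verdict)),
    seed = config$seed,
    config = unclass(config),
    timing_sec = timing
  )
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(contam, file.path(outDir, "contamination.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(geneTable(catalog)),
                       file.path(outDir, "genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(expr, file.path(outDir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(clTab),
                       file.path(outDir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(assoc$enrich))
      utils::write.table(assoc$enrich, file.path(outDir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(lgt, file.path(outDir, "lgt.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  c(report,
    list(results = list(contamination = contam, catalog = catalog,
                        expression = expr, gene_de = geneDe,
                        duplication = dup, association = assoc,
                        lgt = lgt)))
}
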