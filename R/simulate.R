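# Synthetic two-condition transcriptome generator with known ground truth.

GENETIC_CODE_BYAA <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

## Reverse-translate a protein with uniformly random codon choice. Because
## every sequence is reverse-translated independently, two genes with
## similar proteins still have essentially unrelated nucleotide sequences
## (expected identical-codon runs of ~1-2 codons), so recent duplicates do
## not share the >=50-nt exact stretches that define isoforms of one gene.
.reverseTranslate <- function(aa) {
  res <- strsplit(aa, "", fixed = TRUE)[[1]]
  codons <- vapply(res, function(r) {
    cs <- GENETIC_CODE_BYAA[[r]]
    cs[sample.int(length(cs), 1L)]
  }, "")
  paste(codons, collapse = "")
}

.randomProtein <- function(nCodons) {
  paste(sample(AA_ALPHABET20, nCodons, replace = TRUE), collapse = "")
}

## Per-site uniform substitution (to a different symbol), no indels.
.mutateSeq <- function(x, rate, alphabet) {
  res <- strsplit(x, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(res)) < rate)
  if (length(hit)) {
    res[hit] <- vapply(res[hit], function(r) {
      sample(setdiff(alphabet, r), 1L)
    }, "")
  }
  paste(res, collapse = "")
}

#' Simulate negative-binomial counts for a two-condition design
#'
#' Counts are drawn from a negative binomial with variance
#' \code{mu + dispersion * mu^2}. Per-feature base means are proportional to
#' feature length (so that length-normalized TPM is flat across lengths),
#' and differentially expressed features have their condition-2 mean
#' multiplied (up) or divided (down) by \code{2^deLog2fcMagnitude}.
#'
#' @param condition factor/character of sample conditions (two levels,
#'   condition 2 is the "treatment", e.g. high salt).
#' @param deTruth named character vector over features with values
#'   \code{"up"}, \code{"down"} or \code{"none"}.
#' @param nbMean expected base count for a feature of average length.
#' @param nbDispersion negative-binomial dispersion (> 0).
#' @param deLog2fcMagnitude |log2 fold change| applied to DE features.
#' @param lengths named numeric vector of feature lengths (nt); every
#'   feature in \code{deTruth} must have a positive length.
#' @param seed integer seed.
#' @param baseMeanFactor optional named multiplier on the base mean (used
#'   for low-abundance features); defaults to 1.
#' @return Integer count matrix, features x samples.
#' @examples
#' cond <- rep(c("cond1", "cond2"), each = 3)
#' truth <- c(g1 = "up", g2 = "none")
#' simulateCounts(cond, truth, nbMean = 100, nbDispersion = 0.1,
#'                deLog2fcMagnitude = 2, lengths = c(g1 = 900, g2 = 900),
#'                seed = 1)
#' @export
simulateCounts <- function(condition, deTruth, nbMean, nbDispersion,
                           deLog2fcMagnitude, lengths, seed,
                           baseMeanFactor = NULL) {
  .assert(nbDispersion > 0, "nbDispersion must be > 0")
  ids <- names(deTruth)
  .assert(!is.null(ids) && all(ids %in% names(lengths)),
          "every feature in deTruth must have a length")
  len <- lengths[ids]
  .assert(all(len > 0), "zero-length sequence")
  set.seed(seed)
  condition <- as.character(condition)
  lev <- unique(condition)
  .assert(length(lev) == 2L, "exactly two conditions are required")
  base <- nbMean * len / mean(len)
  if (!is.null(baseMeanFactor)) base <- base * baseMeanFactor[ids]
  fc <- ifelse(deTruth == "up", 2^deLog2fcMagnitude,
               ifelse(deTruth == "down", 2^-deLog2fcMagnitude, 1))
  mu <- cbind(base, base * fc)[, match(condition, lev), drop = FALSE]
  counts <- matrix(
    stats::rnbinom(length(mu), mu = as.numeric(mu), size = 1 / nbDispersion),
    nrow = length(ids))
  dimnames(counts) <- list(ids,
                           paste0(ifelse(condition == lev[1], "c1", "c2"),
                                  "_r", stats::ave(seq_along(condition),
                                                   condition,
                                                   FUN = seq_along)))
  counts
}

#' Simulate a complete two-condition transcriptome dataset
#'
#' Generates a catalog of genes (some in recent-duplication families, with
#' tunable protein divergence), isoform ORFs sharing an exact central
#' nucleotide block, prokaryotic contaminant ORFs copied from a prokaryote
#' panel at a tunable identity, an other-eukaryote homolog panel,
#' COG-class and intron annotations, and a negative-binomial count matrix
#' with designated DE genes. All components are a deterministic function of
#' the configuration (including its seed).
#'
#' @param config a \code{\linkS4class{SimConfig}}.
#' @param dir optional directory; when given, all artifacts are written
#'   there as plain-text files (FASTA/TSV/JSON) via
#'   \code{\link{writeSimulatedData}}.
#' @return A \code{\linkS4class{SimulatedData}} object.
#' @examples
#' sim <- simulateDataset(simConfig(nGenes = 50L, nFamilies = 4L,
#'                                  nContaminants = 5L, seed = 1L))
#' sim
#' @export
simulateDataset <- function(config, dir = NULL) {
  methods::validObject(config)
  set.seed(config@seed)
  nG <- config@nGenes

  ## --- gene proteins, families first -------------------------------------
  famSizes <- integer(0)
  if (config@nFamilies > 0L) {
    famSizes <- config@familySizes$size[
      sample.int(nrow(config@familySizes), config@nFamilies,
                 replace = TRUE, prob = config@familySizes$weight)]
    .assert(sum(famSizes) <= nG,
            "invalid configuration field 'nFamilies': family members exceed nGenes")
  }
  geneIdsAll <- sprintf("g%05d", seq_len(nG))
  geneAa <- character(nG)
  familyOfGene <- rep(NA_character_, nG)
  names(familyOfGene) <- geneIdsAll
  g <- 0L
  famAncestors <- character(length(famSizes))
  for (f in seq_along(famSizes)) {
    nCod <- sample(150:300, 1L)
    anc <- .randomProtein(nCod)
    famAncestors[f] <- anc
    for (m in seq_len(famSizes[f])) {
      g <- g + 1L
      geneAa[g] <- .mutateSeq(anc, config@divergencePerCopy, AA_ALPHABET20)
      familyOfGene[g] <- sprintf("fam%03d", f)
    }
  }
  nFamilyGenes <- g
  while (g < nG) {
    g <- g + 1L
    geneAa[g] <- .randomProtein(sample(150:300, 1L))
  }
  geneNt <- vapply(geneAa, .reverseTranslate, "", USE.NAMES = FALSE)

  ## --- isoform ORFs -------------------------------------------------------
  blockCod <- ceiling(config@sharedStretchLen / 3)
  orfIdsL <- list(); orfNt <- list(); orfAa <- list()
  geneOfOrf <- character(0)
  for (i in seq_len(nG)) {
    nCod <- nchar(geneAa[i])
    nIso <- sample.int(config@nIsoformsMax, 1L)
    bStart <- max(1L, floor((nCod - blockCod) / 2))
    bEnd <- min(nCod, bStart + blockCod - 1L)
    ids <- sprintf("%s.o%d", geneIdsAll[i], seq_len(nIso))
    for (k in seq_len(nIso)) {
      if (k == 1L) {
        s <- 1L; e <- nCod
      } else {
        s <- sample.int(bStart, 1L)
        e <- bEnd + sample.int(nCod - bEnd + 1L, 1L) - 1L
      }
      orfNt[[length(orfNt) + 1L]] <- substr(geneNt[i], 3L * (s - 1L) + 1L, 3L * e)
      orfAa[[length(orfAa) + 1L]] <- substr(geneAa[i], s, e)
    }
    orfIdsL[[i]] <- ids
    geneOfOrf <- c(geneOfOrf, stats::setNames(rep(geneIdsAll[i], nIso), ids))
  }
  orfIdsV <- unlist(orfIdsL)

  ## --- prokaryote panel and contaminants ----------------------------------
  nProk <- max(8L, config@nContaminants)
  prokAa <- vapply(seq_len(nProk),
                   function(i) .randomProtein(sample(250:400, 1L)), "")
  prokNt <- vapply(prokAa, .reverseTranslate, "", USE.NAMES = FALSE)
  prokIds <- sprintf("prok%03d", seq_len(nProk))
  contIds <- character(0)
  if (config@nContaminants > 0L) {
    src <- sample.int(nProk, config@nContaminants, replace = FALSE)
    contIds <- sprintf("cont%03d", seq_len(config@nContaminants))
    for (j in seq_len(config@nContaminants)) {
      full <- prokNt[src[j]]
      nCod <- nchar(full) / 3L
      wCod <- sample(60:min(250L, nCod), 1L)
      s <- sample.int(nCod - wCod + 1L, 1L)
      frag <- substr(full, 3L * (s - 1L) + 1L, 3L * (s + wCod - 1L))
      mut <- .mutateSeq(frag, 1 - config@contaminantIdentity,
                        c("A", "C", "G", "T"))
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(mut), no.init.codon = TRUE))
      aa <- gsub("*", "X", aa, fixed = TRUE)
      orfNt[[length(orfNt) + 1L]] <- mut
      orfAa[[length(orfAa) + 1L]] <- aa
    }
    orfIdsV <- c(orfIdsV, contIds)
  }

  ## --- other-eukaryote panel ----------------------------------------------
  eukAa <- character(0); eukIds <- character(0)
  famHasPanel <- stats::setNames(logical(length(famSizes)),
                                 sprintf("fam%03d", seq_along(famSizes)))
  for (f in seq_along(famSizes)) {
    if (stats::runif(1) < config@familyPanelProb) {
      famHasPanel[f] <- TRUE
      for (h in 1:2) {
        eukIds <- c(eukIds, sprintf("euk_f%03d_%d", f, h))
        eukAa <- c(eukAa, .mutateSeq(famAncestors[f], 0.5, AA_ALPHABET20))
      }
    }
  }
  for (i in seq.int(nFamilyGenes + 1L, length.out = nG - nFamilyGenes)) {
    if (stats::runif(1) < config@singletonPanelProb) {
      eukIds <- c(eukIds, sprintf("euk_s%05d", i))
      eukAa <- c(eukAa, .mutateSeq(geneAa[i], 0.3, AA_ALPHABET20))
    }
  }

  ## --- annotations and DE truth -------------------------------------------
  cogClass <- config@cogClasses$class[
    sample.int(nrow(config@cogClasses), nG, replace = TRUE,
               prob = config@cogClasses$weight)]
  intron <- stats::runif(nG) < config@intronFraction
  names(intron) <- geneIdsAll
  deStatus <- stats::setNames(rep("none", nG), geneIdsAll)
  nDe <- round(config@deFraction * nG)
  if (nDe > 0) {
    deGenes <- sample(geneIdsAll, nDe)
    nUp <- round(nDe * config@deUpShare)
    deStatus[deGenes[seq_len(nUp)]] <- "up"
    if (nUp < nDe) deStatus[deGenes[seq.int(nUp + 1L, nDe)]] <- "down"
  }

  ## --- counts ---------------------------------------------------------------
  orfLen <- stats::setNames(nchar(unlist(orfNt)), orfIdsV)
  deOfOrf <- stats::setNames(rep("none", length(orfIdsV)), orfIdsV)
  focalOrfs <- names(geneOfOrf)
  deOfOrf[focalOrfs] <- deStatus[geneOfOrf[focalOrfs]]
  baseFactor <- stats::setNames(rep(1, length(orfIdsV)), orfIdsV)
  nLow <- round(config@lowAbundanceFraction * length(focalOrfs))
  ## low-abundance ORFs are drawn from non-DE genes so that DE truth stays
  ## recoverable after the low-count filter
  lowPool <- focalOrfs[deOfOrf[focalOrfs] == "none"]
  if (nLow > 0 && length(lowPool) > 0)
    baseFactor[sample(lowPool, min(nLow, length(lowPool)))] <- 0.002
  if (length(contIds)) baseFactor[contIds] <- 0.05
  condition <- rep(c("cond1", "cond2"), each = config@nReplicates)
  counts <- simulateCounts(condition, deOfOrf, config@nbMean,
                           config@nbDispersion, config@deLog2fcMagnitude,
                           orfLen, seed = .deriveSeed(config@seed, 7L),
                           baseMeanFactor = baseFactor)

  ## --- assemble -------------------------------------------------------------
  orfs <- orfSet(stats::setNames(unlist(orfNt), orfIdsV),
                 stats::setNames(unlist(orfAa), orfIdsV))
  se <- countExperiment(counts, condition, orfLen)
  origin <- c(stats::setNames(rep("focal", length(focalOrfs)), focalOrfs),
              stats::setNames(rep("contaminant", length(contIds)), contIds),
              stats::setNames(rep("other_eukaryote", length(eukIds)), eukIds),
              stats::setNames(rep("prokaryote", nProk), prokIds))
  geneOfOrfAll <- c(geneOfOrf,
                    stats::setNames(sprintf("gcont%03d",
                                            seq_along(contIds)), contIds))
  truth <- list(gene_of_orf = geneOfOrfAll,
                family_of_gene = familyOfGene,
                de_status = deStatus,
                origin = origin,
                intron = intron,
                family_has_panel = famHasPanel)
  sim <- new("SimulatedData",
             config = config, orfs = orfs, counts = se,
             panelEukAa = Biostrings::AAStringSet(
               stats::setNames(eukAa, eukIds)),
             panelProkNt = Biostrings::DNAStringSet(
               stats::setNames(prokNt, prokIds)),
             panelProkAa = Biostrings::AAStringSet(
               stats::setNames(prokAa, prokIds)),
             cog = data.frame(gene_id = geneIdsAll, class = cogClass,
                              stringsAsFactors = FALSE),
             introns = data.frame(gene_id = geneIdsAll,
                                  intron = as.integer(intron),
                                  stringsAsFactors = FALSE),
             truth = truth)
  if (!is.null(dir)) writeSimulatedData(sim, dir)
  sim
}
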