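#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings DNAStringSet AAStringSet
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Simulation configuration
#'
#' Parameters of the synthetic two-condition transcriptome generator. The
#' defaults describe the study conditions every downstream stage is tested
#' under: a desk-scale catalog of ~1,200 genes, recent duplicate families at
#' 5\% protein divergence, contaminants copied from a prokaryote panel at
#' 95\% nucleotide identity, and negative-binomial counts in which 20\% of
#' genes are differentially expressed with a 62/38 up/down split.
#'
#' @slot nGenes number of genes (each may have several isoform ORFs).
#' @slot nFamilies number of recent-duplication families among the genes.
#' @slot familySizes data.frame with columns \code{size} and \code{weight};
#'   family sizes are drawn from this distribution.
#' @slot divergencePerCopy expected substitutions/site between a family
#'   member and the family ancestor, at the protein level, in [0, 1).
#' @slot nIsoformsMax maximal number of isoform ORFs per gene.
#' @slot sharedStretchLen length (nt) of the exact block all isoforms of a
#'   gene share; must exceed the collapsing threshold to be recoverable.
#' @slot nContaminants number of prokaryotic contaminant ORFs.
#' @slot contaminantIdentity per-site identity of a contaminant to its
#'   source prokaryote sequence, in (0.9, 1].
#' @slot nReplicates replicates per condition (two conditions are fixed).
#' @slot deFraction fraction of genes differentially expressed.
#' @slot deUpShare fraction of DE genes up-regulated in condition 2.
#' @slot deLog2fcMagnitude |log2 fold change| of DE genes (> 1).
#' @slot nbMean expected base count of an average-length ORF.
#' @slot nbDispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @slot lowAbundanceFraction fraction of ORFs given near-zero counts.
#' @slot intronFraction fraction of genes flagged as intron-containing.
#' @slot cogClasses data.frame with columns \code{class} and \code{weight}.
#' @slot familyPanelProb probability that a family has homologs in the
#'   other-eukaryote panel (families without any are "species only").
#' @slot singletonPanelProb probability that a non-family gene has a
#'   panel ortholog.
#' @slot seed integer seed; the whole dataset is a deterministic function
#'   of the configuration including this seed.
#' @export
setClass("SimConfig", representation(
  nGenes = "integer",
  nFamilies = "integer",
  familySizes = "data.frame",
  divergencePerCopy = "numeric",
  nIsoformsMax = "integer",
  sharedStretchLen = "integer",
  nContaminants = "integer",
  contaminantIdentity = "numeric",
  nReplicates = "integer",
  deFraction = "numeric",
  deUpShare = "numeric",
  deLog2fcMagnitude = "numeric",
  nbMean = "numeric",
  nbDispersion = "numeric",
  lowAbundanceFraction = "numeric",
  intronFraction = "numeric",
  cogClasses = "data.frame",
  familyPanelProb = "numeric",
  singletonPanelProb = "numeric",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  frac <- function(x, name, lo = 0, hi = 1) {
    if (length(x) != 1 || is.na(x) || x < lo || x > hi)
      return(sprintf("invalid configuration field '%s': must be in [%g, %g]",
                     name, lo, hi))
    NULL
  }
  msgs <- c(
    if (object@nGenes < 1L) "invalid configuration field 'nGenes': must be >= 1",
    if (object@nFamilies < 0L) "invalid configuration field 'nFamilies': must be >= 0",
    if (!all(c("size", "weight") %in% names(object@familySizes)) ||
        nrow(object@familySizes) == 0 || sum(object@familySizes$weight) <= 0)
      "invalid configuration field 'familySizes': needs size/weight columns with positive total weight",
    if (any(object@familySizes$size < 2))
      "invalid configuration field 'familySizes': family sizes must be >= 2",
    frac(object@divergencePerCopy, "divergencePerCopy", 0, 0.999),
    if (object@nIsoformsMax < 1L) "invalid configuration field 'nIsoformsMax': must be >= 1",
    if (object@sharedStretchLen < 1L) "invalid configuration field 'sharedStretchLen': must be >= 1",
    if (object@nContaminants < 0L) "invalid configuration field 'nContaminants': must be >= 0",
    if (object@nContaminants > 0L &&
        (object@contaminantIdentity <= 0.9 || object@contaminantIdentity > 1))
      "invalid configuration field 'contaminantIdentity': must be in (0.9, 1]",
    if (object@nReplicates < 2L) "invalid configuration field 'nReplicates': must be >= 2",
    frac(object@deFraction, "deFraction"),
    frac(object@deUpShare, "deUpShare"),
    if (object@deLog2fcMagnitude <= 1)
      "invalid configuration field 'deLog2fcMagnitude': must be > 1",
    if (object@nbMean <= 0) "invalid configuration field 'nbMean': must be > 0",
    if (object@nbDispersion <= 0) "invalid configuration field 'nbDispersion': must be > 0",
    frac(object@lowAbundanceFraction, "lowAbundanceFraction"),
    frac(object@intronFraction, "intronFraction"),
    if (!all(c("class", "weight") %in% names(object@cogClasses)) ||
        sum(object@cogClasses$weight) <= 0)
      "invalid configuration field 'cogClasses': needs class/weight columns with positive total weight",
    frac(object@familyPanelProb, "familyPanelProb"),
    frac(object@singletonPanelProb, "singletonPanelProb")
  )
  msgs <- msgs[!vapply(msgs, is.null, TRUE)]
  if (length(msgs)) unlist(msgs) else TRUE
})

#' Construct a simulation configuration
#'
#' @param nGenes,nFamilies,familySizes,divergencePerCopy,nIsoformsMax
#'   see the slot documentation of \code{\linkS4class{SimConfig}}.
#' @param sharedStretchLen,nContaminants,contaminantIdentity,nReplicates
#'   see the slot documentation of \code{\linkS4class{SimConfig}}.
#' @param deFraction,deUpShare,deLog2fcMagnitude,nbMean,nbDispersion
#'   see the slot documentation of \code{\linkS4class{SimConfig}}.
#' @param lowAbundanceFraction,intronFraction,cogClasses see the slot
#'   documentation of \code{\linkS4class{SimConfig}}.
#' @param familyPanelProb,singletonPanelProb,seed see the slot
#'   documentation of \code{\linkS4class{SimConfig}}.
#' @return A validated \code{SimConfig} object.
#' @examples
#' cfg <- simConfig(nGenes = 100L, nFamilies = 5L, seed = 1L)
#' @export
simConfig <- function(nGenes = 1200L,
                      nFamilies = 40L,
                      familySizes = data.frame(size = c(2L, 3L),
                                               weight = c(0.7, 0.3)),
                      divergencePerCopy = 0.05,
                      nIsoformsMax = 3L,
                      sharedStretchLen = 60L,
                      nContaminants = 25L,
                      contaminantIdentity = 0.95,
                      nReplicates = 3L,
                      deFraction = 0.2,
                      deUpShare = 0.62,
                      deLog2fcMagnitude = 2,
                      nbMean = 100,
                      nbDispersion = 0.1,
                      lowAbundanceFraction = 0.05,
                      intronFraction = 0.3,
                      cogClasses = data.frame(
                        class = c("C", "E", "G", "J", "K", "L", "O", "P", "T", "S"),
                        weight = rep(1, 10)),
                      familyPanelProb = 0.7,
                      singletonPanelProb = 0.3,
                      seed = 1L) {
  new("SimConfig",
      nGenes = as.integer(nGenes), nFamilies = as.integer(nFamilies),
      familySizes = familySizes, divergencePerCopy = divergencePerCopy,
      nIsoformsMax = as.integer(nIsoformsMax),
      sharedStretchLen = as.integer(sharedStretchLen),
      nContaminants = as.integer(nContaminants),
      contaminantIdentity = contaminantIdentity,
      nReplicates = as.integer(nReplicates),
      deFraction = deFraction, deUpShare = deUpShare,
      deLog2fcMagnitude = deLog2fcMagnitude,
      nbMean = nbMean, nbDispersion = nbDispersion,
      lowAbundanceFraction = lowAbundanceFraction,
      intronFraction = intronFraction, cogClasses = cogClasses,
      familyPanelProb = familyPanelProb,
      singletonPanelProb = singletonPanelProb,
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenes, "genes,", object@nFamilies,
      "duplicate families,", object@nContaminants, "contaminants,",
      2L * object@nReplicates, "samples, seed", object@seed, "\n")
})

#' ORF catalog
#'
#' Paired nucleotide and protein sequences of predicted open reading
#' frames, keyed by a shared set of ORF identifiers.
#'
#' @slot nt a \code{\link[Biostrings]{DNAStringSet}} of ORF nucleotide
#'   sequences.
#' @slot aa a \code{\link[Biostrings]{AAStringSet}} of the corresponding
#'   protein sequences, with identical names.
#' @export
setClass("OrfSet", representation(nt = "DNAStringSet", aa = "AAStringSet"))

setValidity("OrfSet", function(object) {
  msgs <- c(
    if (length(object@nt) != length(object@aa))
      "nt and aa must have the same length",
    if (!identical(names(object@nt), names(object@aa)))
      "nt and aa must carry identical ORF names",
    if (is.null(names(object@nt)) && length(object@nt) > 0)
      "ORF sequences must be named",
    if (anyDuplicated(names(object@nt))) "ORF ids must be unique",
    if (length(object@nt) > 0 && any(Biostrings::width(object@nt) == 0))
      "zero-length nucleotide sequence"
  )
  if (length(msgs)) msgs else TRUE
})

#' Construct an ORF catalog
#'
#' @param nt named \code{DNAStringSet} (or named character vector).
#' @param aa named \code{AAStringSet} (or named character vector) with the
#'   same names.
#' @return An \code{OrfSet}.
#' @export
orfSet <- function(nt, aa) {
  if (!methods::is(nt, "DNAStringSet")) nt <- Biostrings::DNAStringSet(nt)
  if (!methods::is(aa, "AAStringSet")) aa <- Biostrings::AAStringSet(aa)
  new("OrfSet", nt = nt, aa = aa)
}

#' @describeIn orfSet number of ORFs.
#' @param x an \code{OrfSet}.
#' @export
setMethod("length", "OrfSet", function(x) length(x@nt))

#' ORF identifiers
#' @param x an \code{OrfSet}.
#' @return Character vector of ORF ids.
#' @export
orfIds <- function(x) names(x@nt)

#' Nucleotide sequences of an ORF catalog
#' @param x an \code{OrfSet}.
#' @return A \code{DNAStringSet}.
#' @export
ntSeqs <- function(x) x@nt

#' Protein sequences of an ORF catalog
#' @param x an \code{OrfSet}.
#' @return An \code{AAStringSet}.
#' @export
aaSeqs <- function(x) x@aa

setMethod("show", "OrfSet", function(object) {
  cat("OrfSet with", length(object), "ORFs\n")
  if (length(object) > 0)
    cat("  nt widths:", paste(range(Biostrings::width(object@nt)),
                              collapse = "-"), "\n")
})

#' Gene catalog produced by isoform collapsing
#'
#' @slot genes a \code{DataFrame} with one row per gene: \code{gene_id},
#'   \code{representative} (longest isoform, ties broken by smallest ORF
#'   id), \code{n_orfs}, and \code{orf_ids} (comma-separated).
#' @slot orf2gene named character vector mapping every ORF id to its gene.
#' @export
setClass("GeneCatalog", representation(genes = "DataFrame",
                                       orf2gene = "character"))

setValidity("GeneCatalog", function(object) {
  msgs <- c(
    if (anyDuplicated(names(object@orf2gene))) "ORF ids must be unique",
    if (!all(object@orf2gene %in% object@genes$gene_id))
      "orf2gene refers to unknown gene ids"
  )
  if (length(msgs)) msgs else TRUE
})

#' @describeIn geneIds number of genes in the catalog.
#' @export
setMethod("length", "GeneCatalog", function(x) nrow(x@genes))

#' Gene-catalog accessors
#'
#' @param x a \code{GeneCatalog}.
#' @return \code{geneIds}: character vector of gene ids;
#'   \code{orfToGene}: named character vector ORF id -> gene id;
#'   \code{geneTable}: the per-gene \code{DataFrame}.
#' @export
geneIds <- function(x) x@genes$gene_id

#' @rdname geneIds
#' @export
orfToGene <- function(x) x@orf2gene

#' @rdname geneIds
#' @export
geneTable <- function(x) x@genes

setMethod("show", "GeneCatalog", function(object) {
  cat("GeneCatalog:", nrow(object@genes), "genes from",
      length(object@orf2gene), "ORFs\n")
})

#' Simulated dataset with ground truth
#'
#' Container returned by \code{\link{simulateDataset}}.
#'
#' @slot config the \code{SimConfig} used.
#' @slot orfs an \code{OrfSet} (focal ORFs plus contaminant ORFs).
#' @slot counts a \code{SummarizedExperiment} of per-ORF counts with
#'   \code{condition} in \code{colData} and \code{length} in \code{rowData}.
#' @slot panelEukAa other-eukaryote protein panel (\code{AAStringSet}).
#' @slot panelProkNt prokaryote nucleotide panel (\code{DNAStringSet}).
#' @slot panelProkAa prokaryote protein panel (\code{AAStringSet}).
#' @slot cog data.frame (gene_id, class).
#' @slot introns data.frame (gene_id, intron 0/1).
#' @slot truth list of ground-truth maps: \code{gene_of_orf},
#'   \code{family_of_gene}, \code{de_status}, \code{origin}, \code{intron},
#'   \code{family_has_panel}.
#' @export
setClass("SimulatedData", representation(
  config = "SimConfig",
  orfs = "OrfSet",
  counts = "SummarizedExperiment",
  panelEukAa = "AAStringSet",
  panelProkNt = "DNAStringSet",
  panelProkAa = "AAStringSet",
  cog = "data.frame",
  introns = "data.frame",
  truth = "list"
))

setMethod("show", "SimulatedData", function(object) {
  cat("SimulatedData:", length(object@orfs), "ORFs (",
      object@config@nContaminants, "contaminants ),",
      ncol(object@counts), "samples, seed", object@config@seed, "\n")
})

#' Duplicate-cluster detection result
#'
#' @slot clusters \code{DataFrame} with one row per cluster: cluster_id,
#'   members (comma-separated), n_members, category, support, reason.
#' @slot geneCategories \code{DataFrame} with per-gene candidate
#'   classification.
#' @slot trees named list of \code{phylo} objects (one per tree-tested
#'   cluster).
#' @export
setClass("DuplicationResult", representation(clusters = "DataFrame",
                                             geneCategories = "DataFrame",
                                             trees = "list"))

setMethod("show", "DuplicationResult", function(object) {
  tab <- table(object@clusters$category)
  cat("DuplicationResult:", nrow(object@clusters), "clusters (",
      paste(names(tab), as.integer(tab), collapse = ", "), ")\n")
})

#' Cluster table of a duplication result
#' @param x a \code{DuplicationResult}.
#' @return The per-cluster \code{DataFrame}.
#' @export
clusterTable <- function(x) x@clusters

#' Per-gene candidate categories of a duplication result
#' @param x a \code{DuplicationResult}.
#' @return The per-gene \code{DataFrame}.
#' @export
geneCategories <- function(x) x@geneCategories
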