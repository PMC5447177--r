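# Plain-text readers and writers for the pipeline's external interfaces.

#' Write a simulated dataset to a directory
#'
#' Emits FASTA (nt and aa ORFs, panels), TSV (counts, sample conditions,
#' COG classes, intron flags) and the ground truth as JSON.
#'
#' @param sim a \code{\linkS4class{SimulatedData}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of written file paths.
#' @export
writeSimulatedData <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(ntSeqs(sim@orfs), p("orfs.fna"))
  Biostrings::writeXStringSet(aaSeqs(sim@orfs), p("orfs.faa"))
  Biostrings::writeXStringSet(sim@panelEukAa, p("panel_eukaryote.faa"))
  Biostrings::writeXStringSet(sim@panelProkNt, p("panel_prokaryote.fna"))
  Biostrings::writeXStringSet(sim@panelProkAa, p("panel_prokaryote.faa"))
  counts <- SummarizedExperiment::assay(sim@counts, "counts")
  utils::write.table(data.frame(orf_id = rownames(counts), counts,
                                check.names = FALSE),
                     p("counts.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = colnames(counts),
               condition = SummarizedExperiment::colData(sim@counts)$condition),
    p("samples.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim@cog, p("cog.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim@introns, p("introns.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ## named vectors as JSON objects so names survive the round trip
  jsonlite::write_json(lapply(sim@truth, as.list), p("truth.json"),
                       auto_unbox = TRUE)
  invisible(p(c("orfs.fna", "orfs.faa", "panel_eukaryote.faa",
                "panel_prokaryote.fna", "panel_prokaryote.faa",
                "counts.tsv", "samples.tsv", "cog.tsv", "introns.tsv",
                "truth.json")))
}

#' Read a simulated (or equivalently formatted real) dataset directory
#'
#' Counterpart of \code{\link{writeSimulatedData}} for the sequence,
#' count and annotation files; the ground-truth JSON is read when present.
#'
#' @param dir directory containing the files written by
#'   \code{\link{writeSimulatedData}}.
#' @return list with orfs (\code{OrfSet}), counts
#'   (\code{SummarizedExperiment}), panelEukAa, panelProkNt, panelProkAa,
#'   cog, introns, truth (or NULL).
#' @export
readDatasetDir <- function(dir) {
  p <- function(f) file.path(dir, f)
  nt <- Biostrings::readDNAStringSet(p("orfs.fna"))
  aa <- Biostrings::readAAStringSet(p("orfs.faa"))
  counts <- utils::read.delim(p("counts.tsv"), check.names = FALSE)
  m <- as.matrix(counts[, -1, drop = FALSE])
  rownames(m) <- counts$orf_id
  samples <- utils::read.delim(p("samples.tsv"))
  lengths <- stats::setNames(Biostrings::width(nt), names(nt))
  truth <- NULL
  if (file.exists(p("truth.json"))) {
    truth <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
    truth <- lapply(truth, unlist)
  }
  list(orfs = orfSet(nt, aa),
       counts = countExperiment(m, samples$condition[
         match(colnames(m), samples$sample_id)], lengths),
       panelEukAa = Biostrings::readAAStringSet(p("panel_eukaryote.faa")),
       panelProkNt = Biostrings::readDNAStringSet(p("panel_prokaryote.fna")),
       panelProkAa = Biostrings::readAAStringSet(p("panel_prokaryote.faa")),
       cog = utils::read.delim(p("cog.tsv"), stringsAsFactors = FALSE),
       introns = utils::read.delim(p("introns.tsv"), stringsAsFactors = FALSE),
       truth = truth)
}
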