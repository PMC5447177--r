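# Lateral gene-transfer candidate screening and short protein-motif scans.

#' Screen a gene as a lateral gene-transfer candidate
#'
#' Combines the evidence the analysis uses to separate genuinely resident
#' genes of prokaryotic affinity from residual contamination:
#' \itemize{
#'   \item prokaryotic affinity AND (intron present OR max TPM strictly
#'     above \code{tpmHigh}) -> \code{lgt_candidate} (clade exclusivity
#'     with prokaryotes raises \code{confidence} but is not required);
#'   \item prokaryotic affinity AND max TPM at or below \code{tpmLow} AND
#'     no intron -> \code{probable_contaminant};
#'   \item prokaryotic affinity otherwise -> \code{uncertain};
#'   \item no prokaryotic affinity -> \code{not_lgt}.
#' }
#'
#' @param geneId gene identifier.
#' @param bestHitsProkaryotic logical; best sequence hits are prokaryotic.
#' @param maxTpm maximal TPM across samples (>= 0).
#' @param hasIntron logical intron flag.
#' @param tree optional \code{phylo} with the focal gene and mixed-origin
#'   homologs; when supplied together with \code{prokLeaves}, exclusivity of
#'   \{focal gene + prokaryote leaves\} is tested with
#'   \code{\link{testExclusiveClade}}.
#' @param focalLeaf tip label of the focal gene in \code{tree}.
#' @param prokLeaves tip labels of prokaryote leaves in \code{tree}.
#' @param absentInSister optional logical: not found in the sister lineage.
#' @param tpmHigh strict high-expression threshold (default 600 TPM).
#' @param tpmLow contaminant ceiling (default 10 TPM).
#' @param minSupport support threshold for clade exclusivity (default 50).
#' @return One-row data.frame (LgtCandidate): gene_id,
#'   best_hits_prokaryotic, prokaryote_clade_exclusive, clade_support,
#'   max_tpm, has_intron, absent_in_sister, confidence, verdict.
#' @examples
#' screenLgtCandidate("g1", TRUE, 3986, TRUE)  # lgt_candidate
#' @export
screenLgtCandidate <- function(geneId, bestHitsProkaryotic, maxTpm,
                               hasIntron, tree = NULL, focalLeaf = NULL,
                               prokLeaves = NULL, absentInSister = NA,
                               tpmHigh = 600, tpmLow = 10,
                               minSupport = 50) {
  .assert(maxTpm >= 0, "negative TPM")
  cladeExcl <- NA
  cladeSup <- NA_real_
  if (!is.null(tree) && !is.null(focalLeaf) && length(prokLeaves) > 0) {
    res <- testExclusiveClade(tree, c(focalLeaf, prokLeaves), minSupport)
    cladeExcl <- res$is_exclusive
    cladeSup <- res$support
  }
  verdict <- if (!bestHitsProkaryotic) "not_lgt"
  else if (hasIntron || maxTpm > tpmHigh) "lgt_candidate"
  else if (maxTpm <= tpmLow && !hasIntron) "probable_contaminant"
  else "uncertain"
  confidence <- if (verdict == "lgt_candidate" && isTRUE(cladeExcl)) "high"
  else if (verdict == "lgt_candidate") "moderate"
  else NA_character_
  data.frame(gene_id = geneId,
             best_hits_prokaryotic = bestHitsProkaryotic,
             prokaryote_clade_exclusive = cladeExcl,
             clade_support = cladeSup,
             max_tpm = maxTpm, has_intron = hasIntron,
             absent_in_sister = absentInSister,
             confidence = confidence, verdict = verdict,
             stringsAsFactors = FALSE)
}

## Parse a motif pattern into a list of allowed-residue sets. Supports
## plain residue letters, x/X single-residue wildcards, and bracketed
## alternations [KR] or [K/R].
.parseMotif <- function(pattern) {
  .assert(nchar(pattern) > 0, "empty motif pattern")
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  sets <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      alt <- character(0)
      while (j <= length(chars) && chars[j] != "]") {
        if (chars[j] != "/") {
          .assert(chars[j] %in% AA_ALPHABET20,
                  sprintf("illegal pattern character '%s'", chars[j]))
          alt <- c(alt, chars[j])
        }
        j <- j + 1L
      }
      .assert(j <= length(chars), "unterminated bracket in motif pattern")
      .assert(length(alt) > 0, "empty alternation in motif pattern")
      sets[[length(sets) + 1L]] <- alt
      i <- j + 1L
    } else if (ch %in% c("x", "X")) {
      sets[[length(sets) + 1L]] <- AA_ALPHABET20
      i <- i + 1L
    } else {
      .assert(ch %in% AA_ALPHABET20,
              sprintf("illegal pattern character '%s'", ch))
      sets[[length(sets) + 1L]] <- ch
      i <- i + 1L
    }
  }
  sets
}

#' Scan a protein for a wildcard motif
#'
#' Reports every (possibly overlapping) occurrence of a short motif in a
#' protein. \code{x} and \code{X} match any single residue; \code{[KR]} or
#' \code{[K/R]} matches either alternative.
#'
#' @param protein amino-acid sequence (character or \code{AAString}).
#' @param pattern motif pattern, e.g. \code{"PxLXHGDLWSxN"} or
#'   \code{"Tx[K/R]"}.
#' @param sequenceId optional id carried into the result.
#' @return data.frame of MotifHit rows: sequence_id, motif, start (1-based),
#'   match (the resolved substring).
#' @examples
#' scanMotif("AAPALAHGDLWSANAA", "PxLXHGDLWSxN")
#' @export
scanMotif <- function(protein, pattern, sequenceId = NA_character_) {
  protein <- as.character(protein)
  sets <- .parseMotif(pattern)
  regex <- paste(vapply(sets, function(s) {
    if (length(s) == 1L && !identical(s, AA_ALPHABET20)) s
    else if (identical(s, AA_ALPHABET20)) "."
    else paste0("[", paste(s, collapse = ""), "]")
  }, ""), collapse = "")
  w <- length(sets)
  m <- gregexpr(paste0("(?=", regex, ")"), protein, perl = TRUE)[[1]]
  starts <- as.integer(m)
  starts <- starts[starts > 0 & starts + w - 1L <= nchar(protein)]
  if (length(starts) == 0 || (length(starts) == 1 && starts[1] == -1))
    return(data.frame(sequence_id = character(0), motif = character(0),
                      start = integer(0), match = character(0)))
  data.frame(sequence_id = sequenceId, motif = pattern, start = starts,
             match = substring(protein, starts, starts + w - 1L),
             stringsAsFactors = FALSE)
}

#' Check ER-retention signals
#'
#' Flags the classical endoplasmic-reticulum retention signals: KDEL or
#' HDEL as the last four residues, KK as the last two, K at positions -3
#' and -1 (KxK), and RR at the N-terminus (positions 1-2, or 2-3 to
#' tolerate the initiator methionine).
#'
#' @param protein amino-acid sequence of length >= 4.
#' @return Named logical vector: KDEL_C, HDEL_C, KK_C, KxK_C, RR_N.
#' @examples
#' checkErRetention("MSTAKDEL")
#' @export
checkErRetention <- function(protein) {
  protein <- as.character(protein)
  n <- nchar(protein)
  .assert(n >= 4L, "protein too short for C-terminal signal checks")
  last4 <- substr(protein, n - 3L, n)
  c(KDEL_C = last4 == "KDEL",
    HDEL_C = last4 == "HDEL",
    KK_C = substr(protein, n - 1L, n) == "KK",
    KxK_C = substr(protein, n - 2L, n - 2L) == "K" &&
      substr(protein, n, n) == "K",
    RR_N = substr(protein, 1L, 2L) == "RR" ||
      substr(protein, 2L, 3L) == "RR")
}
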