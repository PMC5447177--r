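# Isoform collapsing by shared exact nucleotide stretches, and screening of
# prokaryotic contaminant sequences.

#' Longest exact nucleotide stretch shared by two sequences
#'
#' Length of the longest exact common substring of two nucleotide
#' sequences, on the forward strand (assembled transcripts are oriented by
#' ORF prediction; set \code{revComp = TRUE} to also consider the reverse
#' complement of \code{b}).
#'
#' Uses the fact that a common substring of length L exists iff the two
#' k-mer sets intersect at k = L, and binary-searches L; this is exact and
#' avoids the quadratic dynamic program.
#'
#' @param a,b nucleotide sequences (character or \code{DNAString}).
#' @param revComp also consider the reverse complement of \code{b}.
#' @return Integer length of the longest shared stretch (0 if none).
#' @examples
#' longestSharedStretch("ACGTACGT", "GGACGTAA")  # 5 ("ACGTA")
#' @export
longestSharedStretch <- function(a, b, revComp = FALSE) {
  a <- as.character(a); b <- as.character(b)
  .assert(nchar(a) > 0 && nchar(b) > 0, "empty input sequence")
  if (revComp) {
    brc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
    return(max(longestSharedStretch(a, b), longestSharedStretch(a, brc)))
  }
  shares <- function(k) {
    length(intersect(unique(.kmers(a, k)), unique(.kmers(b, k)))) > 0
  }
  hi <- min(nchar(a), nchar(b))
  if (!shares(1L)) return(0L)
  lo <- 1L
  while (lo < hi) {           # invariant: shares(lo) TRUE, find max
    mid <- as.integer(ceiling((lo + hi) / 2))
    if (shares(mid)) lo <- mid else hi <- mid - 1L
  }
  lo
}

#' Collapse ORFs into genes by shared exact stretches
#'
#' Two ORFs belong to the same gene iff they are connected (transitively)
#' through pairs sharing an exact nucleotide stretch of at least
#' \code{minShared} nucleotides. The gene representative is the longest
#' isoform, ties broken by lexicographically smallest ORF id.
#'
#' Sharing a stretch of >= k nt is equivalent to sharing an exact k-mer, so
#' the partition is built by bucketing all \code{minShared}-mers and
#' union-finding ORFs within buckets; this matches the all-pairs
#' longest-common-substring closure exactly.
#'
#' @param orfs an \code{\linkS4class{OrfSet}} or a named character vector of
#'   nucleotide sequences.
#' @param minShared minimum shared stretch length in nucleotides
#'   (default 50, inclusive: "at least 50").
#' @return A \code{\linkS4class{GeneCatalog}}.
#' @examples
#' nt <- c(a = strrep("ACGT", 30), b = paste0(strrep("ACGT", 15), strrep("TTG", 40)))
#' collapseOrfs(nt, minShared = 50)
#' @export
collapseOrfs <- function(orfs, minShared = 50L) {
  nt <- if (methods::is(orfs, "OrfSet")) ntSeqs(orfs) else
    Biostrings::DNAStringSet(orfs)
  ids <- names(nt)
  .assert(!is.null(ids), "ORF sequences must be named")
  .assert(!anyDuplicated(ids), "duplicate ORF ids")
  seqs <- as.character(nt)
  parent <- .ufNew(length(seqs))
  pairs <- .sharedKmerPairs(seqs, as.integer(minShared), 1L)
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs)))
      parent <- .ufUnion(parent, pairs[r, 1L], pairs[r, 2L])
  }
  comp <- .ufComponents(parent)
  geneIdx <- match(comp, unique(comp))
  gid <- sprintf("g%05d", geneIdx)
  widths <- nchar(seqs)
  rows <- lapply(split(seq_along(ids), gid), function(ix) {
    w <- widths[ix]
    cand <- ids[ix][w == max(w)]
    data.frame(representative = sort(cand)[1], n_orfs = length(ix),
               orf_ids = paste(sort(ids[ix]), collapse = ","),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  genes <- S4Vectors::DataFrame(gene_id = rownames(tab), tab,
                                row.names = NULL)
  new("GeneCatalog", genes = genes,
      orf2gene = stats::setNames(gid, ids))
}

## Ungapped diagonal window scan between two sequences: finds the
## best-scoring window of length > minLen under the scoring that is
## positive exactly when identity > minId. Scores are integers (match
## +(1-minId)*S, mismatch -minId*S with S = 10000), so the strict identity
## boundary is decided exactly. Returns list(found, length, identity).
.bestUngappedRegion <- function(a, b, minLen, minId) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  na <- length(av); nb <- length(bv)
  S <- 10000L
  wMatch <- S - as.integer(round(minId * S))
  wMis <- -as.integer(round(minId * S))
  best <- list(found = FALSE, length = 0L, identity = 0)
  bestScore <- -Inf
  for (off in seq.int(-(nb - 1L), na - 1L)) {
    i0 <- max(1L, 1L + off); j0 <- i0 - off
    L <- min(na - i0, nb - j0) + 1L
    if (L <= minLen) next
    eq <- av[i0:(i0 + L - 1L)] == bv[j0:(j0 + L - 1L)]
    w <- c(0L, cumsum(ifelse(eq, wMatch, wMis)))
    nWin <- L - minLen                       # window ends minLen+1 .. L
    pref <- cummin(w[seq_len(nWin)])
    vals <- w[seq.int(minLen + 2L, L + 1L)] - pref
    mx <- max(vals)
    if (mx > bestScore) {
      bestScore <- mx
      jrel <- which.max(vals)                # window end = minLen + jrel
      jend <- minLen + jrel
      istart <- which.min(w[seq_len(jrel)])  # w index of window start
      len <- jend - istart + 1L
      cs <- c(0L, cumsum(eq))
      matches <- cs[jend + 1L] - cs[istart]
      best <- list(found = mx > 0L, length = len,
                   identity = matches / len)
    }
  }
  best
}

#' Screen one ORF against a prokaryote sequence panel
#'
#' Ungapped seeded window scan of the ORF nucleotide sequence against every
#' panel sequence: the ORF is flagged for discarding iff some contiguous
#' region longer than \code{minLen} bp is more than \code{minIdentity}
#' identical (both strict, so a region of exactly 100 bp at 100\% identity
#' is kept). The scan examines every diagonal window, so the decision
#' equals the exhaustive window definition exactly; indels are not modeled
#' (assembled contaminant copies are substitution-diverged).
#'
#' @param orfNt ORF nucleotide sequence (character or \code{DNAString}).
#' @param prokDb named \code{DNAStringSet} (or character vector) of
#'   prokaryote sequences.
#' @param minLen minimum region length in bp (strict; default 100).
#' @param minIdentity minimum region identity (strict; default 0.90).
#' @param orfId optional ORF id carried into the result.
#' @return A one-row data.frame: orf_id, subject_id (NA if no shared
#'   sequence), region_length, region_identity, decision
#'   ("discard"/"keep"). On "keep", the reported region is the longest
#'   exact shared stretch.
#' @export
screenProkaryoticSimilarity <- function(orfNt, prokDb, minLen = 100L,
                                        minIdentity = 0.90, orfId = NA_character_) {
  .assert(length(prokDb) > 0, "prokaryote panel is empty")
  db <- as.character(prokDb)
  if (is.null(names(db))) names(db) <- paste0("db", seq_along(db))
  orfChr <- as.character(orfNt)
  bestHit <- NULL; bestKeepLen <- -1L; bestKeepId <- NA_character_
  for (s in names(db)) {
    reg <- .bestUngappedRegion(orfChr, db[[s]], as.integer(minLen),
                               minIdentity)
    if (reg$found &&
        (is.null(bestHit) || reg$length > bestHit$region_length)) {
      bestHit <- data.frame(orf_id = orfId, subject_id = s,
                            region_length = reg$length,
                            region_identity = reg$identity,
                            decision = "discard", stringsAsFactors = FALSE)
    }
    if (is.null(bestHit)) {
      run <- longestSharedStretch(orfChr, db[[s]])
      if (run > bestKeepLen) { bestKeepLen <- run; bestKeepId <- s }
    }
  }
  if (!is.null(bestHit)) return(bestHit)
  data.frame(orf_id = orfId,
             subject_id = if (bestKeepLen > 0) bestKeepId else NA_character_,
             region_length = max(bestKeepLen, 0L),
             region_identity = if (bestKeepLen > 0) 1 else 0,
             decision = "keep", stringsAsFactors = FALSE)
}

#' Screen a whole ORF catalog for prokaryotic contamination
#'
#' Applies \code{\link{screenProkaryoticSimilarity}} to every ORF, with an
#' exact-seed prefilter: only ORF/panel pairs sharing at least one
#' \code{seedLen}-mer are aligned (a region > minLen bp at > minIdentity
#' contains error-free seeds of this length with overwhelming probability).
#'
#' @param orfs \code{\linkS4class{OrfSet}} or named character vector of
#'   nucleotide sequences.
#' @param prokDb named \code{DNAStringSet}/character vector.
#' @param minLen,minIdentity as in \code{\link{screenProkaryoticSimilarity}}.
#' @param seedLen exact-match seed length for the prefilter (default 14).
#' @return data.frame with one row per ORF (ContaminationHit fields).
#' @export
screenContaminants <- function(orfs, prokDb, minLen = 100L,
                               minIdentity = 0.90, seedLen = 14L) {
  nt <- if (methods::is(orfs, "OrfSet")) as.character(ntSeqs(orfs)) else
    as.character(orfs)
  db <- if (methods::is(prokDb, "DNAStringSet")) prokDb else
    Biostrings::DNAStringSet(prokDb)
  .assert(length(db) > 0, "prokaryote panel is empty")
  all <- c(nt, as.character(db))
  pairs <- .sharedKmerPairs(all, as.integer(seedLen), 1L)
  nOrf <- length(nt)
  cross <- pairs[pairs[, 1L] <= nOrf & pairs[, 2L] > nOrf, , drop = FALSE]
  out <- data.frame(orf_id = names(nt),
                    subject_id = NA_character_,
                    region_length = 0L, region_identity = 0,
                    decision = "keep", stringsAsFactors = FALSE)
  if (nrow(cross)) {
    for (i in unique(cross[, 1L])) {
      subj <- cross[cross[, 1L] == i, 2L] - nOrf
      res <- screenProkaryoticSimilarity(nt[i], db[subj], minLen,
                                         minIdentity, orfId = names(nt)[i])
      out[i, ] <- res
    }
  }
  out
}

#' Classify gene origin from abundance and intron evidence
#'
#' For genes whose sequences resemble prokaryotic sequences, expression
#' level and intron presence separate genuinely eukaryotic (e.g. laterally
#' acquired) genes from residual contamination: confirmed contaminant
#' transcripts never exceeded ~10 TPM, while resident genes of prokaryotic
#' affinity were expressed orders of magnitude higher (> 600 TPM) and/or
#' carry introns.
#'
#' @param hasProkaryoticAffinity logical; best sequence hits prokaryotic.
#' @param maxTpm maximal TPM across all samples (>= 0).
#' @param hasIntron logical intron flag.
#' @param contaminantTpmCeiling genes at or below this TPM are called
#'   contaminant (default 10).
#' @param confidentEukaryoticTpm genes strictly above this TPM are called
#'   eukaryotic (default 600).
#' @return One of "eukaryotic", "contaminant", "uncertain".
#' @examples
#' classifyOriginByAbundance(TRUE, 3986, TRUE)   # eukaryotic
#' classifyOriginByAbundance(TRUE, 8, FALSE)     # contaminant
#' @export
classifyOriginByAbundance <- function(hasProkaryoticAffinity, maxTpm,
                                      hasIntron,
                                      contaminantTpmCeiling = 10,
                                      confidentEukaryoticTpm = 600) {
  .assert(maxTpm >= 0, "negative TPM")
  if (!hasProkaryoticAffinity) return("eukaryotic")
  if (hasIntron || maxTpm > confidentEukaryoticTpm) return("eukaryotic")
  if (maxTpm <= contaminantTpmCeiling) return("contaminant")
  "uncertain"
}
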