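# Recent gene-duplication detection: conspecific similarity ranking,
# homolog gathering, bootstrapped neighbor-joining trees, and the
# exclusive-clade test.

.blosum62 <- function() {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  get("BLOSUM62", envir = environment())
}

## Vectorized local protein alignment of several patterns against one
## subject; returns score, identity (matches / alignment columns) and
## coverage of the shorter sequence.
.alignLocal <- function(patterns, subject) {
  aln <- Biostrings::pairwiseAlignment(patterns, subject, type = "local",
                                       substitutionMatrix = .blosum62(),
                                       gapOpening = 10, gapExtension = 0.5)
  cols <- Biostrings::nchar(aln)
  ident <- ifelse(cols > 0, Biostrings::nmatch(aln) / cols, 0)
  subjLen <- nchar(as.character(subject))
  patLen <- Biostrings::width(patterns)
  spanPat <- Biostrings::width(Biostrings::pattern(aln))
  spanSub <- Biostrings::width(Biostrings::subject(aln))
  covered <- ifelse(patLen <= subjLen, spanPat, spanSub)
  data.frame(score = Biostrings::score(aln), identity = ident,
             coverage_shorter = covered / pmin(patLen, subjLen))
}

#' Pairwise local protein similarity
#'
#' Smith-Waterman local alignment with BLOSUM62 and affine gaps (open 10,
#' extend 0.5); reports the alignment score, identity over aligned columns
#' and coverage of the shorter sequence.
#'
#' @param a,b amino-acid sequences (character or \code{AAString}); standard
#'   residues plus X.
#' @return One-row data.frame: score, identity, coverage_shorter.
#' @examples
#' pairwiseProteinSimilarity("MKLVINTWWPLVI", "MKLVINTWWPLVI")
#' @export
pairwiseProteinSimilarity <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  .assert(nchar(a) > 0 && nchar(b) > 0, "empty sequence")
  .assert(.validAaString(a) && .validAaString(b),
          "non-amino-acid symbols in sequence")
  .alignLocal(Biostrings::AAStringSet(a), Biostrings::AAString(b))
}

#' Does a homolog hit pass the gathering thresholds?
#'
#' Homologs are retained when the alignment covers more than
#' \code{minCoverage} of the shorter sequence AND the sequences are more
#' than \code{minIdentity} identical (both strict).
#'
#' @param identity alignment identity fraction(s).
#' @param coverageShorter coverage fraction(s) of the shorter sequence.
#' @param minIdentity strict identity threshold (default 0.30).
#' @param minCoverage strict coverage threshold (default 2/3).
#' @return Logical vector.
#' @export
homologHitPasses <- function(identity, coverageShorter,
                             minIdentity = 0.30, minCoverage = 2/3) {
  identity > minIdentity & coverageShorter > minCoverage
}

#' Gather homologs of a query protein
#'
#' Aligns the query against every database sequence and returns the hits
#' passing \code{\link{homologHitPasses}}, annotated with their origin.
#'
#' @param query amino-acid sequence (character or \code{AAString}).
#' @param db named \code{AAStringSet} (or character vector).
#' @param origins named character vector mapping db ids to
#'   \{focal, other_eukaryote, prokaryote\} (optional).
#' @param minIdentity,minCoverage strict thresholds (defaults 0.30, 2/3).
#' @param queryId id excluded from the db as self.
#' @return data.frame of HomologHit rows: subject_id, subject_origin,
#'   score, identity, coverage_shorter.
#' @export
gatherHomologs <- function(query, db, origins = NULL, minIdentity = 0.30,
                           minCoverage = 2/3, queryId = NULL) {
  if (!methods::is(db, "AAStringSet")) db <- Biostrings::AAStringSet(db)
  .assert(length(db) > 0, "homolog database is empty")
  if (!is.null(queryId)) db <- db[setdiff(names(db), queryId)]
  if (length(db) == 0)
    return(data.frame(subject_id = character(0),
                      subject_origin = character(0), score = numeric(0),
                      identity = numeric(0), coverage_shorter = numeric(0)))
  hits <- .alignLocal(db, Biostrings::AAString(as.character(query)))
  hits <- data.frame(subject_id = names(db),
                     subject_origin = if (is.null(origins)) NA_character_
                                      else unname(origins[names(db)]),
                     hits, stringsAsFactors = FALSE, row.names = NULL)
  hits[homologHitPasses(hits$identity, hits$coverage_shorter,
                        minIdentity, minCoverage), , drop = FALSE]
}

## k-mer prefiltered all-vs-all passing-hit table over a combined sequence
## panel. Returns data.frame(id1, id2, score, identity, coverage_shorter)
## for unordered pairs that pass the thresholds.
.homologHitTable <- function(seqs, minIdentity, minCoverage,
                             prefilterK = 4L, prefilterMin = 4L) {
  chr <- as.character(seqs)
  pairs <- .sharedKmerPairs(chr, prefilterK, prefilterMin)
  if (nrow(pairs) == 0)
    return(data.frame(id1 = character(0), id2 = character(0),
                      score = numeric(0), identity = numeric(0),
                      coverage_shorter = numeric(0)))
  res <- vector("list", length(unique(pairs[, 2L])))
  k <- 0L
  for (j in unique(pairs[, 2L])) {   # group alignments by second member
    ii <- pairs[pairs[, 2L] == j, 1L]
    hit <- .alignLocal(seqs[ii], Biostrings::AAString(chr[j]))
    k <- k + 1L
    res[[k]] <- data.frame(id1 = names(seqs)[ii], id2 = names(seqs)[j],
                           hit, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out[homologHitPasses(out$identity, out$coverage_shorter,
                       minIdentity, minCoverage), , drop = FALSE]
}

#' Classify focal genes as candidate recent duplicates
#'
#' For each focal (conspecific) gene, all passing homolog hits against the
#' combined focal + panel database are ranked by alignment score:
#' \itemize{
#'   \item \emph{candidate}: the best hit is a focal sequence and it
#'     strictly outscores the best other-eukaryote hit;
#'   \item \emph{species_only}: at least one focal homolog passes but no
#'     non-focal homolog passes at all;
#'   \item \emph{non_candidate}: otherwise (including score ties between
#'     the best focal and the best non-focal hit, a conservative
#'     tie-break).
#' }
#'
#' @param focal named \code{AAStringSet}/character of focal representatives
#'   (longest isoform per gene).
#' @param panel named \code{AAStringSet}/character of non-focal sequences.
#' @param panelOrigins named character vector over panel ids with values
#'   "other_eukaryote" or "prokaryote".
#' @param minIdentity,minCoverage strict homolog-gathering thresholds.
#' @param prefilterK,prefilterMin exact k-mer prefilter: only pairs sharing
#'   at least \code{prefilterMin} k-mers of length \code{prefilterK} are
#'   aligned.
#' @return list with \code{categories} (data.frame gene_id, category,
#'   best_focal_score, best_other_euk_score) and \code{hits} (the passing
#'   pairwise hit table).
#' @export
classifyCandidateDuplicates <- function(focal, panel, panelOrigins,
                                        minIdentity = 0.30,
                                        minCoverage = 2/3,
                                        prefilterK = 4L, prefilterMin = 4L) {
  if (!methods::is(focal, "AAStringSet")) focal <- Biostrings::AAStringSet(focal)
  if (!methods::is(panel, "AAStringSet")) panel <- Biostrings::AAStringSet(panel)
  .assert(!anyDuplicated(c(names(focal), names(panel))),
          "sequence ids must be unique across focal set and panel")
  origins <- c(stats::setNames(rep("focal", length(focal)), names(focal)),
               panelOrigins[names(panel)])
  allSeq <- Biostrings::AAStringSet(c(as.character(focal),
                                      as.character(panel)))
  hits <- .homologHitTable(allSeq, minIdentity, minCoverage,
                           prefilterK, prefilterMin)
  ## symmetric closure so that every gene sees all its hits
  sym <- rbind(hits,
               data.frame(id1 = hits$id2, id2 = hits$id1,
                          score = hits$score, identity = hits$identity,
                          coverage_shorter = hits$coverage_shorter))
  sym <- sym[sym$id1 != sym$id2, , drop = FALSE]
  category <- character(length(focal))
  bestFocalV <- bestEukV <- rep(NA_real_, length(focal))
  bestOrigin <- rep(NA_character_, length(focal))
  for (gi in seq_along(focal)) {
    gid <- names(focal)[gi]
    h <- sym[sym$id1 == gid, , drop = FALSE]
    org <- origins[h$id2]
    if (nrow(h) > 0) bestOrigin[gi] <- org[which.max(h$score)]
    bestFocal <- suppressWarnings(max(h$score[org == "focal"]))
    bestNonFocal <- suppressWarnings(max(h$score[org != "focal"]))
    bestEuk <- suppressWarnings(max(h$score[org == "other_eukaryote"]))
    bestFocalV[gi] <- if (is.finite(bestFocal)) bestFocal else NA_real_
    bestEukV[gi] <- if (is.finite(bestEuk)) bestEuk else NA_real_
    ## candidate: the best passing hit is a conspecific paralog and it
    ## strictly outscores every non-focal hit (ties are conservative).
    category[gi] <- if (!is.finite(bestFocal)) "non_candidate"
    else if (!is.finite(bestNonFocal)) "species_only"
    else if (bestFocal > bestNonFocal) "candidate"
    else "non_candidate"
  }
  categories <- data.frame(gene_id = names(focal),
                           category = category,
                           best_focal_score = bestFocalV,
                           best_other_euk_score = bestEukV,
                           best_hit_origin = bestOrigin,
                           stringsAsFactors = FALSE, row.names = NULL)
  list(categories = categories, hits = sym, origins = origins)
}

## ---- multiple alignment (center-star) and distances ----------------------

## Center-star progressive alignment: every sequence is globally aligned to
## the longest sequence (the center) and gaps are merged ("once a gap,
## always a gap"). Exact for the no-indel families the generator emits and
## adequate as a lightweight stand-in for a full MSA program.
.centerStarAlign <- function(seqs) {
  chr <- as.character(seqs)
  n <- length(chr)
  if (length(unique(nchar(chr))) == 1L) {
    m <- do.call(rbind, strsplit(chr, "", fixed = TRUE))
    rownames(m) <- names(chr)
    return(m)
  }
  center <- order(-nchar(chr), names(chr))[1]
  others <- setdiff(seq_len(n), center)
  L <- nchar(chr[center])
  alnP <- vector("list", n); alnS <- vector("list", n)
  insAfter <- matrix(0L, nrow = n, ncol = L + 1L)  # insertions after pos i
  for (i in others) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(chr[i]), Biostrings::AAString(chr[center]),
      type = "global", substitutionMatrix = .blosum62(),
      gapOpening = 10, gapExtension = 0.5)
    p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    alnP[[i]] <- p; alnS[[i]] <- s
    pos <- 0L; run <- 0L
    for (k in seq_along(s)) {
      if (s[k] == "-") run <- run + 1L
      else {
        if (run > 0L) insAfter[i, pos + 1L] <- run
        run <- 0L; pos <- pos + 1L
      }
    }
    if (run > 0L) insAfter[i, pos + 1L] <- run
  }
  master <- apply(insAfter, 2, max)
  width <- L + sum(master)
  rows <- matrix("-", nrow = n, ncol = width, dimnames = list(names(chr), NULL))
  ## project the center; master[1] gaps come before position 1
  centerRow <- c(rep("-", master[1L]),
                 unlist(lapply(seq_len(L), function(p)
                   c(substr(chr[center], p, p), rep("-", master[p + 1L])))))
  rows[center, ] <- centerRow
  for (i in others) {
    p <- alnP[[i]]; s <- alnS[[i]]
    out <- character(0)
    pos <- 0L; k <- 1L
    ## leading insertions
    ins <- character(0)
    while (k <= length(s) && s[k] == "-") { ins <- c(ins, p[k]); k <- k + 1L }
    out <- c(out, ins, rep("-", master[1L] - length(ins)))
    while (k <= length(s)) {
      pos <- pos + 1L
      out <- c(out, p[k]); k <- k + 1L
      ins <- character(0)
      while (k <= length(s) && s[k] == "-") { ins <- c(ins, p[k]); k <- k + 1L }
      out <- c(out, ins, rep("-", master[pos + 1L] - length(ins)))
    }
    rows[i, ] <- out
  }
  rows
}

## p-distance with pairwise deletion on a character alignment matrix
.pDistance <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    d[i, j] <- d[j, i] <- if (any(ok)) mean(m[i, ok] != m[j, ok]) else 0.75
  }
  stats::as.dist(d)
}

#' Build a bootstrapped neighbor-joining tree
#'
#' Aligns the sequences (trivially when they are equal-length, otherwise by
#' center-star merging of global pairwise alignments), computes p-distances
#' with pairwise deletion, infers a neighbor-joining topology, and attaches
#' bootstrap supports: the percentage of \code{nBootstrap} column-resampled
#' replicates containing each internal-edge bipartition of the tree.
#' Alignment columns with more than \code{maxGapFrac} gaps are dropped
#' before distance computation.
#'
#' @param seqs named \code{AAStringSet} or character vector (>= 4).
#' @param nBootstrap number of bootstrap replicates (default 100).
#' @param seed integer seed (column resampling is the only randomness).
#' @param maxGapFrac drop alignment columns with a higher gap fraction
#'   (default 0.5).
#' @return An \code{ape} \code{phylo} object whose \code{node.label} holds
#'   the bootstrap percentage of each internal node's bipartition (NA at
#'   the root).
#' @export
buildBootstrapTree <- function(seqs, nBootstrap = 100L, seed = 1L,
                               maxGapFrac = 0.5) {
  if (!methods::is(seqs, "AAStringSet")) seqs <- Biostrings::AAStringSet(seqs)
  .assert(length(seqs) >= 4L,
          paste("fewer than 4 sequences: use the 3-taxon shortcut",
                "(any 2-vs-1 split is trivially monophyletic)"))
  .assert(!is.null(names(seqs)) && !anyDuplicated(names(seqs)),
          "sequences must carry unique names")
  m <- .centerStarAlign(seqs)
  gapFrac <- colMeans(m == "-")
  m <- m[, gapFrac <= maxGapFrac, drop = FALSE]
  .assert(ncol(m) > 0, "no alignment columns left after gap trimming")
  tr <- ape::nj(.pDistance(m))
  set.seed(seed)
  boots <- vector("list", nBootstrap)
  for (b in seq_len(nBootstrap)) {
    cols <- sample.int(ncol(m), replace = TRUE)
    boots[[b]] <- ape::nj(.pDistance(m[, cols, drop = FALSE]))
  }
  class(boots) <- "multiPhylo"
  counts <- ape::prop.clades(tr, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / nBootstrap)
  support[1L] <- NA  # root of the unrooted representation, not an edge
  tr$node.label <- as.character(support)
  tr
}

#' Test whether focal leaves form an exclusive, supported clade
#'
#' TRUE iff some internal edge of the (unrooted) tree bipartitions the
#' leaves into exactly the focal set versus all others AND that edge's
#' support is strictly greater than \code{minSupport}. With exactly one
#' non-focal leaf the split is topologically forced and counts as exclusive
#' with support NA.
#'
#' @param tree an \code{ape} \code{phylo} with numeric (or numeric-string)
#'   \code{node.label} supports on internal nodes.
#' @param focalLeaves character vector of focal tip labels (>= 2).
#' @param minSupport strict support threshold in percent (default 50).
#' @return list(is_exclusive = logical, support = numeric or NA).
#' @examples
#' tr <- ape::read.tree(text = "((F1,F2)75,(E1,E2));")
#' testExclusiveClade(tr, c("F1", "F2"))
#' @export
testExclusiveClade <- function(tree, focalLeaves, minSupport = 50) {
  tips <- tree$tip.label
  .assert(all(focalLeaves %in% tips), "focal leaf missing from tree")
  .assert(length(focalLeaves) >= 2L, "at least two focal leaves required")
  nonFocal <- setdiff(tips, focalLeaves)
  .assert(length(nonFocal) >= 1L, "at least one non-focal leaf required")
  if (length(nonFocal) == 1L)
    return(list(is_exclusive = TRUE, support = NA_real_))
  parts <- ape::prop.part(tree)
  labels <- attr(parts, "labels")
  focalIdx <- sort(match(focalLeaves, labels))
  allIdx <- seq_along(labels)
  supports <- suppressWarnings(as.numeric(tree$node.label))
  for (nodeI in seq_along(parts)) {
    clade <- sort(parts[[nodeI]])
    if (identical(clade, focalIdx) ||
        identical(clade, setdiff(allIdx, focalIdx))) {
      if (length(clade) == length(allIdx)) next  # root: trivial split
      sup <- if (length(supports) >= nodeI) supports[nodeI] else NA_real_
      ok <- !is.na(sup) && sup > minSupport
      return(list(is_exclusive = ok, support = sup))
    }
  }
  list(is_exclusive = FALSE, support = NA_real_)
}

#' Detect recent duplicate clusters
#'
#' Pipeline composition over a focal set of gene representatives and a
#' mixed-origin panel: classify candidates
#' (\code{\link{classifyCandidateDuplicates}}), cluster candidate and
#' species-only genes by connected components of mutual passing hits,
#' gather each cluster's non-focal homologs, build (or ingest) a
#' bootstrapped tree, and accept clusters whose focal members form an
#' exclusive clade with support strictly above \code{minSupport}.
#'
#' @param focal named \code{AAStringSet}/character of representatives.
#' @param panel named \code{AAStringSet}/character of panel sequences.
#' @param panelOrigins named character vector ("other_eukaryote" /
#'   "prokaryote").
#' @param minIdentity,minCoverage strict homolog thresholds (0.30, 2/3).
#' @param minSupport strict bootstrap support threshold (default 50).
#' @param nBootstrap bootstrap replicates (default 100).
#' @param seed integer seed for the bootstrap resampling.
#' @param treeDir optional directory of externally computed Newick trees
#'   (\code{<cluster_id>.nwk}, support values as internal node labels);
#'   preferred over the internal tree builder when present.
#' @param maxHomologsPerCluster cap on non-focal leaves per cluster tree
#'   (the highest-scoring homologs are kept; default 10).
#' @return A \code{\linkS4class{DuplicationResult}}.
#' @export
detectDuplicateClusters <- function(focal, panel, panelOrigins,
                                    minIdentity = 0.30, minCoverage = 2/3,
                                    minSupport = 50, nBootstrap = 100L,
                                    seed = 1L, treeDir = NULL,
                                    maxHomologsPerCluster = 10L) {
  if (!methods::is(focal, "AAStringSet")) focal <- Biostrings::AAStringSet(focal)
  if (!methods::is(panel, "AAStringSet")) panel <- Biostrings::AAStringSet(panel)
  cls <- classifyCandidateDuplicates(focal, panel, panelOrigins,
                                     minIdentity, minCoverage)
  cats <- cls$categories
  hits <- cls$hits
  eligible <- cats$gene_id[cats$category %in% c("candidate", "species_only")]
  ## connected components over mutual passing focal-focal hits
  parent <- .ufNew(length(eligible))
  ff <- hits[hits$id1 %in% eligible & hits$id2 %in% eligible, , drop = FALSE]
  if (nrow(ff)) {
    i1 <- match(ff$id1, eligible); i2 <- match(ff$id2, eligible)
    for (r in seq_len(nrow(ff))) parent <- .ufUnion(parent, i1[r], i2[r])
  }
  comp <- .ufComponents(parent)
  clusters <- split(eligible, comp)
  clusters <- clusters[vapply(clusters, length, 1L) >= 2L]
  allSeqs <- Biostrings::AAStringSet(c(as.character(focal),
                                       as.character(panel)))
  rows <- list(); trees <- list()
  ci <- 0L
  for (members in clusters) {
    ci <- ci + 1L
    cid <- sprintf("cluster%04d", ci)
    members <- sort(members)
    memberCats <- cats$category[match(members, cats$gene_id)]
    ## non-focal homologs of any member
    hm <- hits[hits$id1 %in% members &
                 cls$origins[hits$id2] != "focal", , drop = FALSE]
    hm <- hm[order(-hm$score), , drop = FALSE]
    homologs <- unique(hm$id2)
    if (length(homologs) > maxHomologsPerCluster)
      homologs <- homologs[seq_len(maxHomologsPerCluster)]
    category <- NA_character_; support <- NA_real_; reason <- ""
    if (length(homologs) == 0L) {
      category <- "species_only"
    } else {
      leaves <- c(members, homologs)
      tr <- NULL
      if (!is.null(treeDir)) {
        f <- file.path(treeDir, paste0(cid, ".nwk"))
        if (file.exists(f)) {
          tr <- ape::read.tree(f)
          if (!all(members %in% tr$tip.label)) {
            tr <- NULL
            category <- "rejected"
            reason <- "external tree missing cluster genes"
          }
        } else {
          category <- "rejected"
          reason <- "external tree not found"
        }
      } else if (length(leaves) >= 4L) {
        tr <- buildBootstrapTree(allSeqs[leaves], nBootstrap,
                                 seed = .deriveSeed(seed, ci))
      }
      if (is.na(category)) {
        if (is.null(tr)) {
          ## 2 focal members + 1 homolog: exclusivity topologically forced
          category <- "exclusive_clade"
        } else {
          trees[[cid]] <- tr
          res <- testExclusiveClade(tr, members, minSupport)
          support <- res$support
          category <- if (res$is_exclusive) "exclusive_clade" else "rejected"
          if (category == "rejected" && reason == "")
            reason <- "focal genes not an exclusive supported clade"
        }
      }
    }
    rows[[ci]] <- data.frame(cluster_id = cid,
                             members = paste(members, collapse = ","),
                             n_members = length(members),
                             category = category, support = support,
                             reason = reason, stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = character(0), members = character(0),
               n_members = integer(0), category = character(0),
               support = numeric(0), reason = character(0))
  new("DuplicationResult",
      clusters = S4Vectors::DataFrame(tab),
      geneCategories = S4Vectors::DataFrame(cats),
      trees = trees)
}

#' Count distinct gene copies after near-identity deduplication
#'
#' Collapses sequences whose pairwise local-alignment identity is strictly
#' greater than \code{identityDedup} into single-linkage groups and returns
#' the number of groups (each represented by its longest member).
#'
#' @param seqs named \code{AAStringSet}/character vector (>= 1).
#' @param identityDedup strict identity threshold (default 0.90).
#' @return Integer copy count.
#' @export
countGeneCopies <- function(seqs, identityDedup = 0.90) {
  if (!methods::is(seqs, "AAStringSet")) seqs <- Biostrings::AAStringSet(seqs)
  .assert(length(seqs) >= 1L, "at least one sequence required")
  n <- length(seqs)
  if (n == 1L) return(1L)
  parent <- .ufNew(n)
  for (j in 2:n) {
    hit <- .alignLocal(seqs[seq_len(j - 1L)], Biostrings::AAString(
      as.character(seqs[[j]])))
    for (i in which(hit$identity > identityDedup))
      parent <- .ufUnion(parent, i, j)
  }
  length(unique(.ufComponents(parent)))
}
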