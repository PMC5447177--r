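# Hypergeometric enrichment, the duplication x differential-expression
# overlap test, and the mixed-direction cluster statistic with its
# Monte-Carlo randomization null and analytic expectation.

## COG classes excluded from enrichment testing by default
COG_EXCLUDED_CLASSES <- c("Cell motility", "Defense mechanisms",
                          "Unknown function", "General predictions only",
                          "Nuclear structures", "No hits found")

#' Hypergeometric tail probability
#'
#' Upper tail \eqn{P(X \ge k)} (or lower tail \eqn{P(X \le k)} for
#' depletion) of a hypergeometric draw of \code{n} from a universe of
#' \code{N} containing \code{K} marked items.
#'
#' @param N universe size.
#' @param K marked items in the universe.
#' @param n draw size.
#' @param k observed marked items in the draw.
#' @param lower return the lower tail (default FALSE: upper tail).
#' @return Tail probability.
#' @examples
#' hypergeometricTail(10, 5, 4, 4)  # 5/210
#' @export
hypergeometricTail <- function(N, K, n, k, lower = FALSE) {
  .assert(K <= N && n <= N && k >= 0 && k <= n && k <= K + 0,
          "inconsistent hypergeometric counts")
  if (lower) stats::phyper(k, K, N - K, n)
  else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Functional-class (COG) enrichment by the hypergeometric test
#'
#' Per class, tests over-representation (upper tail) and depletion (lower
#' tail) of the class among foreground genes relative to the universe, with
#' Benjamini-Hochberg correction across the retained classes only. Classes
#' in \code{excludedClasses} are removed before testing and do not
#' participate in the BH family (default exclusion list:
#' \code{COG_EXCLUDED_CLASSES}).
#'
#' @param annotations data.frame with columns \code{gene_id}, \code{class};
#'   genes may carry multiple classes (one row per gene/class pair; each
#'   class family is tested marginally).
#' @param foreground character vector of foreground gene ids (subset of the
#'   universe).
#' @param universe character vector of universe gene ids.
#' @param excludedClasses classes removed before testing.
#' @return data.frame: class_label, n_class_fg, n_fg, n_class_bg,
#'   n_universe, p_enriched, p_depleted, adj_p_enriched, adj_p_depleted,
#'   direction.
#' @export
classEnrichment <- function(annotations, foreground, universe,
                            excludedClasses = COG_EXCLUDED_CLASSES) {
  .assert(all(foreground %in% universe),
          "foreground gene missing from universe")
  ann <- annotations[annotations$gene_id %in% universe &
                       !(annotations$class %in% excludedClasses), ,
                     drop = FALSE]
  ann <- unique(ann[, c("gene_id", "class")])
  classes <- sort(unique(ann$class))
  N <- length(unique(universe))
  nFg <- length(unique(foreground))
  rows <- lapply(classes, function(cl) {
    inClass <- unique(ann$gene_id[ann$class == cl])
    K <- length(inClass)
    k <- length(intersect(inClass, foreground))
    data.frame(class_label = cl, n_class_fg = k, n_fg = nFg,
               n_class_bg = K, n_universe = N,
               p_enriched = hypergeometricTail(N, K, nFg, k),
               p_depleted = hypergeometricTail(N, K, nFg, k, lower = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$adj_p_enriched <- bhAdjust(out$p_enriched)
  out$adj_p_depleted <- bhAdjust(out$p_depleted)
  out$direction <- ifelse(out$p_enriched <= out$p_depleted,
                          "enriched", "depleted")
  out
}

#' Overlap between duplicated and differentially expressed genes
#'
#' Fraction of duplicated genes that are DE, with the upper-tail
#' hypergeometric probability of an overlap at least that large when DE
#' labels are drawn at random from the universe (which should be the gene
#' set surviving the low-abundance exclusion).
#'
#' @param duplicated,de,universe character vectors of gene ids; both sets
#'   must be subsets of the universe.
#' @return list(fraction, p_value, n_overlap, n_duplicated, n_de,
#'   n_universe).
#' @export
dupDeOverlapTest <- function(duplicated, de, universe) {
  .assert(length(duplicated) > 0, "empty duplicated gene set")
  .assert(all(duplicated %in% universe) && all(de %in% universe),
          "sets must be subsets of the universe")
  duplicated <- unique(duplicated); de <- unique(de)
  ov <- length(intersect(duplicated, de))
  list(fraction = ov / length(duplicated),
       p_value = hypergeometricTail(length(unique(universe)), length(de),
                                    length(duplicated), ov),
       n_overlap = ov, n_duplicated = length(duplicated),
       n_de = length(de), n_universe = length(unique(universe)))
}

#' Fraction of clusters containing both up- and down-regulated genes
#'
#' @param clusters list of character vectors (gene ids per cluster).
#' @param direction named character vector gene id -> "up"/"down"/"none".
#' @return Fraction of clusters with at least one up AND one down member.
#' @export
mixedDirectionFraction <- function(clusters, direction) {
  .assert(length(clusters) > 0, "no clusters")
  genes <- unlist(clusters)
  .assert(all(genes %in% names(direction)),
          "missing direction for some cluster genes")
  mean(vapply(clusters, function(g) {
    d <- direction[g]
    any(d == "up") && any(d == "down")
  }, TRUE))
}

#' Monte-Carlo randomization null for mixed-direction clusters
#'
#' Each replicate draws \code{nGenes} labels without replacement from the
#' universe label multiset, partitions them into clusters of the given
#' sizes, and records the fraction of clusters containing both an up- and a
#' down-regulated gene. Reports the null mean and sample SD across
#' replicates and, when an observed fraction is supplied, the empirical
#' upper-tail p-value with the (r+1)/(n+1) convention (never exactly zero).
#'
#' @param universeLabels character vector of "up"/"down"/"none" labels for
#'   the complete gene dataset (size N).
#' @param nGenes number of genes drawn per replicate (must equal
#'   \code{sum(clusterSizes)}).
#' @param clusterSizes integer vector of cluster sizes.
#' @param nReps number of replicates (default 1000).
#' @param seed integer seed.
#' @param observed optional observed mixed-direction fraction.
#' @return list: observed_fraction, null_mean, null_sd, n_reps,
#'   empirical_p, seed.
#' @export
randomizationNull <- function(universeLabels, nGenes, clusterSizes,
                              nReps = 1000L, seed = 1L, observed = NULL) {
  .assert(sum(clusterSizes) == nGenes, "cluster sizes must sum to nGenes")
  .assert(nGenes <= length(universeLabels),
          "cannot draw more genes than the universe holds")
  .assert(nReps >= 1L, "nReps must be >= 1")
  set.seed(seed)
  cl <- rep.int(seq_along(clusterSizes), clusterSizes)
  nC <- length(clusterSizes)
  isUp <- universeLabels == "up"
  isDown <- universeLabels == "down"
  fracs <- vapply(seq_len(nReps), function(r) {
    idx <- sample.int(length(universeLabels), nGenes)
    up <- tabulate(cl[isUp[idx]], nbins = nC) > 0L
    dn <- tabulate(cl[isDown[idx]], nbins = nC) > 0L
    mean(up & dn)
  }, 0)
  list(observed_fraction = if (is.null(observed)) NA_real_ else observed,
       null_mean = mean(fracs),
       null_sd = stats::sd(fracs),
       n_reps = nReps,
       empirical_p = if (is.null(observed)) NA_real_ else
         (sum(fracs >= observed) + 1) / (nReps + 1),
       seed = seed)
}

#' Analytic expectation of the mixed-direction cluster fraction
#'
#' Closed-form oracle for \code{\link{randomizationNull}}: for a cluster of
#' size k filled by simple random sampling from a universe with
#' \code{nUp} up and \code{nDown} down labels,
#' \deqn{P(\mathrm{both}) = 1 - \frac{C(N-n_{up},k)}{C(N,k)}
#'   - \frac{C(N-n_{down},k)}{C(N,k)}
#'   + \frac{C(N-n_{up}-n_{down},k)}{C(N,k)},}
#' and the expected fraction is the mean over clusters.
#'
#' @param N universe size.
#' @param nUp,nDown numbers of up/down labels in the universe.
#' @param clusterSizes integer vector of cluster sizes.
#' @return Expected mixed-direction fraction.
#' @export
analyticMixedExpectation <- function(N, nUp, nDown, clusterSizes) {
  .assert(nUp + nDown <= N, "more labels than universe items")
  .assert(all(clusterSizes <= N), "cluster size exceeds universe")
  lratio <- function(M, k) {
    ifelse(M >= k, lchoose(M, k) - lchoose(N, k), -Inf)
  }
  p <- vapply(clusterSizes, function(k) {
    1 - exp(lratio(N - nUp, k)) - exp(lratio(N - nDown, k)) +
      exp(lratio(N - nUp - nDown, k))
  }, 0)
  mean(p)
}
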