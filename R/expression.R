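# TPM computation, low-count filtering, negative-binomial differential
# expression, and multi-caller consensus.

#' Build a count experiment
#'
#' Wraps a per-ORF count matrix into a \code{SummarizedExperiment} with the
#' sample condition in \code{colData} and the ORF length in \code{rowData},
#' validating the two-condition design.
#'
#' @param counts non-negative integer matrix, ORFs x samples (named).
#' @param condition character/factor of length ncol(counts) with exactly two
#'   levels and at least two samples per level.
#' @param lengths named numeric vector of ORF lengths (nt), positive.
#' @return A \code{SummarizedExperiment}.
#' @export
countExperiment <- function(counts, condition, lengths) {
  .assert(is.matrix(counts) && !is.null(rownames(counts)),
          "counts must be a matrix with ORF row names")
  .assert(all(counts >= 0), "counts must be non-negative")
  condition <- as.character(condition)
  .assert(length(condition) == ncol(counts), "one condition per sample")
  tab <- table(condition)
  .assert(length(tab) == 2L && all(tab >= 2L),
          "two conditions with >=2 samples each are required")
  len <- lengths[rownames(counts)]
  .assert(!any(is.na(len)) && all(len > 0),
          "positive lengths are required for all ORFs")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(condition = condition,
                                   row.names = colnames(counts)),
    rowData = S4Vectors::DataFrame(length = as.numeric(len)))
}

.counts <- function(se) SummarizedExperiment::assay(se, "counts")
.condition <- function(se) SummarizedExperiment::colData(se)$condition
.lengths <- function(se) {
  stats::setNames(SummarizedExperiment::rowData(se)$length, rownames(se))
}

#' Transcripts-per-million normalization
#'
#' Per sample, \code{rate_i = count_i / length_i} and
#' \code{TPM_i = 1e6 * rate_i / sum(rate)}; columns sum to one million.
#'
#' @param se a \code{SummarizedExperiment} from \code{\link{countExperiment}},
#'   or a count matrix (then \code{lengths} is required).
#' @param lengths named lengths when \code{se} is a plain matrix.
#' @return Numeric TPM matrix with the dimensions of the counts.
#' @examples
#' m <- matrix(c(10, 10, 10, 10), 2, 2,
#'             dimnames = list(c("a", "b"), c("s1", "s2")))
#' computeTPM(m, lengths = c(a = 100, b = 200))
#' @export
computeTPM <- function(se, lengths = NULL) {
  if (methods::is(se, "SummarizedExperiment")) {
    counts <- .counts(se); lengths <- .lengths(se)
  } else counts <- se
  .assert(!is.null(lengths) && all(rownames(counts) %in% names(lengths)),
          "lengths available for all ORFs are required")
  len <- lengths[rownames(counts)]
  .assert(all(len > 0), "zero-length sequence")
  rate <- counts / len
  tot <- colSums(rate)
  .assert(all(tot > 0), "all-zero sample: TPM normalization undefined")
  sweep(rate, 2, tot, "/") * 1e6
}

#' Low-expression filter
#'
#' Removes ORFs whose 75th percentile of counts across all samples is below
#' \code{threshold} reads. Percentiles use linear interpolation between
#' order statistics (quantile type 7).
#'
#' @param se \code{SummarizedExperiment} or count matrix.
#' @param quantile percentile used (default 0.75).
#' @param threshold minimum count at that percentile (default 10; an ORF is
#'   removed iff the percentile is strictly below it).
#' @return Character vector of retained ORF ids.
#' @export
lowExpressionFilter <- function(se, quantile = 0.75, threshold = 10) {
  counts <- if (methods::is(se, "SummarizedExperiment")) .counts(se) else se
  .assert(ncol(counts) >= 1, "at least one sample is required")
  q <- apply(counts, 1, stats::quantile, probs = quantile, names = FALSE,
             type = 7)
  rownames(counts)[q >= threshold]
}

## median-of-ratios size factors with column-sum fallback
.sizeFactors <- function(counts) {
  logg <- rowMeans(log(counts))
  use <- is.finite(logg)
  if (sum(use) >= 10) {
    sf <- apply(counts[use, , drop = FALSE], 2, function(cnt)
      exp(stats::median(log(cnt) - logg[use])))
  } else {
    sf <- colSums(counts)
    sf <- sf / exp(mean(log(sf)))
  }
  sf
}

#' Negative-binomial differential-expression test
#'
#' Per ORF, a likelihood-ratio test of the condition effect in a
#' negative-binomial log-linear model with a library-size offset
#' (median-of-ratios size factors). Dispersion is estimated per ORF by the
#' method of moments on normalized counts and shrunk toward the
#' across-ORF median (prior weight 10 vs residual df), then treated as
#' fixed in the two GLM fits. The deviance difference is given a
#' Bartlett-style finite-sample correction, \code{LRT * (n-2)/(n-1)}, and
#' referred to the chi-square distribution with 1 df; without the
#' correction the asymptotic reference is visibly liberal at 3+3
#' replicates.
#'
#' @param se \code{SummarizedExperiment} (apply
#'   \code{\link{lowExpressionFilter}} first) or count matrix.
#' @param condition required when \code{se} is a plain matrix.
#' @return data.frame: orf_id, log2fc (log2 ratio of shrunken normalized
#'   condition means, condition 2 over condition 1), p_value.
#' @export
nbDeTest <- function(se, condition = NULL) {
  if (methods::is(se, "SummarizedExperiment")) {
    counts <- .counts(se); condition <- .condition(se)
  } else counts <- se
  condition <- as.character(condition)
  lev <- unique(condition)
  .assert(length(lev) == 2L && all(table(condition) >= 2L),
          "two conditions with >=2 replicates each are required")
  n <- ncol(counts)
  sf <- .sizeFactors(counts)
  z <- sweep(counts, 2, sf, "/")
  grp <- condition == lev[2]
  m1 <- rowMeans(z[, !grp, drop = FALSE]); m2 <- rowMeans(z[, grp, drop = FALSE])
  v1 <- apply(z[, !grp, drop = FALSE], 1, stats::var)
  v2 <- apply(z[, grp, drop = FALSE], 1, stats::var)
  corr1 <- mean(1 / sf[!grp]); corr2 <- mean(1 / sf[grp])
  dg <- pmax((v1 - m1 * corr1) + (v2 - m2 * corr2), 0) / (m1^2 + m2^2)
  dg[!is.finite(dg)] <- 0
  common <- stats::median(dg[m1 + m2 > 0])
  if (!is.finite(common)) common <- 0.1
  w0 <- 10; dfg <- n - 2L
  duse <- pmax((w0 * common + dfg * dg) / (w0 + dfg), 1e-8)
  cf <- factor(condition, levels = lev)
  off <- log(sf)
  pvals <- numeric(nrow(counts)); lfc <- numeric(nrow(counts))
  for (g in seq_len(nrow(counts))) {
    y <- counts[g, ]
    lfc[g] <- log2((m2[g] + 0.5) / (m1[g] + 0.5))
    if (all(y == y[1]) && length(unique(sf)) == 1L) {
      pvals[g] <- 1
      next
    }
    fam <- MASS::negative.binomial(theta = 1 / duse[g])
    f0 <- try(stats::glm(y ~ 1 + offset(off), family = fam), silent = TRUE)
    f1 <- try(stats::glm(y ~ cf + offset(off), family = fam), silent = TRUE)
    if (inherits(f0, "try-error") || inherits(f1, "try-error")) {
      pvals[g] <- NA_real_
      next
    }
    lrt <- max(f0$deviance - f1$deviance, 0)
    pvals[g] <- stats::pchisq(lrt * (n - 2) / (n - 1), df = 1,
                              lower.tail = FALSE)
  }
  data.frame(orf_id = rownames(counts), log2fc = lfc, p_value = pvals,
             stringsAsFactors = FALSE)
}

#' Pseudocount-shrunken fold change
#'
#' \code{(mean2 + pseudocount) / (mean1 + pseudocount)}: a transparent,
#' bounded stand-in for model-based posterior fold changes; monotone in
#' \code{mean2} and equal to 1 when both means are zero.
#'
#' @param mean1,mean2 condition means (TPM), >= 0. Vectorized.
#' @param pseudocount positive shrinkage constant (default 1 TPM).
#' @return Numeric fold-change ratio(s).
#' @examples
#' shrunkenFoldChange(10, 90, 10)  # 5
#' @export
shrunkenFoldChange <- function(mean1, mean2, pseudocount = 1) {
  .assert(all(pseudocount > 0), "pseudocount must be > 0")
  .assert(all(mean1 >= 0) && all(mean2 >= 0), "means must be >= 0")
  (mean2 + pseudocount) / (mean1 + pseudocount)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (monotone, capped at 1,
#' order-preserving with the input indexing).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in input order.
#' @export
bhAdjust <- function(p) {
  .assert(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential-expression call from significance and fold change
#'
#' An ORF is DE iff it is significant (adjusted p strictly below
#' \code{alpha}, or posterior probability strictly above 0.95 in
#' \code{posteriorMode}) AND its fold change is strictly outside
#' [\code{fcLow}, \code{fcHigh}] (i.e. FC < 0.5 or FC > 2 at the defaults).
#' Direction is "up" iff FC > fcHigh, "down" iff FC < fcLow.
#'
#' @param x data.frame with column \code{fc} and either \code{adj_p} or
#'   \code{posterior}.
#' @param alpha significance level on adjusted p (default 0.05).
#' @param fcLow,fcHigh fold-change thresholds (default 0.5 and 2, strict).
#' @param posteriorMode use \code{posterior > posteriorCut} instead of
#'   \code{adj_p < alpha}.
#' @param posteriorCut posterior-probability cut (default 0.95, strict).
#' @return \code{x} with added logical \code{de_flag} and character
#'   \code{direction} ("up"/"down"/"none") columns.
#' @export
callDE <- function(x, alpha = 0.05, fcLow = 0.5, fcHigh = 2.0,
                   posteriorMode = FALSE, posteriorCut = 0.95) {
  .assert("fc" %in% names(x), "missing field 'fc'")
  if (posteriorMode) {
    .assert("posterior" %in% names(x), "missing field 'posterior'")
    sig <- x$posterior > posteriorCut
  } else {
    .assert("adj_p" %in% names(x), "missing field 'adj_p'")
    sig <- x$adj_p < alpha
  }
  fcOut <- x$fc < fcLow | x$fc > fcHigh
  x$de_flag <- !is.na(sig) & sig & fcOut
  x$direction <- ifelse(x$de_flag & x$fc > fcHigh, "up",
                        ifelse(x$de_flag & x$fc < fcLow, "down", "none"))
  x
}

#' Full expression summary for a two-condition experiment
#'
#' Convenience composition: low-count filter, TPM, NB test, shrunken fold
#' change on TPM condition means, BH adjustment and DE calls.
#'
#' @param se \code{SummarizedExperiment} from \code{\link{countExperiment}}.
#' @param quantile,threshold low-count filter settings.
#' @param alpha,fcLow,fcHigh DE-call settings.
#' @param pseudocount shrinkage pseudocount in TPM units.
#' @return data.frame with one ExpressionSummary row per retained ORF:
#'   orf_id, mean_tpm_cond1, mean_tpm_cond2, raw_fc, shrunken_fc (used as
#'   \code{fc} for calling), log2fc, p_value, adj_p, de_flag, direction.
#' @export
summarizeExpression <- function(se, quantile = 0.75, threshold = 10,
                                alpha = 0.05, fcLow = 0.5, fcHigh = 2.0,
                                pseudocount = 1) {
  keep <- lowExpressionFilter(se, quantile, threshold)
  se <- se[keep, ]
  tpm <- computeTPM(se)
  cond <- .condition(se)
  lev <- unique(cond)
  m1 <- rowMeans(tpm[, cond == lev[1], drop = FALSE])
  m2 <- rowMeans(tpm[, cond == lev[2], drop = FALSE])
  de <- nbDeTest(se)
  out <- data.frame(orf_id = de$orf_id,
                    mean_tpm_cond1 = m1, mean_tpm_cond2 = m2,
                    raw_fc = ifelse(m1 > 0, m2 / m1, NA_real_),
                    fc = shrunkenFoldChange(m1, m2, pseudocount),
                    log2fc = de$log2fc, p_value = de$p_value,
                    adj_p = bhAdjust(de$p_value),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- callDE(out, alpha = alpha, fcLow = fcLow, fcHigh = fcHigh)
  names(out)[names(out) == "fc"] <- "shrunken_fc"
  out
}

#' Reduce ORF-level DE calls to gene level
#'
#' A gene is DE iff any of its isoforms is DE; its direction is taken from
#' the isoform with the smallest adjusted p-value.
#'
#' @param summary data.frame from \code{\link{summarizeExpression}}.
#' @param orf2gene named character vector ORF id -> gene id.
#' @return data.frame: gene_id, de_flag, direction.
#' @export
geneLevelDE <- function(summary, orf2gene) {
  gene <- orf2gene[summary$orf_id]
  .assert(!any(is.na(gene)), "every ORF must map to a gene")
  rows <- lapply(split(seq_len(nrow(summary)), gene), function(ix) {
    sub <- summary[ix, ]
    flag <- any(sub$de_flag)
    dir <- if (flag) sub$direction[order(sub$adj_p)][
      which(sub$direction[order(sub$adj_p)] != "none")[1]] else "none"
    data.frame(de_flag = flag, direction = dir, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  data.frame(gene_id = rownames(tab), tab, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Consensus across multiple DE callers
#'
#' @param calls named list (>= 2) of data.frames, each with columns
#'   \code{orf_id}, \code{de_flag} and optionally \code{direction}. ORF
#'   universes are outer-joined; missing entries are marked \code{NA}.
#' @return list with \code{table} (per-ORF flag matrix plus a
#'   \code{direction_conflict} column among agreeing callers),
#'   \code{n_all} (flagged by every caller), \code{n_any},
#'   \code{n_pairwise} (matrix), and \code{callers}.
#' @export
consensusDE <- function(calls) {
  .assert(is.list(calls) && length(calls) >= 2L, "at least two callers")
  .assert(!is.null(names(calls)) && !anyDuplicated(names(calls)),
          "callers must be uniquely named")
  ids <- sort(unique(unlist(lapply(calls, function(x) x$orf_id))))
  flags <- sapply(calls, function(x) {
    f <- x$de_flag[match(ids, x$orf_id)]
    f
  })
  rownames(flags) <- ids
  dirs <- sapply(calls, function(x) {
    if ("direction" %in% names(x)) x$direction[match(ids, x$orf_id)]
    else rep(NA_character_, length(ids))
  })
  allFlag <- apply(flags, 1, function(f) all(!is.na(f) & f))
  anyFlag <- apply(flags, 1, function(f) any(!is.na(f) & f))
  conflict <- vapply(seq_along(ids), function(i) {
    d <- dirs[i, !is.na(flags[i, ]) & flags[i, ]]
    d <- d[!is.na(d) & d != "none"]
    length(unique(d)) > 1L
  }, TRUE)
  k <- length(calls)
  pw <- matrix(0L, k, k, dimnames = list(names(calls), names(calls)))
  for (i in seq_len(k)) for (j in seq_len(k))
    pw[i, j] <- sum(flags[, i] & flags[, j], na.rm = TRUE)
  list(table = data.frame(orf_id = ids, flags,
                          flagged_by_all = allFlag,
                          direction_conflict = conflict,
                          stringsAsFactors = FALSE, row.names = NULL),
       n_all = sum(allFlag), n_any = sum(anyFlag),
       n_pairwise = pw, callers = names(calls))
}

#' Read an external caller's output table
#'
#' Ingests a TSV with columns \code{orf_id}, \code{stat_type} ("adj_p" or
#' "posterior"), \code{value} and \code{fc}, and applies
#' \code{\link{callDE}} in the matching mode.
#'
#' @param path TSV file path.
#' @param ... passed to \code{\link{callDE}}.
#' @return data.frame with de_flag/direction columns.
#' @export
readCallerTable <- function(path, ...) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  .assert(all(c("orf_id", "stat_type", "value", "fc") %in% names(x)),
          "caller table needs orf_id, stat_type, value, fc columns")
  mode <- unique(x$stat_type)
  .assert(length(mode) == 1L && mode %in% c("adj_p", "posterior"),
          "stat_type must be uniformly 'adj_p' or 'posterior'")
  if (mode == "adj_p") {
    x$adj_p <- x$value
    callDE(x, posteriorMode = FALSE, ...)
  } else {
    x$posterior <- x$value
    callDE(x, posteriorMode = TRUE, ...)
  }
}
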