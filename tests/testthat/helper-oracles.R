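# Independent brute-force oracles used to verify the implementation paths.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

randomDna <- function(n) paste(sample(c("A","C","G","T"), n, TRUE), collapse = "")
randomAa <- function(n) paste(sample(AA20, n, TRUE), collapse = "")

substituteAt <- function(x, pos, alphabet) {
  res <- strsplit(x, "")[[1]]
  for (p in pos) res[p] <- sample(setdiff(alphabet, res[p]), 1)
  paste(res, collapse = "")
}

## O(n*m) dynamic-programming longest common substring
lcsOracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  prev <- integer(length(bv))
  best <- 0L
  for (i in seq_along(av)) {
    cur <- integer(length(bv))
    match <- av[i] == bv
    cur[match] <- c(1L, prev[-length(prev)] + 1L)[match]
    best <- max(best, cur)
    prev <- cur
  }
  best
}

## Gene partition by transitive closure over all-pairs LCS >= minShared
collapseOracle <- function(seqs, minShared) {
  n <- length(seqs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    adj[i, j] <- i == j || lcsOracle(seqs[i], seqs[j]) >= minShared
  ## Warshall transitive closure
  for (k in seq_len(n)) adj <- adj | (adj[, k] %o% adj[k, ])
  comp <- integer(n)
  lab <- 0L
  for (i in seq_len(n)) if (comp[i] == 0L) {
    lab <- lab + 1L
    comp[adj[i, ]] <- lab
  }
  comp
}

## Contamination decision by diagonal window scan (indel-free pairs): TRUE
## iff some contiguous window longer than minLen on some diagonal has
## identity > minId.
contamOracle <- function(orf, db, minLen = 100, minId = 0.90) {
  ov <- strsplit(orf, "")[[1]]
  for (s in db) {
    sv <- strsplit(s, "")[[1]]
    for (off in seq(-(length(sv) - 1L), length(ov) - 1L)) {
      i <- max(1L, 1L + off); j <- max(1L, 1L - off)
      len <- min(length(ov) - i, length(sv) - j) + 1L
      if (len <= minLen) next
      eq <- ov[i:(i + len - 1L)] == sv[j:(j + len - 1L)]
      cs <- c(0L, cumsum(eq))
      for (w in (minLen + 1L):len) {
        matches <- cs[(w + 1L):(len + 1L)] - cs[1L:(len - w + 1L)]
        if (any(matches / w > minId)) return(TRUE)
      }
    }
  }
  FALSE
}

## Enumerate all non-trivial bipartitions of a phylo tree by edge traversal
## of the edge matrix, with the support label of the defining edge.
bipartitionOracle <- function(tree) {
  nt <- length(tree$tip.label)
  below <- function(node) {
    if (node <= nt) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, below))
  }
  internal <- setdiff(unique(tree$edge[, 1]), nt + 1L)  # exclude basal node
  sup <- suppressWarnings(as.numeric(tree$node.label))
  lapply(internal, function(nd) {
    list(tips = sort(tree$tip.label[below(nd)]),
         support = sup[nd - nt])
  })
}

exclusiveOracle <- function(tree, focal, minSupport = 50) {
  tips <- tree$tip.label
  if (length(setdiff(tips, focal)) == 1L)
    return(list(is_exclusive = TRUE, support = NA_real_))
  focal <- sort(focal)
  for (bp in bipartitionOracle(tree)) {
    side <- bp$tips
    other <- sort(setdiff(tips, side))
    if (identical(side, focal) || identical(other, focal)) {
      sup <- bp$support
      return(list(is_exclusive = !is.na(sup) && sup > minSupport,
                  support = sup))
    }
  }
  list(is_exclusive = FALSE, support = NA_real_)
}

## Exact hypergeometric upper tail by integer choose-sums (exact in double
## arithmetic for N <= 30 since every term is <= C(N, n) <= C(30, 15)).
hyperOracle <- function(N, K, n, k, lower = FALSE) {
  total <- choose(N, n)
  ks <- if (lower) 0:k else k:min(n, K)
  sum(choose(K, ks) * choose(N - K, n - ks)) / total
}

## Hand-executed BH step-up
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

## Position-by-position motif scan; sets = list of allowed-character vectors
motifOracle <- function(protein, sets) {
  pv <- strsplit(protein, "")[[1]]
  w <- length(sets)
  hits <- integer(0)
  if (length(pv) >= w) {
    for (s in 1:(length(pv) - w + 1L)) {
      ok <- TRUE
      for (j in seq_len(w)) if (!(pv[s + j - 1L] %in% sets[[j]])) {
        ok <- FALSE; break
      }
      if (ok) hits <- c(hits, s)
    }
  }
  hits
}
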