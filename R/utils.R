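# Internal utilities shared across modules.

AA_ALPHABET20 <- c("A","R","N","D","C","Q","E","G","H","I",
                   "L","K","M","F","P","S","T","W","Y","V")

#' @keywords internal
#' @noRd
.assert <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

## Iterative union-find with path halving; parents is an integer vector.
.ufNew <- function(n) seq_len(n)

.ufFind <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

.ufUnion <- function(parent, i, j) {
  ri <- .ufFind(parent, i)
  rj <- .ufFind(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}

## Final component labels (1-based, in order of first appearance).
.ufComponents <- function(parent) {
  roots <- vapply(seq_along(parent), function(i) .ufFind(parent, i), 1L)
  match(roots, unique(roots))
}

## All k-mers of one string (character vector; may contain duplicates).
.kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

## Pairs of sequence indices sharing at least minShared distinct k-mers.
## seqs: character vector. Returns two-column integer matrix (i < j).
.sharedKmerPairs <- function(seqs, k, minShared = 1L) {
  idx <- rep.int(seq_along(seqs), pmax(nchar(seqs) - k + 1L, 0L))
  km <- unlist(lapply(seqs, .kmers, k = k), use.names = FALSE)
  if (length(km) == 0L) return(matrix(integer(0), ncol = 2L))
  ## distinct (kmer, seq) pairs only
  dup <- duplicated(paste0(km, "\r", idx))
  km <- km[!dup]; idx <- idx[!dup]
  ## keep only k-mers seen in >1 sequence
  tab <- table(km)
  keep <- km %in% names(tab)[tab > 1L]
  km <- km[keep]; idx <- idx[keep]
  if (length(km) == 0L) return(matrix(integer(0), ncol = 2L))
  buckets <- split(idx, km)
  pairs <- lapply(buckets, function(b) {
    b <- sort.int(b)
    if (length(b) < 2L) return(NULL)
    cb <- utils::combn(b, 2L)
    t(cb)
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) return(matrix(integer(0), ncol = 2L))
  key <- paste0(pairs[, 1L], "_", pairs[, 2L])
  cnt <- table(key)
  sel <- names(cnt)[cnt >= minShared]
  if (length(sel) == 0L) return(matrix(integer(0), ncol = 2L))
  out <- do.call(rbind, strsplit(sel, "_", fixed = TRUE))
  storage.mode(out) <- "integer"
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}

## Derive a stage-specific seed from a master seed, keeping it < 2^31.
.deriveSeed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

.validAaString <- function(x) {
  all(strsplit(x, "", fixed = TRUE)[[1]] %in% c(AA_ALPHABET20, "X"))
}
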