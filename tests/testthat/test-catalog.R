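test_that("longestSharedStretch matches the dynamic-programming oracle", {
  set.seed(101)
  a <- randomDna(80)
  expect_identical(longestSharedStretch(a, a), 80L)
  ## constructed single 50-nt shared block on otherwise disjoint alphabets
  block <- paste(sample(c("A", "C"), 50, TRUE), collapse = "")
  x <- paste0(strrep("G", 40), block, strrep("G", 40))
  y <- paste0(strrep("T", 35), block, strrep("T", 45))
  expect_identical(longestSharedStretch(x, y), lcsOracle(x, y))
  expect_identical(lcsOracle(x, y), 50L)
  ## no common 2-mer
  p <- "ACACACAC"; q <- "GTGTGTGT"
  expect_identical(longestSharedStretch(p, q), lcsOracle(p, q))
  expect_lte(longestSharedStretch(p, q), 1L)
  ## random pairs
  for (i in 1:15) {
    u <- randomDna(sample(30:120, 1)); v <- randomDna(sample(30:120, 1))
    expect_identical(longestSharedStretch(u, v), lcsOracle(u, v))
  }
  expect_error(longestSharedStretch("", "ACGT"), "empty")
})

test_that("isoform collapsing honors the 50-nt boundary and transitivity", {
  set.seed(102)
  block50 <- randomDna(50); block49 <- randomDna(49)
  orfs <- c(A = paste0(randomDna(60), block50, block49),
            B = paste0(block50, randomDna(70)),
            C = paste0(randomDna(70), block49))
  cat1 <- collapseOrfs(orfs, minShared = 50)
  o2g <- orfToGene(cat1)
  expect_identical(unname(o2g["A"]), unname(o2g["B"]))  # 50 shared
  expect_false(o2g["A"] == o2g["C"])                    # only 49 shared

  ## transitivity A~B, B~C, A and C unrelated
  b1 <- randomDna(55); b2 <- randomDna(55)
  orfs2 <- c(A = paste0(randomDna(40), b1),
             B = paste0(b1, randomDna(20), b2),
             C = paste0(b2, randomDna(40)))
  cat2 <- collapseOrfs(orfs2)
  expect_identical(length(unique(orfToGene(cat2))), 1L)

  ## unrelated singletons stay singletons
  singles <- stats::setNames(vapply(1:8, function(i) randomDna(120), ""),
                             paste0("s", 1:8))
  expect_identical(length(collapseOrfs(singles)), 8L)
  expect_error(collapseOrfs(c(a = "ACGT", a = "ACGT")), "duplicate")
})

test_that("collapsing equals the all-pairs closure oracle on random ORFs", {
  set.seed(103)
  for (trial in 1:3) {
    ## mixture: some share planted blocks, some are unrelated
    blocks <- vapply(1:6, function(i) randomDna(55), "")
    seqs <- vapply(1:30, function(i) {
      if (i %% 3 == 0) paste0(randomDna(30), sample(blocks, 1), randomDna(30))
      else randomDna(sample(80:140, 1))
    }, "")
    names(seqs) <- paste0("o", seq_along(seqs))
    got <- orfToGene(collapseOrfs(seqs, minShared = 50))[names(seqs)]
    want <- collapseOracle(unname(seqs), 50)
    ## same partition up to labeling
    expect_identical(as.integer(factor(got, levels = unique(got))),
                     as.integer(factor(want, levels = unique(want))))
  }
})

test_that("lowering minShared never increases the gene count", {
  set.seed(104)
  pool <- vapply(1:3, function(i) randomDna(45), "")
  seqs <- stats::setNames(vapply(1:20, function(i) {
    paste0(randomDna(40), sample(c("", pool), 1), randomDna(40))
  }, ""), paste0("o", 1:20))
  counts <- vapply(c(30L, 40L, 50L, 60L),
                   function(ms) length(collapseOrfs(seqs, ms)), 1L)
  expect_true(all(diff(counts) >= 0))
})

test_that("representative is the longest isoform with lexicographic ties", {
  set.seed(105)
  core <- randomDna(60)
  orfs <- c(zz = paste0(core, randomDna(10)),
            aa = paste0(core, randomDna(10)),
            mm = core)
  tab <- geneTable(collapseOrfs(orfs))
  expect_identical(tab$representative, "aa")  # ties at 70 nt: aa < zz
})

test_that("prokaryotic screening applies strict >100 bp / >90% rules", {
  set.seed(106)
  dbseq <- randomDna(400)
  ## 120-bp block with 8 interior substitutions: identity 112/120 = 93.3%
  block <- substr(dbseq, 101, 220)
  blockMut <- substituteAt(block, sample(10:110, 8), c("A", "C", "G", "T"))
  orf1 <- paste0(randomDna(60), blockMut, randomDna(60))
  hit1 <- screenProkaryoticSimilarity(orf1, c(db1 = dbseq))
  expect_identical(hit1$decision, "discard")
  expect_gt(hit1$region_identity, 0.90)
  expect_gt(hit1$region_length, 100)

  ## exactly 100 bp at 100% identity: kept (length not > 100)
  db2 <- substr(dbseq, 1, 100)
  orf2 <- paste0(strrep("A", 50), db2, strrep("A", 50))
  ## guard flanks against accidental extension of the alignment
  hit2 <- screenProkaryoticSimilarity(orf2, c(db2 = db2))
  expect_identical(hit2$decision, "keep")
  expect_lte(hit2$region_length, 100)

  ## nothing in common: keep with no subject requirement violated
  orf3 <- strrep("AC", 100)
  hit3 <- screenProkaryoticSimilarity(orf3, c(db1 = strrep("GT", 100)))
  expect_identical(hit3$decision, "keep")
})

test_that("screening decisions match the window oracle and ignore db order", {
  set.seed(107)
  db <- vapply(1:3, function(i) randomDna(300), "")
  names(db) <- paste0("p", 1:3)
  orfs <- lapply(1:8, function(i) {
    if (i <= 4) {
      src <- substr(db[[sample(3, 1)]], 50, 50 + sample(110:160, 1))
      nmut <- round(nchar(src) * sample(c(0.04, 0.12), 1))
      paste0(randomDna(40),
             substituteAt(src, sample(nchar(src), nmut), c("A","C","G","T")),
             randomDna(40))
    } else randomDna(250)
  })
  for (i in seq_along(orfs)) {
    got <- screenProkaryoticSimilarity(orfs[[i]], db)$decision == "discard"
    want <- contamOracle(orfs[[i]], db)
    expect_identical(got, want)
    gotRev <- screenProkaryoticSimilarity(orfs[[i]], rev(db))$decision
    expect_identical(gotRev == "discard", want)
  }
})

test_that("abundance/intron evidence classifies prokaryote-affiliated genes", {
  expect_identical(classifyOriginByAbundance(TRUE, 3986, TRUE), "eukaryotic")
  expect_identical(classifyOriginByAbundance(TRUE, 3986, FALSE), "eukaryotic")
  expect_identical(classifyOriginByAbundance(TRUE, 8, FALSE), "contaminant")
  expect_identical(classifyOriginByAbundance(TRUE, 100, FALSE), "uncertain")
  expect_identical(classifyOriginByAbundance(FALSE, 0, FALSE), "eukaryotic")
  ## boundaries: 10 TPM is contaminant-consistent, 600 exactly is not "above"
  expect_identical(classifyOriginByAbundance(TRUE, 10, FALSE), "contaminant")
  expect_identical(classifyOriginByAbundance(TRUE, 600, FALSE), "uncertain")
  expect_error(classifyOriginByAbundance(TRUE, -1, FALSE), "negative")
})
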