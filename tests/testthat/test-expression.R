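makeSe <- function(counts, condition, lengths) {
  countExperiment(counts, condition, lengths)
}

test_that("TPM normalization matches the hand formula and sums to 1e6", {
  m <- matrix(c(5, 7), 1, 2, dimnames = list("a", c("s1", "s2")))
  expect_equal(unname(computeTPM(m, lengths = c(a = 300))[1, ]), c(1e6, 1e6))

  m2 <- matrix(c(10, 10, 10, 10), 2, 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  tpm <- computeTPM(m2, lengths = c(a = 100, b = 200))
  expect_equal(unname(tpm[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  expect_equal(unname(colSums(tpm)), c(1e6, 1e6), tolerance = 1e-6)

  ## permutation invariance
  m3 <- m2[c("b", "a"), ]
  tpm3 <- computeTPM(m3, lengths = c(a = 100, b = 200))
  expect_equal(tpm3["a", ], tpm["a", ])
  expect_error(computeTPM(matrix(0, 2, 1, dimnames = list(c("a", "b"), "s")),
                          lengths = c(a = 10, b = 10)), "all-zero")
})

test_that("low-expression filter uses the interpolated 75th percentile", {
  cnt <- rbind(a = c(0, 0, 0, 9, 9, 9),
               b = rep(10, 6),
               c = c(0, 0, 0, 0, 0, 1000),
               d = rep(50, 6))
  colnames(cnt) <- paste0("s", 1:6)
  keep <- lowExpressionFilter(cnt)
  expect_setequal(keep, c("b", "d"))   # a: q75 = 9; c: q75 = 0; both removed
})

test_that("shrunken fold change is bounded and matches hand values", {
  expect_equal(shrunkenFoldChange(5, 5), 1)
  expect_equal(shrunkenFoldChange(0, 0), 1)
  expect_equal(shrunkenFoldChange(10, 90, 10), 5)
  expect_true(all(diff(shrunkenFoldChange(10, c(1, 5, 50, 500))) > 0))
  expect_error(shrunkenFoldChange(-1, 2), ">= 0")
})

test_that("BH adjustment reproduces the hand-executed step-up", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.3), 0.3)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(201)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    expect_equal(bhAdjust(p), bhOracle(p), tolerance = 1e-12)
  }
})

test_that("NB test returns null results for flat genes and needs replication", {
  cnt <- matrix(50, 4, 6, dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  cond <- rep(c("c1", "c2"), each = 3)
  res <- nbDeTest(cnt, cond)
  expect_equal(res$log2fc, rep(0, 4))
  expect_true(all(res$p_value > 0.5))
  expect_error(nbDeTest(cnt[, c(1, 4)], c("c1", "c2")), "replicates")
})

test_that("DE calling pins the strict FC and significance boundaries", {
  x <- data.frame(adj_p = c(0.01, 0.01, 0.2, 0.01, 0.049, 0.05),
                  fc = c(2.0, 4, 10, 0.5, 2.1, 2.1))
  out <- callDE(x)
  expect_identical(out$de_flag, c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_identical(out$direction[2], "up")
  expect_identical(out$direction[1], "none")  # fc exactly 2 is not "> 2"
  down <- callDE(data.frame(adj_p = 0.01, fc = 0.49))
  expect_identical(down$direction, "down")
  ## posterior mode: > 0.95 strict
  post <- callDE(data.frame(posterior = c(0.95, 0.96), fc = c(4, 4)),
                 posteriorMode = TRUE)
  expect_identical(post$de_flag, c(FALSE, TRUE))
  expect_error(callDE(data.frame(fc = 1)), "adj_p")
})

test_that("consensus across callers reports intersections and conflicts", {
  mk <- function(ids, flagged, dirs = NULL) {
    data.frame(orf_id = ids, de_flag = ids %in% flagged,
               direction = if (is.null(dirs)) ifelse(ids %in% flagged, "up", "none")
                           else dirs)
  }
  ids <- c("x", "y", "z")
  ## disjoint: intersection 0
  cs <- consensusDE(list(A = mk(ids, "x"), B = mk(ids, "y"), C = mk(ids, "z")))
  expect_identical(cs$n_all, 0L)
  expect_identical(cs$n_any, 3L)
  ## nested: intersection = |A|
  cs2 <- consensusDE(list(A = mk(ids, "x"), B = mk(ids, c("x", "y")),
                          C = mk(ids, c("x", "y", "z"))))
  expect_identical(cs2$n_all, 1L)
  ## worked example {x,y},{y,z},{y}
  cs3 <- consensusDE(list(A = mk(ids, c("x", "y")), B = mk(ids, c("y", "z")),
                          C = mk(ids, "y")))
  expect_identical(cs3$table$orf_id[cs3$table$flagged_by_all], "y")
  expect_identical(cs3$n_any, 3L)
  expect_identical(unname(cs3$n_pairwise["A", "B"]), 1L)
  ## direction conflict flagged, not an error
  cs4 <- consensusDE(list(
    A = mk(ids, "x", c("up", "none", "none")),
    B = mk(ids, "x", c("down", "none", "none"))))
  expect_true(cs4$table$direction_conflict[cs4$table$orf_id == "x"])
})

test_that("gene-level reduction takes any-DE flag and best isoform direction", {
  s <- data.frame(orf_id = c("a1", "a2", "b1"),
                  de_flag = c(TRUE, FALSE, FALSE),
                  direction = c("down", "none", "none"),
                  adj_p = c(0.001, 0.8, 0.9))
  g <- geneLevelDE(s, c(a1 = "gA", a2 = "gA", b1 = "gB"))
  expect_identical(g$de_flag, c(TRUE, FALSE))
  expect_identical(g$direction, c("down", "none"))
})

test_that("external caller tables are ingested in both statistic modes", {
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(orf_id = c("a", "b"), stat_type = "posterior",
                         value = c(0.99, 0.5), fc = c(3, 3)),
              f, sep = "\t", row.names = FALSE, quote = FALSE)
  got <- readCallerTable(f)
  expect_identical(got$de_flag, c(TRUE, FALSE))
  unlink(f)
})
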