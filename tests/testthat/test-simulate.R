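test_that("simulation is deterministic and writes byte-identical artifacts", {
  cfg <- simConfig(nGenes = 40L, nFamilies = 3L, nContaminants = 4L, seed = 11L)
  d1 <- file.path(tempdir(), "sim1"); d2 <- file.path(tempdir(), "sim2")
  simulateDataset(cfg, dir = d1)
  simulateDataset(cfg, dir = d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("DE truth counts follow deFraction and deUpShare", {
  cfg <- simConfig(nGenes = 100L, nFamilies = 5L,
                   familySizes = data.frame(size = 2L, weight = 1),
                   deFraction = 0.2, deUpShare = 0.62, seed = 1L)
  sim <- simulateDataset(cfg)
  truth <- sim@truth
  expect_identical(sum(!is.na(truth$family_of_gene)), 10L)
  de <- truth$de_status[truth$de_status != "none"]
  expect_identical(length(de), 20L)
  expect_true(sum(de == "up") %in% c(12L, 13L))

  simNone <- simulateDataset(simConfig(nGenes = 30L, nFamilies = 2L,
                                       deFraction = 0, seed = 2L))
  expect_true(all(simNone@truth$de_status == "none"))
})

test_that("truth tables are internally consistent", {
  sim <- simulateDataset(simConfig(nGenes = 60L, nFamilies = 5L,
                                   nContaminants = 6L, seed = 4L))
  truth <- sim@truth
  ## every ORF appears exactly once in gene_of_orf
  expect_setequal(names(truth$gene_of_orf), orfIds(sim@orfs))
  expect_false(anyDuplicated(names(truth$gene_of_orf)) > 0)
  ## every family induces >= 2 genes
  famSizes <- table(truth$family_of_gene)
  expect_true(all(famSizes >= 2))
  ## contaminants labeled as such
  cont <- grep("^cont", orfIds(sim@orfs), value = TRUE)
  expect_true(all(truth$origin[cont] == "contaminant"))
  ## isoforms of one gene share the configured exact stretch
  multi <- names(which(table(truth$gene_of_orf[grep("^g", names(truth$gene_of_orf))]) > 1))[1:3]
  for (g in multi) {
    iso <- names(truth$gene_of_orf)[truth$gene_of_orf == g]
    nt <- as.character(ntSeqs(sim@orfs)[iso])
    expect_gte(longestSharedStretch(nt[1], nt[2]),
               sim@config@sharedStretchLen)
  }
})

test_that("family members diverge at the configured protein rate", {
  sim <- simulateDataset(simConfig(nGenes = 40L, nFamilies = 6L,
                                   familySizes = data.frame(size = 2L, weight = 1),
                                   divergencePerCopy = 0.05, seed = 9L))
  truth <- sim@truth
  fams <- split(names(truth$family_of_gene)[!is.na(truth$family_of_gene)],
                truth$family_of_gene[!is.na(truth$family_of_gene)])
  ## two copies each at 0.05 from the ancestor: expected pairwise ~0.0975
  divs <- vapply(fams, function(g) {
    aa <- as.character(aaSeqs(sim@orfs)[paste0(g, ".o1")])
    a <- strsplit(aa[1], "")[[1]]; b <- strsplit(aa[2], "")[[1]]
    mean(a != b)
  }, 0)
  expect_gt(mean(divs), 0.05)
  expect_lt(mean(divs), 0.16)
})

test_that("simulated counts have negative-binomial moments", {
  n <- 10000L
  truth <- stats::setNames(rep("none", n), sprintf("f%05d", seq_len(n)))
  len <- stats::setNames(rep(900, n), names(truth))
  cnt <- simulateCounts(rep(c("c1", "c2"), each = 1) |> rep(3),
                        truth, nbMean = 100, nbDispersion = 0.1,
                        deLog2fcMagnitude = 2, lengths = len, seed = 5L)
  x <- as.numeric(cnt)
  mu <- mean(x)
  expect_lt(abs(mu - 100), 3 * sqrt((100 + 0.1 * 100^2) / length(x)))
  v <- var(x)
  expect_gt(v, 100)                      # clearly over-dispersed
  expect_lt(abs(v - 1100) / 1100, 0.1)   # matches mu + disp*mu^2

  ## Poisson limit as dispersion -> 0
  cntP <- simulateCounts(rep(c("c1", "c2"), 3), truth, nbMean = 100,
                         nbDispersion = 1e-8, deLog2fcMagnitude = 2,
                         lengths = len, seed = 6L)
  xp <- as.numeric(cntP)
  expect_lt(abs(var(xp) - mean(xp)) / mean(xp), 0.05)
})

test_that("null genes show no systematic fold change and DE genes do", {
  n <- 2000L
  truth <- stats::setNames(rep("none", n), sprintf("f%05d", seq_len(n)))
  len <- stats::setNames(rep(900, n), names(truth))
  cond <- rep(c("c1", "c2"), each = 10)
  cnt <- simulateCounts(cond, truth, 100, 0.1, 2, len, seed = 7L)
  ratio <- rowMeans(cnt[, cond == "c2"]) / rowMeans(cnt[, cond == "c1"])
  expect_lt(abs(mean(log2(ratio))), 0.02)

  ## a truly 4-fold gene lands in log2 ratio [1,3] nearly always (3+3)
  tr1 <- c(gene = "up")
  ok <- vapply(1:400, function(s) {
    cc <- simulateCounts(rep(c("c1", "c2"), each = 3), tr1, 100, 0.1, 2,
                         c(gene = 900), seed = s)
    lr <- log2(mean(cc[1, 4:6]) / mean(cc[1, 1:3]))
    lr >= 1 && lr <= 3
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(simConfig(nReplicates = 1L), "nReplicates")
  expect_error(simConfig(deFraction = 1.5), "deFraction")
  expect_error(simConfig(nbDispersion = 0), "nbDispersion")
  expect_error(simConfig(contaminantIdentity = 0.8), "contaminantIdentity")
  expect_error(
    simulateCounts(rep(c("a", "b"), 2), c(g = "none"), 100, 0.1, 2,
                   c(g = 0), seed = 1),
    "zero-length")
})
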