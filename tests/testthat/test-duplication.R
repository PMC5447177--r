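test_that("pairwise protein similarity reports identity and coverage", {
  set.seed(301)
  a <- randomAa(200)
  self <- pairwiseProteinSimilarity(a, a)
  expect_equal(self$identity, 1.0)
  expect_equal(self$coverage_shorter, 1.0)

  b <- substituteAt(a, sample(200, 20), AA20)  # 10% substituted, no indels
  hit <- pairwiseProteinSimilarity(a, b)
  expect_gt(hit$identity, 0.86)
  expect_lt(hit$identity, 0.94)

  u <- randomAa(100); v <- randomAa(100)
  rnd <- pairwiseProteinSimilarity(u, v)
  expect_lt(rnd$coverage_shorter, 1)
  expect_lt(rnd$score, pairwiseProteinSimilarity(u, u)$score)
  expect_error(pairwiseProteinSimilarity("MK1", "MKL"), "non-amino-acid")
})

test_that("homolog gathering applies strict identity and coverage rules", {
  ## threshold boundaries (strict > in both)
  expect_false(homologHitPasses(0.30, 0.9))
  expect_true(homologHitPasses(0.301, 0.9))
  expect_false(homologHitPasses(0.5, 0.60))
  expect_false(homologHitPasses(0.5, 2/3))
  expect_true(homologHitPasses(0.5, 0.70))

  set.seed(302)
  q <- randomAa(150)
  db <- c(same = q,
          diverged = substituteAt(q, sample(150, 60), AA20),  # ~60% ident
          unrelated = randomAa(150))
  hits <- gatherHomologs(q, db)
  expect_true("same" %in% hits$subject_id)
  expect_true("diverged" %in% hits$subject_id)
  expect_false("unrelated" %in% hits$subject_id)
  ## self-exclusion by id
  hits2 <- gatherHomologs(q, db, queryId = "same")
  expect_false("same" %in% hits2$subject_id)
})

test_that("candidate classification ranks conspecific against panel hits", {
  set.seed(303)
  anc <- randomAa(180)
  focal <- c(gA = substituteAt(anc, sample(180, 9), AA20),
             gB = substituteAt(anc, sample(180, 9), AA20),
             gLone = randomAa(180))
  panelFar <- substituteAt(anc, sample(180, 90), AA20)
  panel <- c(eukFar = panelFar)
  origins <- c(eukFar = "other_eukaryote")
  cls <- classifyCandidateDuplicates(focal, panel, origins)
  cats <- stats::setNames(cls$categories$category, cls$categories$gene_id)
  expect_identical(unname(cats["gA"]), "candidate")
  expect_identical(unname(cats["gB"]), "candidate")
  expect_identical(unname(cats["gLone"]), "non_candidate")

  ## species-only: conspecific paralogs, no panel homolog at all
  cls2 <- classifyCandidateDuplicates(focal[c("gA", "gB")],
                                      c(far = randomAa(180)),
                                      c(far = "other_eukaryote"))
  cats2 <- stats::setNames(cls2$categories$category, cls2$categories$gene_id)
  expect_true(all(cats2 == "species_only"))

  ## tie: panel contains an exact copy of the best conspecific hit
  cls3 <- classifyCandidateDuplicates(
    focal[c("gA", "gB")],
    c(copyOfB = unname(focal["gB"])),
    c(copyOfB = "other_eukaryote"))
  cats3 <- stats::setNames(cls3$categories$category, cls3$categories$gene_id)
  expect_identical(unname(cats3["gA"]), "non_candidate")

  ## invariance to panel ordering
  panel4 <- c(panel, far2 = randomAa(180))
  c4a <- classifyCandidateDuplicates(focal, panel4,
                                     c(eukFar = "other_eukaryote",
                                       far2 = "other_eukaryote"))
  c4b <- classifyCandidateDuplicates(focal, rev(panel4),
                                     c(eukFar = "other_eukaryote",
                                       far2 = "other_eukaryote"))
  expect_identical(c4a$categories$category, c4b$categories$category)
})

test_that("bootstrap NJ tree joins close pairs with full support", {
  set.seed(304)
  a <- randomAa(120)
  b <- randomAa(120)
  seqs <- c(F1 = a, F2 = substituteAt(a, sample(120, 5), AA20),
            E1 = b, E2 = substituteAt(b, sample(120, 5), AA20))
  tr <- buildBootstrapTree(seqs, nBootstrap = 100, seed = 1)
  res <- testExclusiveClade(tr, c("F1", "F2"))
  expect_true(res$is_exclusive)
  expect_gte(res$support, 95)

  ## input order invariance of the supported bipartitions
  tr2 <- buildBootstrapTree(seqs[c(3, 1, 4, 2)], nBootstrap = 100, seed = 1)
  expect_true(testExclusiveClade(tr2, c("F1", "F2"))$is_exclusive)
  expect_true(testExclusiveClade(tr2, c("E1", "E2"))$is_exclusive)

  expect_error(buildBootstrapTree(seqs[1:3]), "3-taxon")
})

test_that("tree building handles unequal lengths via center-star merging", {
  set.seed(305)
  core <- randomAa(150)
  seqs <- c(F1 = core,
            F2 = paste0(substituteAt(core, sample(150, 7), AA20), randomAa(10)),
            E1 = substituteAt(core, sample(150, 75), AA20),
            E2 = paste0(randomAa(5), substituteAt(core, sample(150, 75), AA20)))
  tr <- buildBootstrapTree(seqs, nBootstrap = 50, seed = 2)
  expect_identical(sort(tr$tip.label), c("E1", "E2", "F1", "F2"))
  expect_true(testExclusiveClade(tr, c("F1", "F2"))$is_exclusive)
})

test_that("exclusive-clade test pins the strict >50% support rule", {
  tr <- ape::read.tree(text = "((F1,F2)75,(E1,E2));")
  res <- testExclusiveClade(tr, c("F1", "F2"))
  expect_true(res$is_exclusive)
  expect_equal(res$support, 75)

  para <- ape::read.tree(text = "((F1,E1),(F2,E2));")
  res2 <- testExclusiveClade(para, c("F1", "F2"))
  expect_false(res2$is_exclusive)

  tr50 <- ape::read.tree(text = "((F1,F2)50,(E1,E2));")
  res3 <- testExclusiveClade(tr50, c("F1", "F2"))
  expect_false(res3$is_exclusive)
  expect_equal(res3$support, 50)

  ## one non-focal leaf: topologically forced
  tr3 <- ape::read.tree(text = "((F1,F2),E1);")
  expect_true(testExclusiveClade(tr3, c("F1", "F2"))$is_exclusive)
  expect_error(testExclusiveClade(tr, c("F1", "missing")), "missing")
})

test_that("exclusivity matches bipartition enumeration on random trees", {
  set.seed(306)
  for (i in 1:100) {
    tr <- ape::rtree(8, rooted = FALSE)
    tr$node.label <- as.character(sample(0:100, tr$Nnode, TRUE))
    nFocal <- sample(2:6, 1)
    focal <- sample(tr$tip.label, nFocal)
    got <- testExclusiveClade(tr, focal)
    want <- exclusiveOracle(tr, focal)
    expect_identical(got$is_exclusive, want$is_exclusive)
    if (!is.na(want$support) && !is.na(got$support))
      expect_equal(got$support, want$support)
  }
})

test_that("cluster detection recovers families and rejects invaded clades", {
  set.seed(307)
  mkFam <- function(n, len = 160, div = 0.05) {
    anc <- randomAa(len)
    list(anc = anc,
         members = vapply(seq_len(n), function(i)
           substituteAt(anc, sample(len, round(len * div)), AA20), ""))
  }
  f1 <- mkFam(2); f2 <- mkFam(3)
  ## third family: close pair (c1, c2) plus a distant third member c3, with
  ## a panel ortholog that is closer to the pair than c3 is -- the ortholog
  ## invades the family clade while every member still ranks a conspecific
  ## paralog as its best hit
  anc3 <- randomAa(160)
  c1 <- substituteAt(anc3, sample(160, 4), AA20)
  c2 <- substituteAt(anc3, sample(160, 4), AA20)
  c3 <- substituteAt(anc3, sample(160, 30), AA20)
  inv <- substituteAt(anc3, sample(160, 18), AA20)
  inv2 <- substituteAt(anc3, sample(160, 60), AA20)
  focal <- c(a1 = f1$members[1], a2 = f1$members[2],
             b1 = f2$members[1], b2 = f2$members[2], b3 = f2$members[3],
             c1 = c1, c2 = c2, c3 = c3,
             lone = randomAa(160))
  panel <- c(e1 = substituteAt(f1$anc, sample(160, 80), AA20),
             e2 = substituteAt(f1$anc, sample(160, 80), AA20),
             inv = inv, inv2 = inv2)
  origins <- stats::setNames(rep("other_eukaryote", 4), names(panel))
  dup <- detectDuplicateClusters(focal, panel, origins, seed = 5)
  tab <- as.data.frame(clusterTable(dup))
  memb <- lapply(strsplit(tab$members, ","), sort)
  catOf <- function(genes) tab$category[vapply(memb, identical, TRUE,
                                               sort(genes))]
  expect_identical(catOf(c("a1", "a2")), "exclusive_clade")
  expect_identical(catOf(c("b1", "b2", "b3")), "species_only")
  expect_identical(catOf(c("c1", "c2", "c3")), "rejected")
})

test_that("copy counting dedups at strict 90% identity by single linkage", {
  set.seed(308)
  a <- randomAa(300)
  nearA <- substituteAt(a, sample(300, 15), AA20)    # ~95%
  farA <- substituteAt(a, sample(300, 48), AA20)     # ~84%
  expect_identical(countGeneCopies(c(x = a, y = nearA)), 1L)
  expect_identical(countGeneCopies(c(x = a, y = farA)), 2L)

  ## chain A~B (92%), B~C (92%), A~C (~85%): single linkage collapses all
  b <- substituteAt(a, sample(300, 24), AA20)
  cc <- substituteAt(b, sample(300, 24), AA20)
  expect_identical(countGeneCopies(c(A = a, B = b, C = cc)), 1L)

  ## raising the dedup threshold never decreases the count
  seqs <- c(A = a, B = b, C = cc, D = randomAa(300))
  counts <- vapply(c(0.80, 0.90, 0.97),
                   function(t) countGeneCopies(seqs, t), 1L)
  expect_true(all(diff(counts) >= 0))
})
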