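---
title: "Methods: gene duplication and differential expression in a two-condition transcriptome"
author: "dupexpr maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene duplication and differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`dupexpr` implements the post-assembly computational analysis of a
two-condition (for example optimal- versus high-salinity) transcriptome of a
microbial eukaryote grown with prokaryotic food organisms. The package takes
a predicted ORF catalog and per-ORF read counts as its inputs — read
trimming, mapping, assembly and ORF prediction are upstream of it — and
carries the analysis through six stages:

1. **Decontamination**: removal of ORFs resembling prokaryotic sequences.
2. **Isoform collapsing**: grouping ORFs into genes by shared exact
   nucleotide stretches.
3. **Expression**: TPM, a low-count filter, a negative-binomial
   differential-expression (DE) caller, and consensus across callers.
4. **Duplication**: detection of recently duplicated genes by conspecific
   similarity ranking and phylogenetic exclusivity.
5. **Association**: hypergeometric enrichment, the duplication × DE overlap
   test, and a cluster-randomization null for clusters containing both up-
   and down-regulated duplicates.
6. **LGT screening**: combining prokaryotic sequence affinity with intron
   and abundance evidence, plus short-motif scans.

A synthetic-data generator with complete ground truth makes each stage
testable without any external database or read archive.

# Models and procedures

## Isoform collapsing

Two ORFs are isoforms of one gene when they share an identical nucleotide
stretch of **at least 50 nt** (inclusive), extended transitively. The
implementation exploits the equivalence *longest common substring ≥ k ⇔ a
shared exact k-mer exists*: all 50-mers are bucketed and ORFs sharing a
bucket are merged with union–find. This is exact, and `tests/` verify it
against an \(O(n^2)\) all-pairs dynamic-programming closure. The gene
representative is the longest isoform (ties broken by smallest ORF id, for
determinism). Shared-stretch detection considers the forward strand only —
assembled transcripts are oriented by ORF prediction — with an optional
reverse-complement mode in `longestSharedStretch()`.

## Decontamination

An ORF is discarded when it shares with a prokaryote panel sequence a
contiguous region **longer than 100 bp** that is **more than 90% identical**
(both strict). The screen is an exhaustive ungapped diagonal window scan
with integer-scaled scoring (match \(+(1-p)S\), mismatch \(-pS\), with
\(S = 10^4\)), so a window qualifies exactly when its identity strictly
exceeds the threshold — there is no floating-point ambiguity at the 90%
boundary, and the decision provably equals the brute-force
"every window of every diagonal" definition. Indels are not modeled in the
decision; contaminant reads assembled from a resident prokaryote diverge by
substitutions at the identities relevant here. At catalog scale an
exact-seed prefilter (shared 14-mer) limits the scan to plausible pairs; a
qualifying region (> 100 bp at > 90%) contains an error-free 14-mer with
overwhelming probability.

Genes whose *sequences* look prokaryotic but that are genuinely resident
(for example laterally acquired genes) are separated from residual
contamination by orthogonal evidence (`classifyOriginByAbundance`):
confirmed contaminant transcripts stay at or below ~10 TPM, whereas
resident genes of prokaryotic affinity are expressed orders of magnitude
higher (> 600 TPM) and/or contain introns. Between the two TPM thresholds,
without an intron, a gene is reported `uncertain` rather than forced into
either class.

## Expression and differential expression

**TPM.** Per sample, \(\mathrm{rate}_i = c_i / \ell_i\) and
\(\mathrm{TPM}_i = 10^6 \,\mathrm{rate}_i / \sum_j \mathrm{rate}_j\);
columns sum to \(10^6\) by construction.

**Low-count filter.** An ORF is removed when the 75th percentile of its
counts across all samples is below 10 reads. The percentile is the common
linear-interpolation definition (R's type 7); the filter is applied across
samples (not per sample), a documented reading of the rule.

**NB caller.** Per ORF, a likelihood-ratio test of the condition effect in
a negative-binomial log-linear model with a library-size offset.
Size factors are median-of-ratios. Dispersion (variance
\(\mu + \phi\mu^2\)) is estimated per ORF by the method of moments on
normalized counts and shrunk toward the across-ORF median with a prior
weight of 10 against the residual degrees of freedom, then treated as fixed
in the two GLM fits. At 3 + 3 replicates the asymptotic \(\chi^2_1\)
reference is visibly liberal (empirical type-I error ~0.07–0.09 at
\(\alpha = 0.05\) in our simulations), so the deviance difference receives
a Bartlett-style finite-sample correction, \(\mathrm{LRT}\,(n-2)/(n-1)\),
which brings the type-I error to ~0.045–0.055 across dispersions 0.05–0.3.
The acceptance suite re-measures this calibration on a 2,000-gene null.

**Calling.** An ORF is DE iff its adjusted p-value (Benjamini–Hochberg) is
strictly below 0.05 — or, for ingested empirical-Bayes caller output, its
posterior probability strictly above 0.95 — *and* its fold change is
strictly outside \([0.5, 2]\). The fold change used for calling is a
pseudocount-shrunken TPM ratio \((m_2 + 1)/(m_1 + 1)\): a transparent,
bounded stand-in for model-based posterior fold changes (the empirical-Bayes
model itself is out of scope; its output can be ingested via
`readCallerTable()`). DE is assessed at ORF level; the gene-level reduction
flags a gene when any isoform is DE, with direction from the isoform with
the smallest adjusted p-value. `consensusDE()` reports intersection,
union, pairwise-agreement counts and direction conflicts across callers.

## Duplicate detection

For each focal (conspecific) gene representative, all local-alignment hits
(BLOSUM62, affine gaps 10/0.5) that cover **more than 2/3 of the shorter
sequence** at **more than 30% identity** (both strict) are ranked by
alignment score. A gene is a *candidate recent duplicate* when its best
passing hit is conspecific and strictly outscores every non-focal hit;
score ties go against candidacy (conservative, deterministic — the ranking
uses raw alignment score, since a self-contained search has no
database-size-dependent E-value). Genes whose only passing homologs are
conspecific are *species-only*. Candidates are clustered by connected
components over mutual passing hits.

Each cluster with non-focal homologs is then tested phylogenetically: a
multiple alignment (trivial for equal-length sequences, otherwise
center-star merging of global pairwise alignments with "once a gap, always
a gap"), columns with more than 50% gaps dropped, p-distances with pairwise
deletion, a neighbor-joining topology, and bootstrap support as the
percentage of 100 column-resampled replicates containing each
internal-edge bipartition. A cluster is accepted (`exclusive_clade`) when
some edge bipartitions the tree into exactly the focal members versus
everything else with support **strictly above 50%**. Exclusivity is tested
on unrooted bipartitions and is therefore rooting-invariant. With exactly
one non-focal leaf the split is topologically forced and counts as
exclusive (support reported as NA) — three-taxon cases cannot carry
bootstrap evidence either way. Externally computed Newick trees (from a
dedicated maximum-likelihood tool) are preferred over the internal NJ
stand-in when a tree directory is supplied; clusters whose external tree
is absent or lacks the cluster's genes are rejected with a logged reason.

`countGeneCopies()` supports copy-number surveys: sequences more than 90%
identical (strict) are collapsed by single linkage — so a chain A~B~C
collapses into one copy even when A and C fall below the threshold — and
the longest member represents each group.

## Association statistics

Class enrichment uses the hypergeometric upper tail (lower tail for
depletion), computed per COG class over a configurable universe, with BH
correction across the *retained* classes only; six uninformative classes
("Cell motility", "Defense mechanisms", "Unknown function", "General
predictions only", "Nuclear structures", "No hits found") are excluded
before testing by default. Genes carrying several classes count once per
class (classes are tested marginally). Both tails are reported because the
direction of interest varies by question.

The duplication × DE overlap test reports the fraction of duplicated genes
that are DE and its hypergeometric upper-tail probability; the universe
should be the gene set surviving the low-abundance exclusion and is an
explicit required argument, since published analyses are often ambiguous
about it.

The *mixed-direction* statistic is the fraction of duplicate clusters
containing at least one up- and at least one down-regulated member. Its
null distribution is obtained by drawing the same number of genes without
replacement from the complete labeled gene set, partitioning them into the
observed cluster sizes, and repeating 1,000 times (mean ± sample SD across
replicates; empirical p with the \((r+1)/(n+1)\) convention, never exactly
zero). The real cluster-size distribution is an explicit input — in the
integrated pipeline it is taken from the detected clusters. A closed-form
companion, `analyticMixedExpectation()`, gives the exact per-cluster
probability \(1 - \tfrac{\binom{N-n_{up}}{k}}{\binom{N}{k}} -
\tfrac{\binom{N-n_{down}}{k}}{\binom{N}{k}} +
\tfrac{\binom{N-n_{up}-n_{down}}{k}}{\binom{N}{k}}\) and serves as the
oracle for the Monte-Carlo implementation in the acceptance suite.

## LGT screening and motifs

The verdict table composes the two evidence rules literally: prokaryotic
affinity with an intron or expression strictly above 600 TPM →
`lgt_candidate`; prokaryotic affinity at or below 10 TPM without an intron
→ `probable_contaminant`; other prokaryotic-affinity genes → `uncertain`;
no prokaryotic affinity → `not_lgt`. Exclusive placement with prokaryotes
in a tree raises a confidence field but is not required — it is supporting,
not defining, evidence. The 600-TPM figure describes observed candidates
rather than a designed cutoff and is exposed as a parameter with that
default. Absence from a sister lineage is an optional input flag, never
computed (it requires external data).

`scanMotif()` reports every possibly-overlapping occurrence of a short
pattern with `x`/`X` single-residue wildcards and `[KR]`/`[K/R]`
alternations, 1-based. `checkErRetention()` flags KDEL/HDEL/KK/KxK at the
C-terminus and RR at the N-terminus; RR is also accepted at positions 2–3
so that an initiator methionine does not mask the signal.

# The synthetic-data generator

`simulateDataset()` emulates the statistical structure the analysis
assumes, with complete ground truth:

- **Genes and families.** Gene proteins are uniform random sequences;
  recent-duplicate family members derive from a family ancestor by per-site
  uniform substitution at `divergencePerCopy` (default 0.05, no indels —
  the divergence model is deliberately minimal since nothing downstream
  depends on a substitution matrix). Nucleotide sequences are independent
  random reverse-translations of the proteins, which makes protein
  divergence the controlled quantity and guarantees that duplicate genes do
  not share the ≥ 50-nt exact stretches that define isoforms (expected
  identical-codon runs are 1–2 codons).
- **Isoforms** are codon-aligned windows of the gene sequence that all
  contain a central exact block of `sharedStretchLen` (default 60 nt), so
  the collapsing rule is exercised on both sides of its boundary.
- **Contaminants** are fragments of the prokaryote panel mutated per site
  to `contaminantIdentity` (default 0.95), each from a distinct panel
  sequence; the > 90%-identity screening boundary is directly tunable.
- **Panels.** Families receive two other-eukaryote homologs at divergence
  0.5 from the ancestor with probability `familyPanelProb` (default 0.7;
  families without any are the species-only truth), and singleton genes an
  ortholog at divergence 0.3 with probability 0.3.
- **Counts** are negative-binomial (variance \(\mu + \phi\mu^2\),
  default \(\mu = 100\), \(\phi = 0.1\)) with means proportional to ORF
  length, two conditions × 3 replicates. 20% of genes are DE at
  \(|\log_2 FC| = 2\), 62% of them up-regulated — the direction split
  reported for the real high-salinity data. Low-abundance ORFs (5%) get
  near-zero means and are drawn from non-DE genes so that DE
  sensitivity/FDR stay well defined after the filter.
- **Scale.** The default is 1,200 genes — a desk-scale stand-in for the
  real catalog of ~12,000 genes — with 40 families of size 2–3. These sizes
  keep the full pipeline run in the low minutes while leaving every rate
  estimate (sensitivity, FDR, calibration) enough events to be meaningful.

What the generator does *not* emulate: read-level noise and isoform-level
quantification uncertainty (counts are drawn directly per ORF), splice-graph
realism, codon usage and compositional bias, indels within families,
correlated DE among duplicates, and annotation errors. Passing the
recovery tests therefore demonstrates the correctness and calibration of
the implementation under its stated assumptions, not performance on real
reads — the real analysis additionally depends on assembler, mapper and
annotation behavior that is out of scope here.

# Numerical choices and degenerate inputs

- Thresholds quoted as "more than"/"above" are strict; "at least 50 nt" is
  inclusive. Boundary tests pin each one.
- The screening decision uses integer-scaled scores (denominator
  \(10^4\)), making the 90% boundary exact.
- The randomization null seeds every replicate stream from a single master
  seed; `runAll()` derives one sub-seed per stage, so stage results are
  reproducible independently of each other.
- Degenerate inputs: all-zero samples make TPM undefined and raise an
  error; a fold change over two zero means is 1 by the pseudocount;
  flat genes return \(p = 1\); trees with fewer than four leaves are
  refused with a pointer to the forced three-taxon rule; an empty
  duplicated set makes the overlap test an error rather than a NaN.
- `empirical_p` can never be exactly zero by construction.

# Problem sizes used in the checks

The packaged tests run the full pipeline on the 1,200-gene default (about
two minutes), the caller calibration on 2,000-gene null and power panels,
the randomization-versus-analytic comparison up to the real study's scale
(11,280 genes, 435 drawn into 153 clusters, 1,000 replicates), and the
oracle equivalences on small constructed instances where brute force is
exact. `scripts/acceptance.R` recomputes all headline quantities from
scratch at these same sizes.

# Known limitations

- The NJ/p-distance/center-star tree stand-in is not a maximum-likelihood
  phylogeny; for real data, externally computed trees should be supplied
  via `treeDir`.
- The candidate-duplicate prefilter (≥ 4 shared protein 4-mers) is tuned
  for homologs of ≥ ~45% identity; homologs barely above the 30% identity
  threshold can escape the *pipeline* search (the direct
  `gatherHomologs()` has no prefilter).
- Median-of-ratios normalization assumes most genes are not DE; datasets
  where a majority of genes shift in one direction violate it (as they do
  for the published tools sharing this normalization).
- The decontamination decision is ungapped; a contaminant diverged by
  indels could evade it (upstream read-level filters are the primary
  defense there).
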