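# dupexpr

Post-assembly analysis of two-condition transcriptomes of microbial
eukaryotes, centered on the question: **are recent gene duplications
associated with the expression response to an environmental shift** (for
example a salinity change)?

The package is written for researchers who have an assembled, ORF-predicted
transcriptome with replicated read counts under two conditions, plus protein
panels from other organisms, and who want a tested, reproducible
implementation of the following analysis chain:

1. **Decontamination** — discard ORFs sharing a region > 100 bp at > 90%
   identity with a prokaryote sequence panel; separate genuinely resident
   genes of prokaryotic affinity from residual contamination using intron
   presence and expression level (contaminant transcripts stay ≤ 10 TPM,
   resident genes reach > 600 TPM).
2. **Isoform collapsing** — ORFs sharing an identical stretch of at least
   50 nt are isoforms of one gene (transitive closure; the longest isoform
   represents the gene).
3. **Differential expression** — TPM; removal of ORFs whose 75th count
   percentile is < 10 reads; a negative-binomial likelihood-ratio caller
   with library-size offsets and moderated dispersion; Benjamini–Hochberg
   correction; an ORF is DE iff adjusted *p* < 0.05 (or posterior > 0.95
   for ingested empirical-Bayes output) **and** fold change < 0.5 or > 2;
   consensus across multiple callers.
4. **Duplicate detection** — a gene is a candidate recent duplicate when
   its best homolog (local alignment, hits kept at > 30% identity covering
   > 2/3 of the shorter sequence) is conspecific and outscores every
   other-species hit; candidate clusters are accepted when their genes form
   an exclusive clade with bootstrap support > 50% in a
   neighbor-joining/bootstrap tree (or an externally supplied tree).
5. **Association statistics** — hypergeometric COG-class enrichment
   (six uninformative classes excluded), the duplication × DE overlap test,
   and the fraction of duplicate clusters containing both up- and
   down-regulated members, compared against a null that randomly reassigns
   genes to clusters of the observed sizes 1,000 times
   (mean ± SD, empirical *p*). A closed-form expectation
   `analyticMixedExpectation()` backs the Monte-Carlo null:
   for a cluster of size *k* drawn from *N* genes with *n_up*/*n_down*
   labels, P(both directions) =
   1 − C(N−n_up,k)/C(N,k) − C(N−n_down,k)/C(N,k) + C(N−n_up−n_down,k)/C(N,k).
6. **LGT screening and motifs** — verdicts combining prokaryotic affinity,
   intron and abundance evidence; wildcard motif scans (for example
   `PxLXHGDLWSxN`, `Tx[K/R]`) and ER-retention signals (KDEL, HDEL, KK,
   KxK, RR).

A synthetic-data generator (`simulateDataset()`) produces gene families,
isoforms, contaminants, homolog panels and negative-binomial counts with
complete ground truth, so the whole pipeline is testable end to end.

## Worked example

```r
library(dupexpr)

sim <- simulateDataset(simConfig(nGenes = 200L, nFamilies = 10L,
                                 nContaminants = 10L, seed = 42L))
sim
#> SimulatedData: 423 ORFs ( 10 contaminants ), 6 samples, seed 42

report <- runAll(sim, runConfig(nReps = 1000L, seed = 42L))
str(report[c("n_orfs_in", "n_discarded_contaminant", "n_genes",
             "n_de_genes_up", "n_de_genes_down", "clusters_by_category",
             "overlap_fraction", "overlap_p", "mixed_direction_fraction",
             "null_mean", "null_sd")])
#> List of 11
#>  $ n_orfs_in               : int 423
#>  $ n_discarded_contaminant : int 10
#>  $ n_genes                 : int 200
#>  $ n_de_genes_up           : int 25
#>  $ n_de_genes_down         : int 19
#>  $ clusters_by_category    :List of 2
#>   ..$ exclusive_clade: int 9
#>   ..$ species_only   : int 1
#>  $ overlap_fraction        : num 0.36
#>  $ overlap_p               : num 0.0734
#>  $ mixed_direction_fraction: num 0
#>  $ null_mean               : num 0.0478
#>  $ null_sd                 : num 0.0666
```

Reading the output: all 10 planted contaminant ORFs were discarded; the
413 remaining ORFs collapse to exactly the 200 simulated genes; 25 genes
are called up- and 19 down-regulated; the 10 planted duplicate families are
recovered (9 as bootstrap-supported exclusive clades, 1 — which has no
panel homolog — as a species-only cluster); 36% of duplicated genes are DE
(hypergeometric *p* = 0.073 against the 22% genome-wide DE rate at this
scale); no cluster mixes up- and down-regulated members, against a null
expectation of 4.8% ± 6.7% from 1,000 random reassignments.

Per-stage functions (`collapseOrfs`, `screenContaminants`,
`summarizeExpression`, `detectDuplicateClusters`, `classEnrichment`,
`randomizationNull`, `screenLgtCandidate`, `scanMotif`, ...) expose each
step individually; `writeSimulatedData()`/`readDatasetDir()` and the
`outDir` argument of `runAll()` provide plain-text (FASTA/TSV/JSON)
interfaces for external data.

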