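---
title: "Discovering miRNA-mRNA correlation-network module pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering miRNA-mRNA correlation-network module pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirModNet)
```

## The problem

MicroRNAs repress their target mRNAs post-transcriptionally, mostly by
binding seed-complementary sites in 3'UTRs. In a tumour cohort the
expression of both miRNAs and mRNAs varies from patient to patient, and
that within-class variability carries signal: a group of miRNAs whose
expression co-varies (negatively) with a group of mRNAs across tumours is
a candidate regulatory module. mirModNet implements a correlation-network
workflow for finding such **module pairs** — one miRNA cluster together
with a positively connected gene module and a negatively connected gene
module — in two tumour subtypes analysed in parallel (a large
primary-like class and a small metastatic-like class), and for asking
whether a negative module is *semi-canonical*: whether its genes' 3'UTRs
are enriched for the modular miRNAs' seed-match motifs, as direct
miRNA-mediated degradation would predict.

## The procedure

1. **Preprocessing.** Probe-level intensities are collapsed to gene
   symbols by the arithmetic mean on the linear scale, then
   log2-transformed (`collapse_probes()`, `log2_transform()`). Genes must
   span at least a two-fold range between their maximum and minimum
   intensity (`filter_variability()`, boundary inclusive); miRNAs must be
   observed in *more than* 80% of samples (`filter_presence()`, boundary
   strict — an entity present in exactly 80% is dropped). Both boundaries
   are configurable because reasonable readings of "two-fold change" and
   "over 80%" differ; the defaults take the inclusive and the strict
   reading respectively.
2. **Subsample-averaged correlation.** For each class, the Pearson
   coefficient of every gene-miRNA pair is computed in each of 1000
   replicates over a random 80% subsample of the class's samples (drawn
   *without* replacement — a subsample, not a bootstrap) and averaged
   (`subsampled_correlation()`). Missing miRNA values are excluded
   pairwise. A pair with fewer than 3 usable samples in a replicate, or
   with zero variance in the draw, contributes nothing to that
   replicate's average rather than being imputed as 0, which would bias
   low-variance entities toward zero. The subsample size is
   `floor(0.8 * n)`, which keeps correlations defined even for a
   13-sample class (draw size 10).
3. **Signed network.** The correlation matrix is discretized to
   {-1, 0, +1}: the top 1% of entries become +1 and the bottom 1% become
   -1, with `k = floor(quantile * M)` per sign so the two counts are
   exactly equal (`discretize()`). Boundary ties break lexicographically
   by (row, column) for bit-reproducibility, and the -1 set is drawn from
   entries not already claimed by the +1 set, so count conservation holds
   even for degenerate all-equal matrices.
4. **Condensation.** Columns are restricted to a cancer-miRNA whitelist
   (order preserved), then genes with fewer than two non-zero connections
   — of either sign — to the remaining miRNAs are dropped
   (`condense()`; columns strictly first).
5. **Clustering and module extraction.** The condensed network's miRNA
   columns are clustered by agglomerative clustering with Manhattan
   distance and Ward linkage, and the dendrogram is cut into `k_mirna`
   clusters (default 5). The cluster count replaces a visual
   dendrogram-reading step with an explicit parameter — the one
   non-algorithmic step of the original workflow. Genes are clustered
   the same way for heatmap display only; module membership comes from
   the connection patterns. Per cluster and per sign,
   `extract_module_pairs()` collects the connected genes, drops genes
   with a single connection, and by default iterates — dropping miRNAs
   with fewer than two within-module connections and genes falling below
   two — until a fixed point. The fixed point *guarantees* the module
   property that every member has at least two within-module connections;
   the literal one-shot gene-drop (`mode = "single_pass"`) is available
   for strict replication, but can leave miRNAs with a single connection
   (after dropping weak genes, a miRNA's support can fall to one — the
   two modes genuinely differ, and the single-pass output need not
   satisfy the two-connection property).
6. **SVD characterization** (`svd_characterize()`). A correlation matrix
   is treated as a pseudo-dataset — genes as observations, miRNAs as
   features. Entries are first mapped through Fisher's r-to-z transform,
   `z = atanh(r)`, after clipping |r| at `1 - 1e-6` so perfect planted
   correlations stay finite. The SVD is taken of the raw z matrix
   *without column centering*: centering would subtract the sign
   structure that makes the leading gene-score distributions bimodal,
   which is exactly the feature of interest. Variance fractions are
   `sigma_k^2 / sum(sigma_j^2)` over all singular values; each left
   vector is sign-fixed to a non-negative sum. Score shapes are
   quantified by bias-corrected skewness and Sarle's bimodality
   coefficient with the finite-sample correction; BC > 5/9 (the uniform
   distribution's value) is flagged bimodal-leaning, turning a visual
   "two-peak" judgement into a number. The structure is contrasted with
   a shuffle null (`shuffle_null()`): a uniformly random entrywise
   permutation, the strongest null preserving the value multiset;
   within-row and within-column permutation variants are available.
7. **Target-site enrichment** (`seed_motifs()`, `scan_utr()`,
   `target_enrichment()`). From each mature miRNA the three canonical
   seed-match motifs are derived: 7mer-m8 (reverse complement of
   positions 2-8), 7mer-A1 (reverse complement of positions 2-7 followed
   by A) and 8mer (7mer-m8 followed by A). 3'UTRs are scanned by exact
   sense-strand substring matching (N never matches), giving the binary
   affinity matrix A with `A[i, j] = 1` iff at least one motif of miRNA
   j occurs in gene i's UTR — existence, not count. Enrichment of a
   modular gene list is a one-sided (greater) Fisher exact test against
   the whole gene universe; the odds ratio is Haldane-corrected for
   reporting only, never for the p-value. P-values are
   Benjamini-Hochberg adjusted across the modular miRNAs.
8. **Annotation enrichment and sample partitions.**
   `overrepresentation()` applies the same Fisher/BH machinery to a
   GMT term table — a local stand-in for web annotation services that
   keeps the statistic (hypergeometric over-representation, BH-adjusted)
   while removing the web dependency and version drift.
   `cluster_samples()` and `partition_association()` compare two sample
   partitions (e.g. clustering on modular miRNA expression vs on a
   driver-gene panel) by Pearson's chi-square without continuity
   correction (Yates behind a flag); expected counts below 5 raise a
   flag in the result.

`run_pipeline()` chains the stages per class, writes every artifact as
TSV/JSON with a manifest of md5 hashes, parameters and seeds, and can
resume from cached artifacts. Artifacts are written with 17 significant
digits so a resume round-trip is numerically exact.

## The synthetic-data generator

`generate_expression()` emulates the structure of a two-class tumour
cohort with a shared-latent-factor model: per module one standard-normal
factor per sample; modular miRNAs and positive-module genes load
`+lambda`, negative-module genes `-lambda`; every entity adds a baseline
drawn once (log2 intensity scale, mean 8, sd 1.5) and i.i.d. Gaussian
noise. The model is chosen because the workflow defines modules through
correlation, not mechanism — a shared factor is the simplest generator
of a correlated block with both signs. The population correlation of a
planted pair is `lambda^2 / (lambda^2 + sigma^2)`: `lambda = sigma`
gives |r| = 1/2, and the default `lambda = 3, sigma = 1` gives
|r| = 0.9, a regime in which module recovery should be (and in the
packaged tests is) essentially exact. Modules can be restricted to a
subset of classes to create subtype-specific structure.

Defaults mirror the cohort the pipeline targets: 98 primary-like, 13
metastatic-like and 28 normal samples; five modules with the module-size
profile of the motivating study (2-8 miRNAs; gene sets scaled to ~1/10);
400 genes of which 10% are generated near-constant (noise sd 0.05) so
the variability filter has a real pass/fail mix; 60 miRNAs with 5%
missing entries so the presence filter and pairwise-complete correlation
are exercised, and so the whitelist (the planted modular miRNAs plus a
sample of background ones) covers only part of the miRNA panel, keeping
the condensation step non-trivial.

`generate_utr_fasta()` plants verbatim seed-match motifs at recorded
positions in i.i.d. uniform A/C/G/T background sequences, and
rejection-samples each sequence (cap 1000 whole-sequence retries) until
every (gene, miRNA) pair marked 0 in the plant matrix is *clean* — the
sequence contains none of that miRNA's motifs. Exact negatives are what
make enrichment tests sharply testable. The clean-negative guarantee
applies to the miRNAs given as plant-matrix columns: a random 7-mer
occurs in an L-nt uniform sequence with expectation `(L - 6) / 4^7`
(about 0.05 at the default L = 800), so constraining a UTR against a
handful of modular miRNAs converges in a few retries, while constraining
against hundreds of miRNAs would make the clean event exponentially
rare; non-constrained miRNAs simply acquire natural background
occurrences. The default UTR length of 800 nt is near the human median.

What the generator does **not** emulate: probe-level and batch effects,
array normalization artifacts, heavy-tailed expression noise, linkage
between genomic position and expression, realistic UTR base composition
or conservation, and miRNA family structure (each synthetic mature
sequence is random, so motif sets rarely collide). Passing tests
therefore demonstrate correctness of the machinery under a clean
generative model, not performance on real arrays.

## Numerical and design choices

- **Ward with Manhattan distance.** Ward's criterion is derived for
  squared Euclidean distances; the workflow nevertheless specifies
  Manhattan + Ward, and `hclust(method = "ward.D")` reproduces the
  classical update on whatever distance it is given. The combination is
  kept as specified (it operates on {-1, 0, +1} column vectors, where
  Manhattan distance is a natural mismatch count); Euclidean and
  `ward.D2` are one argument away.
- **Resampling mean vs plain Pearson.** With `fraction = 1` the
  implementation short-circuits to a single exact pass, so the
  degenerate case equals plain Pearson bit for bit. For
  `fraction < 1` the replicate mean estimates the *subsample-size*
  correlation, which differs from the full-sample coefficient by a
  deterministic O(1/m - 1/n) term; at 1000+ replicates this offset —
  not Monte-Carlo noise — dominates the gap to the full-sample matrix.
  It is a property of the estimator, shared by any faithful
  implementation of the protocol.
- **Undefined correlations.** Pairs undefined in every replicate are
  reported as `NA`; the pipeline sets them to 0 (with a message) before
  discretization, treating "no evidence" as "no connection".
- **Seeds.** Every stochastic operation takes an explicit seed and uses
  `withr::with_seed`, so nothing perturbs or depends on the caller's RNG
  state; the pipeline splits per-stage seeds deterministically from one
  master seed (kept below 2^31).
- **Missing values in sample clustering.** Manhattan distances are
  undefined for sample pairs with no shared observed features, so
  `cluster_samples()` imputes missing values with the feature mean
  before clustering (observed values untouched).
- **chi-square without continuity correction**, matching the plain
  Pearson statistic on the partition contingency table; the hand-checked
  identity `[[5,0],[0,5]] -> X^2 = 10, df = 1` pins the convention.

## Problem sizes used in the packaged checks

The test suite and the acceptance script run entirely on synthetic data
at desk scale, chosen so the whole suite completes in well under a
minute: correlation fixtures of 10-20 genes x 4-5 miRNAs x 25-40
samples (up to 2000 replicates), discretization oracles on 100 x 40
matrices, module-extraction oracles on 30 x 6 signed networks, pipeline
runs of 80-120 genes x 9-12 miRNAs over 25-60 samples per class, and
the full-default study (139 samples, 400 genes, 60 miRNAs, 1000
replicates) in the acceptance script. Recovery checks use the
signal-to-noise-3, 60-sample regime, where every planted module pair is
recovered with Jaccard 1.0 on miRNA and gene sets; the zero-noise limit
is recovered exactly.

## Known limitations

- The cluster count `k_mirna` is an explicit parameter, not estimated;
  if the planted (or real) module count differs, modules merge or split
  and the pruning step absorbs some of the mismatch but not all of it.
- At study-scale defaults the top-1% cut marks fewer pairs than are
  planted, so recovered study-scale modules are the strongest cores of
  the planted ones — by design, since the quantile, not an effect-size
  threshold, defines the network.
- Fisher tests on overlapping modular gene lists are not independent;
  BH is applied within a module's miRNAs (and within a term table), not
  across modules.
- `single_pass` extraction reproduces the literal one-shot drop but its
  output need not satisfy the two-connection module property; the
  fixed-point default does, at the cost of occasionally emptying small
  modules.
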