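# mirModNet

Identification of **miRNA–mRNA correlation-network module pairs** from
paired expression profiles of tumour cohorts, with seed-motif target-site
enrichment and SVD characterization of the correlation structure.

## What it does

MicroRNAs repress mRNAs by binding seed-complementary sites in 3′UTRs.
Across the tumours of one subtype, the expression of a regulating miRNA
group co-varies with its target genes, so modules can be inferred from
the correlation structure alone. mirModNet implements that workflow:

1. **Preprocess**: probe-to-gene collapsing (linear-scale mean), log2
   transform, a two-fold variability filter on genes and an
   over-80%-presence filter on miRNAs.
2. **Correlate**: for each sample class, the gene × miRNA Pearson matrix
   is estimated as the average over 1000 replicates, each computed on a
   random 80% subsample drawn without replacement
   (`subsampled_correlation()`).
3. **Discretize**: the top 1% positive correlations become +1, the top
   1% negative correlations −1, all else 0 — a signed bipartite network
   with exactly `k = floor(0.01·M)` entries per sign (`discretize()`).
4. **Condense**: columns are restricted to a cancer-miRNA whitelist,
   then genes with fewer than two non-zero connections are dropped
   (`condense()`).
5. **Cluster and extract**: two-way hierarchical clustering (Manhattan
   distance, Ward linkage) cuts the miRNAs into `k` clusters; per
   cluster and sign, genes with a single connection are dropped and the
   network is pruned to a fixed point in which every module member has
   ≥ 2 within-module connections (`cluster_bipartite()`,
   `extract_module_pairs()`). Each cluster yields a **module pair**:
   one positive-connection and one negative-connection gene module
   sharing the cluster's miRNAs.
6. **Sequence evidence**: canonical seed-match motifs (7mer-m8 =
   reverse complement of miRNA positions 2–8; 7mer-A1 = reverse
   complement of positions 2–7 plus A; 8mer = 7mer-m8 plus A) are
   scanned over 3′UTRs into a binary affinity matrix A (A_ij = 1 iff a
   motif of miRNA j occurs in gene i's UTR). Enrichment of a module's
   gene list is tested per miRNA with a one-sided Fisher exact test
   against the whole gene universe, BH-adjusted
   (`seed_motifs()`, `scan_utr()`, `target_enrichment()`).
7. **Context**: Fisher r-to-z transformed correlation matrices are
   characterized by uncentered SVD (variance fractions, score skewness,
   Sarle bimodality) against an entrywise shuffle null
   (`svd_characterize()`, `shuffle_null()`); gene lists are tested for
   term over-representation against a GMT (`overrepresentation()`);
   sample partitions are compared by chi-square
   (`cluster_samples()`, `partition_association()`).

A synthetic-data generator (`synthetic_config()`, `generate_expression()`,
`generate_utr_fasta()`, `generate_term_table()`, `simulate_study()`)
plants shared-latent-factor modules — planted pair correlation
λ²/(λ²+σ²) — and seed motifs with exact clean negatives, so the whole
pipeline is testable end to end without any downloads.
`run_pipeline()` orchestrates all stages per class with manifests,
per-stage seeds and resumable artifacts; `inst/scripts/mirmodnet.R` is a
command-line wrapper (`simulate`, `run-all`).

## Worked example

```r
library(mirModNet)

cfg <- synthetic_config(
  n_samples_per_class = c(PPC = 40, MPC = 13),
  n_genes = 120, n_mirnas = 12,
  module_specs = list(module_spec(3, 12, 10), module_spec(4, 14, 8)),
  seed = 42)
st <- simulate_study(cfg, "readme_study")

pc <- pipeline_config(
  gene_tsv = st$paths$gene_tsv, mirna_tsv = st$paths$mirna_tsv,
  labels_tsv = st$paths$labels_tsv, whitelist = st$paths$whitelist,
  utr_fasta = st$paths$utr_fasta, mature_fasta = st$paths$mature_fasta,
  gmt = st$paths$gmt, classes = "PPC",
  n_reps = 200, quantile = 0.05, k_mirna = 2, seed = 1)
res <- run_pipeline(pc, "readme_run")
```

The run logs the filter and condensation outcomes:

```
variability filter (fold=2): kept 108 of 120 entities
presence filter (>80%): kept 12 of 12 entities
condense: 11 of 12 miRNAs, 42 of 108 genes retained
```

and recovers the two planted module pairs:

```r
for (mp in res$PPC$module_pairs) print(mp)
#> ModulePair modu-1: 3 miRNAs; +module 12 genes (3 miRNAs), -module 10 genes (3 miRNAs)
#> ModulePair modu-2: 8 miRNAs; +module 11 genes (4 miRNAs), -module 9 genes (4 miRNAs)
```

Module pair 1 is exactly the first planted module (3 miRNAs, 12
positive, 10 negative genes); the second cluster absorbed the remaining
whitelist miRNAs, and the fixed-point pruning pared it back to the four
planted module-2 miRNAs on both sides. The SVD profile of the
z-transformed correlation matrix shows the two planted factors carrying
~98% of the variance:

```r
res$PPC$svd
#> SvdProfile: 10 components returned of 11 singular values
#>   leading variance fractions: 0.514 0.466 0.005 0.004 0.003
```

and the negative modules are sharply enriched for their miRNAs' planted
target-site motifs — 10 of 10 module genes carry mir001-003 sites
versus 0 of the 98 background genes:

```r
head(res$PPC$target_enrichment)
#>          module  mirna list_targets bg_targets odds_ratio      p_value        adj_p
#> 1 PPC-modu-1-ne mir001           10          0   4641.000 8.615626e-15 8.615626e-15
#> 2 PPC-modu-1-ne mir002           10          0   4641.000 8.615626e-15 8.615626e-15
#> 3 PPC-modu-1-ne mir003           10          0   4641.000 8.615626e-15 8.615626e-15
#> 4 PPC-modu-2-ne mir004            8          0   1263.667 1.071095e-11 1.071095e-11
#> 5 PPC-modu-2-ne mir005            8          0   1263.667 1.071095e-11 1.071095e-11
#> 6 PPC-modu-2-ne mir006            8          0   1263.667 1.071095e-11 1.071095e-11
```

All artifacts (filtered matrices, correlation TSVs with resampling
metadata, SVD JSON, condensed network, module edge lists and summaries,
enrichment tables) land under `readme_run/` with `manifest.json`
recording parameters, seeds and md5 hashes of every input and output.

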