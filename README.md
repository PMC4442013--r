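# metexpress

Prediction of key (driver) enzyme-coding genes for a disease by
integrating a gene-coexpression network built from case/control
expression data with a directed enzyme–enzyme metabolic network.

## The problem and who this is for

In diseases with a metabolic component (the motivating application is
neurodegeneration — Parkinson's and Huntington's disease), some
enzyme-coding genes both change expression with the disease *and* sit
upstream of many other enzymes in metabolism, so their dysregulation
can propagate through pathways. `metexpress` is for computational
biologists who have (i) one or more expression datasets with binary
disease/normal labels, (ii) a reaction database (KGML-style XML or a
flat reaction table), and optionally (iii) a functional-association
network and known disease-gene lists, and who want a ranked,
statistically validated list of candidate driver enzymes.

## Method

For each dataset:

1. **Preprocessing.** Genes with a missing-value fraction ≥ 0.8 are
   removed; values are normalized (per-gene z-score by default).
2. **Coexpression modules.** Pearson correlations r_ij are computed for
   all gene pairs (pairwise-complete over missing values); an edge is
   kept when |r_ij| ≥ t (default t = 0.7). The network is partitioned
   by modularity (Q) optimization — recursive leading-eigenvector
   bisection with single-vertex refinement and a greedy merge step —
   and modules with more than 10 genes are retained. Each module's
   disease specificity is the orientation-invariant ROC-AUC of its
   per-sample median expression profile against the labels:
   `specificity = max(AUC, 1 − AUC)`, with up/down direction kept
   separately.
3. **Metabolic network.** Reactions are read from KGML or a reaction
   TSV; reversible reactions are split into two directed reactions.
   Metabolites participating in ≥ 18 source reactions (currency
   metabolites such as ATP) or appearing in an excluded pathway
   ("Xenobiotics Biodegradation and Metabolism") are removed. For every
   retained metabolite, each producing enzyme gets a directed edge to
   each consuming enzyme. Enzymes with outward edges form the scoring
   **background**.
4. **Scoring.** For a background gene g in module M, the enrichment of
   its outward links inside M is the upper hypergeometric tail
   P(X ≥ k) of drawing n out-neighbors from N = |background| − 1 genes
   of which K = |M ∩ background| − 1 are module-mates. The importance
   score is `specificity(M) × (−log10 p)`. Genes scoring strictly above
   the per-dataset median are the dataset's candidates.
5. **Combination.** Genes selected in at least 2 datasets are the key
   enzyme-coding genes (the all-datasets core is reported too).

Validation statistics: one-sided Fisher exact term enrichment of the
key genes against the enzyme background with Benjamini–Hochberg FDR
adjustment, and a network-proximity permutation test — the observed
statistic is the mean over key genes of each gene's mean shortest-path
distance (Dijkstra) to all known disease genes, compared with 1000
same-size random draws; the empirical p is the fraction of null means
≤ the observed mean.

A synthetic-data generator (`gen_expression()`, `gen_reactions()`,
`gen_term_map()`, `gen_association_network()`, `gen_study()`) produces
all inputs with planted ground truth, so every stage is testable
without external downloads.

## Worked example

```r
library(metexpress)

study <- gen_study(seed = 1)   # 3 synthetic datasets + reactions + networks
ds <- normalize_expression(filter_missing(study$datasets[[1]]), "per_gene_zscore")

mods <- detect_modules(ds, threshold = 0.7, min_size = 11, seed = 1)
mods
#> <metx_modules 'synthetic_1'> 5 modules (Q = 0.792), 100 unassigned genes
#>  module_id n_genes specificity    auc direction
#>          1      20      0.9400 0.9400        up
#>          2      20      0.5950 0.4050      down
#>          3      20      0.5350 0.5350        up
#>          4      20      0.5325 0.4675      down
#>          5      20      0.5400 0.5400        up
```

Module 1 is the planted disease-specific module: its median profile
separates disease from normal samples with AUC 0.94, while the other
modules sit near chance (0.5).

```r
reactions <- split_reactions(study$reactions)
net <- build_enzyme_graph(reactions, filter_metabolites(reactions))
net
#> <metx_metnet> 200 enzyme genes, 458 directed edges, 200 with outward edges

scores <- score_genes(ds, mods, net, outward_genes(net))
head(scores[order(-scores$importance),
            c("gene_id", "module_id", "specificity", "enrichment_p", "importance")])
#>    gene_id module_id specificity enrichment_p importance
#> 12    G012         1        0.94 8.776513e-15  13.213277
#> 2     G002         1        0.94 3.245541e-14  12.679390
#> 20    G020         1        0.94 1.101523e-13  12.180526
#> 16    G016         1        0.94 6.658954e-11   9.565998
#> 3     G003         1        0.94 8.229298e-11   9.479559
#> 1     G001         1        0.94 1.428905e-09   8.314297
```

The top-ranked genes combine membership in the disease-specific module
(specificity 0.94) with many outward metabolic links landing inside
that module (tiny hypergeometric p), exactly the joint signal the
method looks for; the five planted key genes G001–G005 are among them.

```r
assoc <- permutation_test(study$truth$planted_key_genes,
                          study$assoc$disease_genes, study$assoc$graph,
                          n_perm = 1000, seed = 1)
assoc
#> <metx_assoc> observed mean shortest path = 1.000; null 5.048 +/- 0.874;
#>   empirical p = 0 (n_perm = 1000)
```

The planted key genes sit one hop from the known disease genes, while
random same-size gene sets average about five hops — the permutation p
is 0 at 1000 draws.

`run_pipeline(config, out_dir)` chains all stages for a multi-dataset
study from one YAML configuration and writes per-dataset score tables,
the combined key-gene list, enrichment and association results, and a
deterministic `manifest.json` (see `?run_pipeline` for the config
format).

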