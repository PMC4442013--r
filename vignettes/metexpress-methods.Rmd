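---
title: "Methods and design choices in metexpress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in metexpress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metexpress)
```

# The model

`metexpress` prioritizes enzyme-coding genes that jointly satisfy two
conditions: they belong to a gene-coexpression module whose expression
separates disease from normal samples, and their outward metabolic
links (edges from a metabolite's producer to its consumers) fall
inside that same module more often than chance. The underlying
assumption is that an enzyme whose products feed many co-regulated
enzymes is positioned to propagate a disease-associated expression
change through metabolism, making it a candidate driver rather than a
passenger.

The pipeline is deliberately modular: each stage has a plain-data
interface (matrices, data frames, igraph graphs) so that any stage can
be run, inspected and tested in isolation.

# Stage-by-stage procedure and its assumptions

## Expression preprocessing

Genes are filtered on their **per-gene missing-value fraction**, with
cutoff 0.8: a gene is kept when strictly less than 80% of its entries
are missing. Filtering on the per-gene fraction is one of two possible
readings of a per-dataset missingness rule ("median ratio of null
values"); we chose it because it is the only reading that yields a
gene-level filter compatible with downstream per-gene correlations.
The cutoff is a parameter (`max_null_fraction`).

Missing entries are recorded, never imputed; all downstream
correlations use pairwise-complete observations, and gene pairs
sharing fewer than 4 non-missing samples get an undefined correlation,
treated as 0 (no edge). Duplicate gene ids (multiple probes mapping to
one gene) are collapsed by the per-sample median across rows, a common
probe-to-gene convention; `first` and `max-variance` are available for
users who prefer a representative-probe rule.

Normalization defaults to the per-gene z-score. Note the z-score uses
the sample standard deviation (denominator *n* − 1, R's `sd`), so a
normalized non-constant row has `sd(row) == 1` exactly; constant rows
are set to all-zero rather than NaN. Quantile normalization (via
limma) and no-op normalization are selectable; the choice matters
little for the default pipeline because both Pearson correlation and
the rank-based AUC are invariant to per-gene affine transforms.

## Coexpression modules

The coexpression graph keeps an edge when |PCC| ≥ `threshold`. The
original analyses this package re-implements do not state their edge
rule; we default to the absolute threshold t = 0.7 — a conventional
"strong correlation" cutoff in coexpression practice — and expose both
the threshold and an alternative top-k-per-gene rule, because module
granularity genuinely depends on this choice.

Partitioning maximizes Newman modularity Q in the style of Qcut:
starting from connected components, each community is split by the
sign pattern of the leading eigenvector of its generalized modularity
matrix, each split is refined by greedy single-vertex moves
(Kernighan–Lin style, each vertex moving at most once per pass, best
configuration kept), recursion stops when no split increases Q, and a
final greedy step merges community pairs whenever merging increases Q.
The procedure is deterministic; the `seed` argument only fixes
tie-breaking order. We implement this directly (rather than wrapping a
generic community detector) so the stopping rule, the merge step and
determinism are under the package's control and testable. Modules with
**more than 10 genes** (`min_size = 11`, the strict reading) are
retained; smaller communities go to an explicit unassigned pool so the
partition plus pool always exactly covers the graph.

Module disease specificity is the ROC-AUC of the module's per-sample
median expression against the labels, computed by the Mann–Whitney
rank statistic with ties contributing ½. Whether disease or normal
was treated as the positive class in the original analyses is
unstated; we sidestep the question by reporting the
orientation-invariant `max(AUC, 1 − AUC)` as specificity and keeping
the direction (up/down/flat) as a separate field, so down-regulated
disease modules score as high as up-regulated ones.

## Metabolic network

Reversible reactions are split into two directed reactions with
substrates and products swapped before any edge is built. Three
decisions here were genuinely open:

* **Metabolite participation counting.** The currency-metabolite
  cutoff (retain metabolites in fewer than 18 reactions) is applied to
  *source* (pre-split) reactions, counting a metabolite once per
  reaction regardless of side. Counting after splitting would double
  every reversible reaction's contribution and silently change the
  cutoff's semantics.
* **Pathway exclusion.** A metabolite appearing in any reaction of an
  excluded pathway is removed globally (the stricter reading);
  restricting the exclusion to those reactions only would be the other
  defensible reading and is a one-line change in
  `filter_metabolites()`.
* **Self-edges.** An enzyme catalyzing a reversible reaction produces
  and consumes the same metabolite across the two split halves; if
  that counted as "distinct reactions", every reversible reaction
  would force a self-loop on its enzyme. Self-edges are therefore kept
  only when the producing and consuming records descend from distinct
  source reactions, and they are flagged.

Enzyme identity is the gene id (not the EC number); multi-enzyme
reactions link every producer gene to every consumer gene. The genes
with outward edges — those generating a retained metabolite consumed
by some enzyme — form the scoring background for every downstream
statistic, since only they can propagate change onward.

## Importance scoring and combination

Link enrichment is the canonical fixed-background enrichment model:
an upper-tail hypergeometric test on the gene's out-neighbors, with
the gene itself removed from both the background (N = |background| −
1) and its module (K). A gene with no within-module out-neighbors
(k = 0) gets p = 1 by definition rather than by tail evaluation.

The default combiner is `specificity × (−log10 p)`: zero exactly when
the enrichment is null, smoothly increasing in both signals, and
interpretable as a specificity-weighted log-enrichment. Because fusing
an AUC scale with a log-p scale is a genuine modeling choice, a
rank-based combiner (`rank_sum`) is provided. Candidate selection uses
the strict median rule — importance strictly greater than the
per-dataset median over all scored background genes — so at most half
the background is ever selected and an all-ties dataset selects
nothing; a ≥ rule is available. Genes in no retained module score
importance 0 (specificity recorded as the chance value 0.5, p = 1):
they cannot carry module-level evidence, but they still count toward
the median, which anchors the cutoff at the background's typical
signal level. Genes absent from the metabolic background are never
scored. The cross-dataset rule keeps genes selected in ≥ 2 datasets,
with the all-datasets core reported separately.

The overlap significance between two per-dataset prediction sets is
reported as an upper-tail hypergeometric on the shared background.
This is an approximation labeled as such: the test behind the
originally printed overlap p-values is unstated, so the package
reports its own statistic and makes no claim of matching printed
values.

## Validation statistics

Term enrichment is a one-sided (greater) Fisher exact test per term —
enrichment only, since depletion is not reported in this analysis
style — with term gene sets intersected with the enzyme background
first, so N is always the background size. FDR adjustment is
Benjamini–Hochberg (the default of the R tooling this analysis family
uses), with Benjamini–Yekutieli as the conservative alternative. One
caution discovered while testing: the BH step-up adjusted values are
**not idempotent** — re-adjusting an already adjusted vector generally
inflates it (the second pass computes min over j ≥ i of (m/j)² p₍ⱼ₎).
Callers should adjust raw p-values exactly once.

The association test statistic is the mean over query genes of each
gene's mean shortest-path distance to all known disease genes.
Distances default to unweighted hop counts; when confidence weights
are used, edge cost is 1/confidence so higher-confidence links are
shorter. Three conventions, each configurable:

* unreachable disease genes are excluded from a gene's mean rather
  than given a finite penalty (any penalty value would be arbitrary
  and dominate the mean);
* a query gene that is itself a disease gene has its zero
  self-distance excluded;
* the null pool defaults to all network nodes (the natural reference
  when the query is "some gene set on this network"); the enzyme
  background is offered as the stricter pool.

The empirical p is `count(null ≤ observed) / n_perm` with no
smoothing, exactly the resampling definition, so p = 0 is possible; a
(1 + count)/(1 + n_perm) smoothed value is reported alongside for
users who need a strictly positive p.

# The synthetic-data generator

The generator exists so that every stage has inputs with known ground
truth. Its defaults are the package's reference study conditions:
3 datasets; 200 genes (all enzyme-coding, ids shared across every
component); five modules of 20 genes; 20 + 20 samples per dataset; a
2-sd disease shift on module 1's latent factor; within-module
correlation 0.8; 2% missing entries; 5 planted key genes with 8
within-module out-links each; non-key enzymes with 1 + Poisson(0.5)
random out-links (so every enzyme is in the background); 20% of
consumption reactions reversible; 2 currency metabolites placed in 18
reactions each; 30 random annotation terms plus one planted term; and
a 300-node association network at density 0.008 with the key genes
planted adjacent to 10 disease genes.

The expression model is a latent-factor Gaussian: gene g of module m
in sample s is √ρ·f(m, s) + √(1 − ρ)·ε, which produces both the
correlation blocks (correlation ≈ ρ within modules, ≈ 0 between) and
an AUC-detectable shift when module 1's factor gains `effect_size` in
disease samples. With ρ = 0.8 and 40 samples, within-module sample
correlations concentrate near 0.8, so the 0.7 edge threshold recovers
the planted modules while the ≈ 19,900 between-module pairs
essentially never cross it. What the generator does **not** emulate:
probe-level noise structure, batch effects, heavy-tailed expression,
correlated missingness, realistic metabolic topology
(branching/cycles beyond what random consumption induces), or
scale-free association networks. Passing the recovery tests therefore
demonstrates that the machinery is correct and well-calibrated under
its own model assumptions, not that real studies will reach the same
recovery rates.

Every generator is a pure function of its parameters and seed;
`gen_study()` derives per-component seeds from one master seed, and
truth manifests record what was planted.

# Numerical choices and degenerate inputs

* Correlations with zero-variance genes or < 4 shared samples are set
  to 0, never NA, so the edge rule is total.
* The spectral split treats eigenvalues ≤ 1e−9 as indivisible; a
  modularity gain must exceed 1e−10 to accept a split or a merge.
* AUC ties contribute ½ via midranks; samples whose module profile is
  entirely missing are dropped from the AUC.
* Enrichment p-values of exactly 0 (impossible for the hypergeometric,
  possible for user-supplied combiners) are clamped to the smallest
  positive double with a warning before taking logs.
* Proximity ranking breaks distance ties lexicographically by gene id
  so output order is reproducible.
* Pipeline outputs contain no timestamps; reruns with the same
  configuration and seeds are byte-identical.

# Problem sizes used by the test suite

The suite checks statistics against independent oracles (exhaustive
enumeration of hypergeometric draws at N ≤ 12, brute-force
concordant-pair AUC, Floyd–Warshall distances on ≤ 20-node graphs),
and runs resampling calibrations at 200 runs × 200 permutations (null
uniformity, Kolmogorov–Smirnov distance < 0.1) and 100 runs (FDR false
positives). Planted-signal recovery uses 25 replicates of the full
3-dataset study at the reference conditions above and 20 replicates of
the proximity construction at 1000 permutations. These sizes make the
full suite run in well under a minute per file while keeping the
binomial noise of the pass-rate checks small relative to their
margins.

The module-recovery property test (Jaccard ≥ 0.8 and specificity
≥ 0.9 for the planted module in ≥ 90% of 50 replicates) runs at effect
size 2.5 with 25 + 25 samples. At effect 2.0 with 20 + 20 samples the
*expected* module AUC is ≈ 0.92 with a sampling sd of ≈ 0.05
(Hanley–McNeil), so the 0.9 specificity bar would fail in roughly a
third of replicates for purely arithmetic reasons even with perfect
module recovery; the chosen conditions sit inside the regime where the
bound is actually achievable. The end-to-end selection-recovery test
is unaffected and runs at effect 2.0 exactly.

# Known limitations

* The importance combiner and the edge rule are field conventions, not
  identified from data; conclusions can shift with t and the combiner,
  which is why both are mandatory, explicit fields in pipeline
  configurations.
* The modularity partition inherits the resolution limit of Q
  optimization: very small true modules attached to large ones may not
  be separated.
* The overlap-significance test is an approximation (see above).
* SOFT parsing covers the minimal GDS dialect (subset blocks + value
  table); curated annotation lines beyond that are ignored.
* The package predicts candidate drivers; it provides no causal
  inference, and literature-level validation of specific genes is out
  of scope.
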