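---
title: "Consensus signed wTO networks: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus signed wTO networks: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consenet)
```

# What the package computes

`consenet` implements a comparative gene co-expression workflow for
two-condition, multi-dataset bulk RNA-seq designs (case vs control brain
tissue being the motivating setting). The chain is:

1. **Per-dataset signed wTO networks.** Counts are CPM-filtered
   (`cpm_filter()`), normalized by median-of-ratios size factors
   (`median_of_ratios_normalize()`), log2-transformed, and correlated
   gene-by-gene (Pearson). The correlation matrix $A = [a_{ij}]$ is then
   converted to signed weighted topological overlap:
   $$\omega_{ij} = \frac{\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}}
                        {\min(k_i, k_j) + 1 - |a_{ij}|},
     \qquad k_i = \sum_{u \ne i} |a_{iu}|.$$
   A pair's direct correlation is reinforced or contradicted by the
   agreement of their correlations with every shared neighbour; the sign
   is retained. Links with $|\omega| < 0.5$ are discarded
   (`hard_threshold()`; the boundary value is kept, reading "below the
   cutoff is discarded" literally).
2. **Consensus integration.** Same-condition networks from independent
   datasets are intersected (`consensus_integrate()`): a link survives
   only if present in *every* input with a consistent sign, and its
   consensus weight is the strength-weighted average
   $\Omega_{ij} = \sum_k \alpha^k_{ij}\,\omega^k_{ij}$ with
   $\alpha^k_{ij} = |\omega^k_{ij}| / \sum_k |\omega^k_{ij}|$, so strong
   replicated links are not diluted by weak ones. Integration happens
   *after* per-network thresholding.
3. **Differential link classification.** The two condition networks are
   compared link-by-link (`classify_links()`). Genes absent from one
   network re-enter with zero-weight links, so a gene that lost all strong
   correlations in one condition is treated as exactly that rather than as
   missing data. With presence defined as $|\omega| \ge 0.33$ (boundary
   included), links are *conserved* (present in both, same sign),
   *condition-specific* (present in one), or *reversed* (present in both,
   opposite signs).
4. **Topology.** Hub genes are the innermost k-core shell
   (`kcore_decomposition()`; no top-N fallback). Clusters come from
   Louvain modularity maximization on the *unweighted* simple graph at
   resolution 1 (`louvain_clusters()`); clusters with fewer than 20
   internal links are dropped.
5. **Annotation.** Per cluster, protein-coding genes are tested for
   category over-representation with a one-sided hypergeometric test
   against a fixed protein-coding background, BH-adjusted within cluster
   (`cluster_enrichment()`; terms with fewer than 5 background genes are
   excluded). For each significantly enriched category a random walk with
   restart is run on the cluster's unweighted subgraph
   (`rwr_scores()`, restart probability $r = 0.7$, column-normalized
   binary adjacency): lncRNAs at or above the 90th percentile of the
   cluster's lncRNA scores are eligible, and eligibility is accepted only
   if the score clears the leave-one-out floor — the minimum score a
   held-out category gene achieves when its peers act as seeds
   (`loo_threshold()`).
6. **Evaluation statistics.** Szymkiewicz–Simpson overlap coefficients
   with pool-preserving permutation tests (`permutation_overlap_test()`),
   an aggregate per-category consistency test
   (`overlap_consistency_test()`), and Fisher's exact test on core
   lncRNA counts (`core_lncrna_enrichment()`).

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `wto_cutoff` | 0.5 | absolute wTO below which per-dataset links are discarded |
| `diff_cutoff` | 0.33 | presence threshold for differential classification |
| `rwr_restart` | 0.7 | restart probability of the random walk |
| `assign_percentile` | 90 | top tier of cluster lncRNA scores (percent) |
| `min_cluster_links` | 20 | smallest retained Louvain cluster (internal links) |
| `cpm_min`, `cpm_frac` | 1, 0.7 | CPM filter: min CPM in at least this sample fraction |
| `de_fdr`, `de_lfc` | 0.05, 0.3 | DEG thresholds (BH FDR; absolute log2 fold change) |
| `n_perm` | 10000 | permutations for the consistency test |

All of them live in `pipeline_config()` and round-trip through YAML.
Boundary conventions are uniform: thresholds are inclusive
("at least"), so a weight of exactly 0.5 survives filtering and a score
tied at the percentile is eligible.

Two readings were genuinely open and are resolved as follows. The fold
change threshold 0.3 is interpreted on the log2 scale (the convention of
the common DE tools); it is a config knob. "Top 10th percentile" is read
as *score at or above the 90th percentile of the cluster's lncRNA
scores*, computed over lncRNAs only (they are what is being ranked), with
ties included.

# The differential expression stand-in

The pipeline's DEG step is Welch's t-test on `log2(normalized + 1)` with
BH correction and fold changes `log2((mean_B + 0.5)/(mean_A + 0.5))`. It
is a deliberately simple, deterministic engine: the scientific content
this package carries is the *cross-dataset intersection rule*
(`consensus_degs()`: a consensus DEG must be significant with the same
direction in every contributing dataset), not the per-dataset test, and a
negative-binomial GLM engine is out of scope. The stand-in is calibrated
(type-I error at or below nominal on 1000 null genes in the test suite)
and conservative relative to shrinkage-based engines.

# The synthetic study generator

`generate_study()` emulates the study design every downstream stage
expects: three independent datasets per condition from one brain region,
two balanced conditions of 40 samples each, and a gene panel of 220 genes
— four planted co-expression modules of 50 genes plus 20 background
genes, with 25% lncRNAs throughout. Counts are negative binomial
(dispersion 0.05) around `exp(6.5 + 1.0 x)` (median counts ≈ 650), with
library-size factors spanning at most a factor 2, and `x` a per-gene
latent signal: module members load on a per-dataset module eigengene with
latent correlation 0.97, half of them with negative sign (modules are
anti-regulated programs with an up arm and a down arm, which plants
negative links and exercises every signed code path). Eigengenes are
orthogonalized within each dataset: modules are independent pathways by
construction, so no chance eigengene correlation leaks into the planted
structure. A quarter of the modules are *rewired* in condition B: each
member keeps its loading, flips its sign, or detaches
(probabilities 0.2/0.3/0.5), and background genes are recruited — which
plants conserved, reversed, A-specific and B-specific links with known
labels. Protein-coding members of module $m$ define category `CAT_m`;
lncRNA members are the recoverable annotation truth.

Two of these choices deserve their "why". The within-module correlation
(0.97) is set so that planted links populate the regime the 0.5 wTO
filter retains: at a 220-gene panel with 40 samples, the wTO denominator
carries the absolute-correlation mass of every other gene, so only
near-tight modules produce $|\omega| \gtrsim 0.5$ — mirroring real
genome-scale networks, where the surviving links after that filter are
exactly the near-perfect ones. The sign-balanced arms keep the
median-of-ratios size factors honest at panel scale: with mostly
one-signed loadings the per-sample median count ratio would track the
eigengenes themselves and normalization would absorb biological signal —
an artefact of small panels, not of the estimator; balancing the arms
makes the per-sample gene median signal-free, as it is in genome-wide
data where any one module is a tiny minority.

What the generator does **not** emulate: cell-type composition shifts
(deconvolution is out of scope), gene-length or GC effects, batch
structure within a dataset, dispersion trends over the mean, and
genome-scale panels. Passing recovery tests on this generator shows the
pipeline's logic is correct under its assumptions — not that real tissue
data satisfy those assumptions.

Because planted modules are nearly uniform in connectivity, two
quantities degenerate benignly at the defaults: most nodes of a module
share the maximal coreness (the innermost shell is large), and RWR scores
within a module tie almost exactly, so the top-decile rule admits tied
blocks. Both behaviours follow from the definitions; heterogeneous real
networks spread these scores out.

# Numerical choices

* RWR converges by power iteration to L1 change below `1e-10`
  (cap `1e5` iterations, error on failure); the fixed point is unique for
  $r > 0$. Dangling (isolated) nodes teleport their mass to the seed
  distribution, keeping the transition matrix stochastic. Power iteration
  agrees with the direct linear solve to `1e-8` in the test suite.
* wTO is computed densely (one matrix product) with a gene-count guard
  (`max_genes = 5000`) rather than chunked; the package targets
  panel-scale analyses and the synthetic study (220 genes).
* Louvain is order-dependent; the partition is seeded for
  reproducibility, and tests assert modularity properties and planted
  recovery rather than one exact partition.
* Exact zero weights are excluded from consensus integration (the mixing
  factor is undefined when $\sum_k|\omega^k| = 0$); they can only occur
  when thresholding is disabled.
* Permutation p-values are reported as `count/n_perm`, with the
  resolution bound `< 1/n_perm` when no permutation reaches the observed
  statistic. Being discrete, they are conservative
  ($E[p] > 0.5$ under the null), never anti-conservative.
* The Fisher odds ratio is the cross-product ratio (not the conditional
  MLE that `fisher.test()` reports); the p-value is the standard
  two-sided exact test.

# Problem sizes

The test suite and the acceptance script run the full pipeline at the
generator defaults (220 genes, 6 count matrices, 40 samples each; a few
seconds end-to-end), brute-force oracle comparisons on matrices up to 10
genes and graphs up to 50 nodes, a 1000-gene null calibration of the DE
engine, and permutation tests at 200–10000 draws. These sizes were chosen
so every check runs comfortably on a laptop while still exercising each
code path at full stringency.

# Known limitations

* The wTO denominator couples every gene pair to the whole panel's
  correlation mass, so absolute weights — and any fixed cutoff — are not
  comparable across panels of very different size.
* The zero-augmentation convention reads "absent after filtering" as
  "no correlation"; a link just under the cutoff in one condition and
  just over in the other is classified condition-specific, which inflates
  specificity near the threshold (the classification cutoff 0.33 sitting
  below the filter cutoff 0.5 mitigates but does not remove this).
* The consensus sign-exclusion rule discards links with discordant signs
  rather than down-weighting them; with noisy inputs this is conservative.
* `plant_differential_expression()` requires the simulation parameters
  carried by synthetic count matrices (it redraws counts at scaled
  negative-binomial means); it is a ground-truth tool, not applicable to
  external data.
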