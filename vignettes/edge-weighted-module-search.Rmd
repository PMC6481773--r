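---
title: "Edge-weighted dense module search: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-weighted dense module search: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Genome-wide association studies (GWAS) of complex traits such as alcohol
dependence yield many weak gene-level signals that rarely replicate across
cohorts, while model-organism expression experiments identify
treatment-responsive genes without saying which of them matter for the human
trait. `ewdms` integrates the two on a protein--protein interaction (PPI)
scaffold: gene-level GWAS p-values become *node weights*, the change in
co-expression between a treatment and a control condition (here, ethanol- vs
saline-exposed recombinant-inbred mouse brain) becomes an *edge weight*, and
a greedy search extracts connected subnetworks ("dense modules") that are
jointly strong on both axes. Redundant significant modules are merged into
*mega-modules*, hub genes are called from within-module centrality, and the
result is validated against an independent GWAS.

# The model

## Weights

For gene $i$ with gene-level GWAS p-value $p_i$, the node weight is the
upper-tail standard-normal quantile

$$z_i = \Phi^{-1}(1 - p_i),$$

so that smaller p-values give larger weights ($p = 0.5 \mapsto z = 0$).
P-values are clipped to $[10^{-16}, 1 - 10^{-16}]$ to keep $z$ finite.

For an edge $(i, j)$ of the background network, Pearson correlations
$r^{(c)}_{ij}$ and $r^{(t)}_{ij}$ of the two genes' expression across
strains are computed separately in the control and treatment panels and
contrasted on the Fisher-z scale:

$$w_{ij} = \frac{\left| \operatorname{atanh} r^{(t)}_{ij}
  - \operatorname{atanh} r^{(c)}_{ij} \right|}
  {\sqrt{1/(n_t - 3) + 1/(n_c - 3)}}.$$

The standardization puts edge weights on a z-like scale commensurate with
the node weights; under the null of no correlation change, $w$ is
approximately half-normal. A raw $|r^{(t)} - r^{(c)}|$ variant is available
via `edge_weights(mode = "raw")`. Correlations are clipped to
$\pm(1 - 10^{-12})$ before `atanh`; a zero-variance gene contributes
correlation 0 and the event is logged.

## Module score and balance

A module with genes $G$ ($k = |G|$) and induced edges $E$ ($m = |E|$) has
raw score

$$S_m = \lambda \frac{\sum_{i \in G} z_i}{\sqrt{k}}
  + (1 - \lambda) \frac{\sum_{e \in E} w_e}{\sqrt{m}},$$

with the edge term absent when $m = 0$. The balance factor

$$\lambda = \frac{\overline{|w|}}{\overline{|z|} + \overline{|w|}}$$

is computed once from all background weights before any search, so that
$\lambda\,\overline{|z|} = (1 - \lambda)\,\overline{|w|}$: the expected
per-element contributions of the two weight classes are equalized and
neither nodes nor edges can dominate by scale alone.

## Standardization

Inside the greedy loop, scores are standardized analytically, treating a
$(k, m)$ module's weights as i.i.d. draws from the background weight
populations:

$$S_n = \frac{S_m - \left[\lambda \sqrt{k}\, \mu_z
  + (1 - \lambda) \sqrt{m}\, \mu_w\right]}
  {\sqrt{\lambda^2 \sigma_z^2 + (1 - \lambda)^2 \sigma_w^2}}.$$

A Monte-Carlo mode estimates the same moments from random modules of $k$
genes plus $m$ edges drawn uniformly without replacement
(`standardize_score(..., standardization = "montecarlo")`); with finite
background populations the i.i.d. approximation errs only by the
without-replacement correction $(N - k)/(N - 1)$, and the two modes agree
closely (median $|\Delta S_n|$ well under 0.15 at $B = 20{,}000$ on the
default synthetic network — recomputed by `scripts/acceptance.R` as
`sn_standardization_gap_median`). Per-step permutation inside the greedy
loop would be computationally prohibitive, which is why the analytic form is
the default.

## Greedy growth

From every seed gene, the module grows by repeatedly evaluating all
background neighbors of the current module (candidate distance 1) together
with every edge they contribute into it. The neighbor maximizing the new
$S_n$ is admitted if it improves the score by at least the growth rate
$r = 0.005$ (0.5%): $S_n^{new} \ge S_n^{old}(1 + r)$ when $S_n^{old} > 0$.
The multiplicative rule is ill-defined at non-positive scores, where the
additive margin $S_n^{new} \ge S_n^{old} + |S_n^{old}|\,r$ is used instead.
Ties are broken by the higher node weight, then the lexicographically
smaller symbol, making the search fully deterministic. Modules smaller than
5 genes are not reported (configurable).

## Significance, merging, hubs

Module significance compares the observed $S_m$ with $B$ random modules of
the same $(k, m)$ drawn by the null sampler above; the empirical p-value
uses the positively biased but zero-avoiding estimator $(b + 1)/(B + 1)$,
and q-values are Benjamini--Hochberg across all modules with significance at
$q < 0.05$. Null modules are unconstrained node/edge draws rather than
connected subgraphs: connected-subgraph sampling concentrates on hubs and is
not what the score's standardization assumes; it can be emulated by scoring
user-drawn connected sets, but is deliberately not the default.

Significant modules are merged iteratively: percent overlap is
$|A \cap B| / \min(|A|, |B|)$, and while any pair overlaps strictly above
0.8 the maximal-overlap pair is merged (gene union, background-induced
edges) and all overlaps are recomputed. Always merging the current maximal
pair makes the procedure deterministic and order-independent for transitive
overlap clusters; equality at exactly 0.8 does not merge. Merged sets are
rescored with the identical scoring and significance machinery (MM-$S_n$).

Within each mega-module's induced subgraph, connectivity $k_i$ is the
degree and eigencentrality $EC_i$ is the leading adjacency eigenvector,
computed by power iteration on $A + I$ (same Perron vector as $A$; the
shift avoids the two-cycling of bipartite adjacency spectra) to tolerance
$10^{-10}$, normalized so $\max EC = 1$. On a disconnected subgraph the
dominant component carries the mass and the event is logged. A gene is a
*hub* when $EC_i > 0.2$ and $k_i$ is at or above the third quartile of the
module's degrees (linear-interpolation quantile; the convention is not
dictated by the method).

## Validation and enrichment

Genes with validation-GWAS $p < 0.001$ (strict) are "nominal". Each
mega-module containing more than one nominal gene is tested by drawing
10,000 uniform same-size gene sets from the background; the empirical
overrepresentation p uses $(b+1)/(B+1)$ and the per-region significance
threshold is $0.05/n$ with $n$ the number of mega-modules actually tested
in that region (the count of modules tested, not of all modules, is the
denominator used throughout; both interpretations are trivially recovered
by changing $n$). Ordinary least squares of each mega-module's mean
validation p-value on MM-$S_n$ tests score-based prioritization, at
Bonferroni threshold $0.05/3$ for three brain regions; genes absent from
the validation study are excluded from the mean and logged. Pairs of
mega-modules are compared by the upper-tail hypergeometric probability of
their gene overlap given the background size. Over-representation analysis
against GMT annotation sets uses the one-sided hypergeometric tail with
report filters $p < 0.01$, $\ge 3$ hit genes, set size $\le 1000$, and a
Bonferroni factor equal to the number of sets tested within the set's
category.

# The synthetic-data generator

Every stage is exercised on generated data with known ground truth
(`synthetic_config()`, `generate_bundle()`):

* **PPI** — Barabási–Albert preferential attachment (`attach_m = 3` edges
  per node, 2,000 genes), matching the heavy-tailed degree structure of
  real interactomes; a randomly placed planted gene set (40 genes) is
  densified to edge density 0.3 and connected.
* **GWAS** — planted genes draw $p \sim \mathrm{Beta}(\alpha, 1)$ with
  $\alpha = 0.1$; background genes are uniform; $\alpha = 1$ is the exact
  null. Two independent tables (discovery and validation) share the planted
  set, emulating partially concordant cohorts.
* **Expression** — a latent-factor construction: all genes load
  $\sqrt{\rho_{base}}$ ($\rho_{base} = 0.2$) on a strain-level global
  factor; in the treatment condition only, planted genes additionally load
  $\sqrt{\Delta\rho}$ ($\Delta\rho = 0.6$) on a planted factor. The implied
  covariance is positive semi-definite by construction for
  $0 \le \rho_{base}$, $0 \le \Delta\rho$,
  $\rho_{base} + \Delta\rho < 1$; anything else is rejected rather than
  repaired. 30 strains per condition mirror the 27--35 recombinant-inbred
  lines of the emulated panels.
* **S-scores** — a responsive gene set (the planted genes plus random
  background genes up to `responsive_frac = 0.5` of the universe) has
  probesets shifted by $\pm 3$ (direction per probeset); the rest are
  standard normal, the S-score's null reference. Treatment responsiveness
  is deliberately common — in the emulated study roughly a third of all
  probesets passed the responsiveness filter — so the background network
  after filtering is large and the planted disease module is a small subset
  of it, not the whole background.

What the generator does **not** emulate: probe-level microarray intensity
structure, eQTL or LD architecture, correlated null genes (background genes
are exchangeable), region-to-region correlation (each region is generated
independently), and realistic gene-symbol vocabularies (symbols are
`G000001`…, with an identity homolog map so the mapping code path still
runs). Passing tests therefore demonstrate correctness and calibration of
the machinery under a clean planted-signal model, not performance on real
microarray/GWAS data.

# Numerical and design choices

* **Responsiveness permutation null.** Per-strain two-sided p-values from
  the standard-normal S-score reference are Fisher-combined across strains;
  the empirical null permutes each strain's column of S-scores across
  probesets. A sign-flip null is unavailable here: the combined statistic
  depends on $|s|$ only and is sign-invariant. Column permutation preserves
  each strain's empirical S-score distribution (including departures from
  N(0,1)) while breaking probeset identity.
* **Empirical p-values** always use $(b+1)/(B+1)$, avoiding zero and
  matching the permutation-test bias correction.
* **Probeset collapse** keeps, per gene, the probeset with the highest mean
  expression over all strains of the region, both conditions; ties break to
  the lexicographically smallest probeset id.
* **Homolog collisions** (two sources, one target) keep the source with the
  higher mean expression and log the event.
* **Isolated nodes** are removed from the background: a degree-0 gene can
  never join an edge-weighted module.
* **Growth at non-positive scores** uses the additive $|S_n^{old}|\,r$
  margin (see above).
* **Seeding.** Every generator and permutation routine is a pure function
  of its inputs and a seed; the pipeline derives per-stage sub-streams from
  one global seed, so reruns are checksum-identical.

# Problem sizes

The shipped analysis and the acceptance script run the full pipeline at the
default scale (2,000 genes, ~6,200 interactions, 30+30 strains, 4,000
probesets with 1,000 permutations, module significance at $B = 1000$,
overrepresentation at $B = 10{,}000$), which completes in a few minutes on
one core. The test suite uses 300-gene networks for integration tests and
the full scale for the recovery and calibration checks. These sizes were
chosen to keep a complete run interactive while leaving all constants of
the method (thresholds, growth rate, permutation counts) at their
production values.

# Known limitations

* Greedily grown modules are score-selected, so their permutation p-values
  against random same-size modules are anticonservative by construction —
  a property of this class of methods, not of the implementation; the
  calibration suite therefore certifies the significance machinery on
  null-drawn modules, where p-values are uniform.
* The analytic standardization assumes node and edge weights are sampled
  independently of topology; for modules concentrated on hubs of very
  heterogeneous networks the Monte-Carlo mode is the safer reference.
* The regression of mean validation p on MM-$S_n$ treats mega-modules as
  independent observations, though merged modules share genes.
* Eigencentrality on disconnected induced subgraphs is reported for the
  dominant component; genes of minor components get near-zero EC and are
  never hubs.
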