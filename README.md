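# ewdms — edge-weighted dense module search for GWAS × differential co-expression

`ewdms` finds disease-associated gene networks by integrating three data
types on a protein–protein interaction (PPI) scaffold:

* **gene-level GWAS p-values** become node weights
  `z_i = Φ⁻¹(1 − p_i)` — more associated genes weigh more;
* **two-condition expression panels** (e.g. ethanol- vs saline-exposed
  recombinant-inbred mouse brain, strains as replicates) become edge
  weights — the Fisher-z standardized absolute change in a gene pair's
  co-expression, `w = |atanh r_trt − atanh r_ctrl| / √(1/(n_t−3) + 1/(n_c−3))`;
* **a PPI network** restricts the search to biologically plausible
  neighborhoods.

A module with `k` genes and `m` induced edges scores

```
S_m = λ · Σz / √k + (1 − λ) · Σw / √m,
λ   = mean|w| / (mean|z| + mean|w|)
```

with λ fixed once from all background weights so neither weight class
dominates. From every seed gene a connected module is grown greedily,
admitting the neighbor that maximizes the standardized score `S_n`
(standardized against same-size random node/edge draws) whenever it
improves `S_n` by ≥ 0.5%. Module significance is permutation-based
(empirical `q_FDR < 0.05`); significant modules overlapping > 80% of the
smaller module are merged into **mega-modules**, which are rescored, probed
for **hub genes** (eigencentrality > 0.2 and top-quartile connectivity),
validated against an independent GWAS (nominal-gene overrepresentation by
permutation, regression of mean validation p on MM-S_n, hypergeometric
mega-module overlap), and profiled by hypergeometric over-representation
analysis against GMT annotation sets.

The package is aimed at systems-biology analysts who want this class of
cross-species network integration as tested, seeded, reusable functions. A
synthetic-data generator with planted signal (`generate_bundle()`) makes
every stage verifiable end to end: the planted module carries low GWAS
p-values (Beta(0.1, 1)), a treatment-only co-expression shift
(Δρ = 0.6 at 30+30 strains), and shifted S-scores, on a 2,000-gene
scale-free network.

## Worked example

```r
library(ewdms)

cfg  <- synthetic_config(seed = 1)          # 2000 genes, 40 planted
ppi  <- generate_ppi(cfg)
gwas <- generate_gwas(ppi$truth)
expr <- generate_expression(ppi$truth)

bg <- build_background(ppi$graph, names(gwas), rownames(expr$control$values))
wn <- build_weighted_network(bg, gwas, expr$control, expr$treatment)
print(wn)
#> weighted_network: 2000 genes, 6224 edges, lambda = 0.5089
#>   z: mean 0.1024 sd 1.1075 | w: mean 0.8800 sd 0.7463

mods <- search_all(wn)                      # one greedy module per seed gene
print(mods[[1]])
#> module [seed G001876]: k = 60 genes, m = 236 edges, S_m = 30.8268, S_n = 35.3769

top5    <- unique(unlist(lapply(mods[1:5], `[[`, "genes")))
planted <- ppi$truth$planted_genes
sprintf("top-5 union: %d genes | planted recall %.2f, precision %.2f",
        length(top5), length(intersect(top5, planted)) / length(planted),
        length(intersect(top5, planted)) / length(top5))
#> "top-5 union: 69 genes | planted recall 0.95, precision 0.55"
```

λ ≈ 0.51 says node and edge weights contribute about equally; the top
module (S_n ≈ 35) is dominated by planted genes, and the union of the five
best modules recovers 95% of the planted set.

Continue to significance, mega-modules and validation:

```r
mods <- module_significance(mods, wn, B = 1000, seed = 2)
sig  <- mods[attr(mods, "significant")]           # empirical q < 0.05
mms  <- score_megamodules(merge_modules(sig), wn, B = 1000, seed = 3)
cent <- module_centralities(mms[[1]]$genes, bg)
call_hubs(cent)                                   # EC > 0.2 & top-quartile k

val  <- generate_gwas(ppi$truth, seed = 99)       # independent validation GWAS
nom  <- nominal_genes(val, 0.001, background = wn$genes)
overrep_test(mms[[1]]$genes, nom, wn$genes, B = 10000, seed = 4)
score_regression(mms, val)                        # beta < 0: scores prioritize
```

## The analysis workflow

`analysis/01_simulate.R` … `05_validate_enrich.R` run the complete study
pipeline on a generated bundle, writing tables under `results/analysis/`:
responsiveness calls (Fisher-combined S-scores against a permutation null,
`q < 0.1` in any region), the background network (PPI ∩ GWAS ∩ responsive
expression genes), the module table, the mega-module table with per-gene
centralities and hubs, and the validation/enrichment report. Each script
prints what it found; `run_pipeline()` performs the same orchestration as a
single seeded call with a JSON provenance manifest.

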