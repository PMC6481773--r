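#!/usr/bin/env Rscript
# Stage 1: generate the synthetic input bundle with planted structure.
#
# Writes, under results/analysis/bundle/: a scale-free PPI edge list, two
# gene-level GWAS tables (discovery and validation), control/treatment
# expression panels for one region, a probeset-level S-score panel with its
# probeset-to-gene map, an identity homolog map, GMT annotation sets, and
# the ground-truth file naming the planted genes.

suppressMessages(library(ewdms))

seed <- 101L
dir <- "results/analysis/bundle"
cfg <- synthetic_config(seed = seed)
bundle <- generate_bundle(cfg, dir)

cat("Synthetic bundle written to", dir, "\n")
cat(sprintf("  PPI: %d genes, %d interactions\n",
            igraph::vcount(bundle$graph), igraph::ecount(bundle$graph)))
cat(sprintf("  planted module: %d genes, induced density %.2f\n",
            length(bundle$truth$planted_genes),
            igraph::ecount(igraph::induced_subgraph(
              bundle$graph, bundle$truth$planted_genes)) /
              choose(length(bundle$truth$planted_genes), 2)))
cat(sprintf("  strains: %d control + %d treatment; %d probesets\n",
            ncol(bundle$expression$control$values),
            ncol(bundle$expression$treatment$values),
            nrow(bundle$sscores$scores)))
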