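#!/usr/bin/env Rscript
# Stage 2: ethanol-responsiveness calls and background-network construction.
#
# Per-probeset S-scores are combined across strains by Fisher's method,
# referred to a within-strain permutation null, BH-adjusted, and filtered at
# q < 0.1 (any region). Responsive probesets are mapped to genes, the
# expression panels are homolog-mapped, and the background network is the
# PPI induced on genes present in the PPI, the discovery GWAS and the
# responsive expression set (isolated nodes dropped).

suppressMessages(library(ewdms))

bundle <- "results/analysis/bundle"
out <- "results/analysis"
seed <- 102L

panel <- read_sscore_panel(file.path(bundle, "sscores_SYN.tsv"), "SYN")
calls <- responsive_calls(panel, n_perm = 1000L, seed = seed)
write.table(calls, file.path(out, "responsive_calls.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
responsive_ps <- filter_responsive(calls, 0.1)
pmap <- read_probeset_map(file.path(bundle, "probeset_map.tsv"))
responsive_genes <- unique(pmap$gene[pmap$probeset %in% responsive_ps])
cat(sprintf("responsive: %d / %d probesets (q < 0.1), %d genes\n",
            length(responsive_ps), nrow(calls), length(responsive_genes)))

panels <- map_homologs(
  list(control = read_expression_matrix(
         file.path(bundle, "expr_SYN_control.tsv"), "SYN", "control"),
       treatment = read_expression_matrix(
         file.path(bundle, "expr_SYN_treatment.tsv"), "SYN", "treatment")),
  read_homolog_map(file.path(bundle, "homolog_map.tsv")))
ppi <- read_edge_list(file.path(bundle, "ppi_edges.tsv"))
gwas <- read_gwas_table(file.path(bundle, "gwas_discovery.tsv"))

bg <- build_background(ppi, names(gwas),
                       intersect(rownames(panels$control$values),
                                 responsive_genes))
write_edge_list(bg, file.path(out, "background_edges.tsv"))
cat(sprintf("background network: %d genes, %d interactions -> %s\n",
            igraph::vcount(bg), igraph::ecount(bg),
            file.path(out, "background_edges.tsv")))
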