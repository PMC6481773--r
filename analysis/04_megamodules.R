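#!/usr/bin/env Rscript
# Stage 4: mega-modules and hub genes.
#
# Significant modules overlapping by more than 80% of the smaller module are
# merged iteratively; merged sets are rescored with the identical machinery
# (MM-S_n, empirical q), and per-gene within-module connectivity and
# eigencentrality identify hubs (EC > 0.2 and degree in the top quartile).

suppressMessages(library(ewdms))

bundle <- "results/analysis/bundle"
out <- "results/analysis"
seed <- 104L

bg <- read_edge_list(file.path(out, "background_edges.tsv"))
gwas <- read_gwas_table(file.path(bundle, "gwas_discovery.tsv"))
gwas_val <- read_gwas_table(file.path(bundle, "gwas_validation.tsv"))
panels <- map_homologs(
  list(control = read_expression_matrix(
         file.path(bundle, "expr_SYN_control.tsv"), "SYN", "control"),
       treatment = read_expression_matrix(
         file.path(bundle, "expr_SYN_treatment.tsv"), "SYN", "treatment")),
  read_homolog_map(file.path(bundle, "homolog_map.tsv")))
wn <- build_weighted_network(bg, gwas, panels$control, panels$treatment)

mods <- read_modules(file.path(out, "modules_SYN.tsv"))
sig <- Filter(function(m) !is.null(m$q) && !is.na(m$q) && m$q < 0.05, mods)
mms <- merge_modules(sig, threshold = 0.8)
mms <- score_megamodules(mms, wn, B = 1000L, seed = seed)
cat(sprintf("%d significant modules merged into %d mega-modules\n",
            length(sig), length(mms)))

tab <- megamodules_to_table(mms, bg, gwas, gwas_val)
write.table(tab, file.path(out, "megamodules_SYN.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
for (mm in mms[seq_len(min(3, length(mms)))]) {
  cent <- module_centralities(mm$genes, bg)
  hubs <- call_hubs(cent)
  cat(sprintf("  %s: k_g = %d, MM-S_n = %.2f, q = %.3g, hubs: %s\n",
              mm$name, mm$k, mm$S_n, mm$q,
              paste(utils::head(hubs, 5), collapse = ", ")))
}
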