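#!/usr/bin/env Rscript
# Stage 5: validation against the independent GWAS, and enrichment.
#
# Nominal genes (validation p < 0.001) are tested for overrepresentation in
# each mega-module carrying more than one of them (10,000 permutations of
# same-size gene sets; per-region threshold 0.05 / number tested); linear
# regression tests whether MM-S_n predicts mean validation p (Bonferroni
# threshold 0.05/3); the two top mega-modules are compared by a
# hypergeometric overlap test; overrepresented mega-modules are profiled
# against the GMT annotation sets by hypergeometric ORA (p < 0.01, >= 3
# hits, set size <= 1000).

suppressMessages(library(ewdms))

bundle <- "results/analysis/bundle"
out <- "results/analysis"
seed <- 105L

bg <- read_edge_list(file.path(out, "background_edges.tsv"))
bg_genes <- igraph::V(bg)$name
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
mms <- score_megamodules(merge_modules(sig), wn, B = 1000L, seed = 104L)

nominal <- nominal_genes(gwas_val, 0.001, background = bg_genes)
cat(sprintf("validation-nominal genes in background: %d\n", length(nominal)))

tested <- Filter(function(mm) length(intersect(mm$genes, nominal)) > 1L, mms)
thr <- if (length(tested)) 0.05 / length(tested) else NA
over <- lapply(tested, function(mm) {
  ot <- overrep_test(mm$genes, nominal, bg_genes, B = 10000L, seed = seed)
  cat(sprintf("  %s: %d nominal genes, overrep p = %.4g (threshold %.3g)\n",
              mm$name, ot$observed, ot$p, thr))
  list(name = mm$name, observed = ot$observed, p = ot$p,
       significant = ot$p < thr)
})

fit <- tryCatch(score_regression(mms, gwas_val), error = function(e) NULL)
if (!is.null(fit))
  cat(sprintf("MM-S_n ~ mean validation p: beta = %.4g, p = %.3g (%s at %.3f)\n",
              fit$beta, fit$p,
              if (fit$significant) "significant" else "not significant",
              fit$threshold))

if (length(mms) >= 2) {
  ovp <- overlap_test(mms[[1]]$genes, mms[[2]]$genes, length(bg_genes))
  cat(sprintf("overlap of %s and %s: %d genes, hypergeometric p = %.3g\n",
              mms[[1]]$name, mms[[2]]$name,
              length(intersect(mms[[1]]$genes, mms[[2]]$genes)), ovp))
}

sets <- read_gmt(file.path(bundle, "annotation_sets.gmt"))
enr <- do.call(rbind, lapply(Filter(function(o) o$significant, over),
  function(o) {
    mm <- mms[[which(vapply(mms, `[[`, "", "name") == o$name)]]
    tab <- ora_enrichment(mm$genes, sets, bg_genes)
    if (nrow(tab)) cbind(megamodule = o$name, tab) else NULL
  }))
if (!is.null(enr) && nrow(enr)) {
  write.table(enr, file.path(out, "enrichment_SYN.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("enrichment: %d set(s) pass the filters; top: %s (p = %.3g)\n",
              nrow(enr), enr$set[1], enr$p[1]))
} else cat("enrichment: no annotation set passes the filters\n")

report <- list(nominal = length(nominal), overrepresentation = over,
               regression = if (is.null(fit)) NULL else
                 fit[c("beta", "p", "threshold", "significant", "n")])
jsonlite::write_json(report, file.path(out, "validation_SYN.json"),
                     auto_unbox = TRUE, digits = NA, null = "null")
cat("validation report ->", file.path(out, "validation_SYN.json"), "\n")
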