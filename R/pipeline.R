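# End-to-end pipeline driver: preprocess -> weighted network -> module
# search -> significance -> mega-module merge -> rescoring -> hubs ->
# cross-GWAS validation -> enrichment, with a JSON manifest for provenance.

#' Pipeline configuration
#'
#' Collects the input location, the region labels, every stage threshold and
#' the global seed. All parameters are echoed into the output manifest.
#'
#' @param input_dir directory holding the standard input bundle (see
#'   [generate_bundle()] for the file conventions).
#' @param output_dir directory for stage artifacts (created if missing).
#' @param regions character vector of region labels; default: inferred from
#'   `expr_<region>_control.tsv` files in `input_dir`.
#' @param growth_rate greedy growth rule (default 0.005).
#' @param min_module_size smallest reported module (default 5).
#' @param overlap_threshold mega-module merge threshold (default 0.8).
#' @param responsive_q responsiveness FDR threshold (default 0.1).
#' @param responsive_perms permutations for responsiveness calls
#'   (default 1000).
#' @param module_q module/mega-module significance threshold (default 0.05).
#' @param module_perms null draws for module significance (default 1000).
#' @param nominal_p validation nominal threshold (default 0.001).
#' @param overrep_B overrepresentation permutations (default 10000).
#' @param ec_hub eigencentrality hub cutoff (default 0.2).
#' @param edge_mode `"fisherz"` or `"raw"` edge weights.
#' @param apply_responsive_filter restrict the expression universe to
#'   responsive genes before building the background (default TRUE).
#' @param graphml also export each mega-module as GraphML (default FALSE).
#' @param seed global integer seed; every stage derives its own sub-stream.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            regions = NULL,
                            growth_rate = 0.005, min_module_size = 5L,
                            overlap_threshold = 0.8, responsive_q = 0.1,
                            responsive_perms = 1000L, module_q = 0.05,
                            module_perms = 1000L, nominal_p = 0.001,
                            overrep_B = 10000L, ec_hub = 0.2,
                            edge_mode = "fisherz",
                            apply_responsive_filter = TRUE,
                            graphml = FALSE, seed = 1L) {
  for (v in c(overlap_threshold, responsive_q, module_q, nominal_p, ec_hub))
    if (v <= 0 || v >= 1) stop("thresholds must lie in (0, 1)")
  if (growth_rate <= 0) stop("growth_rate must be positive")
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 regions = regions, growth_rate = growth_rate,
                 min_module_size = as.integer(min_module_size),
                 overlap_threshold = overlap_threshold,
                 responsive_q = responsive_q,
                 responsive_perms = as.integer(responsive_perms),
                 module_q = module_q,
                 module_perms = as.integer(module_perms),
                 nominal_p = nominal_p, overrep_B = as.integer(overrep_B),
                 ec_hub = ec_hub, edge_mode = edge_mode,
                 apply_responsive_filter = isTRUE(apply_responsive_filter),
                 graphml = isTRUE(graphml), seed = as.integer(seed)),
            class = "pipeline_config")
}

bundle_regions <- function(input_dir) {
  f <- list.files(input_dir, pattern = "^expr_.*_control\\.tsv$")
  sub("^expr_(.*)_control\\.tsv$", "\\1", f)
}

read_bundle_inputs <- function(config) {
  ind <- config$input_dir
  need <- c("ppi_edges.tsv", "gwas_discovery.tsv", "gwas_validation.tsv",
            "probeset_map.tsv", "homolog_map.tsv")
  for (f in need)
    if (!file.exists(file.path(ind, f)))
      stop("missing input file: ", file.path(ind, f))
  regions <- config$regions %||% bundle_regions(ind)
  if (length(regions) == 0L) stop("no expression files found in ", ind)
  expr <- lapply(stats::setNames(regions, regions), function(rg) {
    list(control = read_expression_matrix(
           file.path(ind, sprintf("expr_%s_control.tsv", rg)), rg, "control"),
         treatment = read_expression_matrix(
           file.path(ind, sprintf("expr_%s_treatment.tsv", rg)), rg,
           "treatment"))
  })
  sscores <- lapply(stats::setNames(regions, regions), function(rg) {
    f <- file.path(ind, sprintf("sscores_%s.tsv", rg))
    if (file.exists(f)) read_sscore_panel(f, region = rg) else NULL
  })
  gmt_path <- file.path(ind, "annotation_sets.gmt")
  list(ppi = read_edge_list(file.path(ind, "ppi_edges.tsv")),
       gwas_discovery = read_gwas_table(file.path(ind, "gwas_discovery.tsv")),
       gwas_validation = read_gwas_table(file.path(ind, "gwas_validation.tsv")),
       probeset_map = read_probeset_map(file.path(ind, "probeset_map.tsv")),
       homolog_map = read_homolog_map(file.path(ind, "homolog_map.tsv")),
       expression = expr, sscores = sscores, regions = regions,
       annotation_sets = if (file.exists(gmt_path)) read_gmt(gmt_path)
                         else NULL)
}

#' Run the full pipeline on an input bundle
#'
#' Orchestrates, per region: responsiveness calls and the q-filter on the
#' S-score panel, homolog mapping of the expression panels, background
#' construction (PPI intersect discovery-GWAS intersect responsive
#' expression genes), weighted-network assembly, greedy module search,
#' permutation significance, mega-module merging and rescoring, hub calls,
#' validation against the second GWAS (nominal-gene overrepresentation and
#' score regression) and, when annotation sets are present, hypergeometric
#' enrichment of overrepresented mega-modules. Stage tables are written as
#' TSV under `output_dir` and a JSON manifest records parameters, seeds, row
#' counts and file checksums. An empty stage (e.g. no responsive gene
#' reaches the background) short-circuits the downstream stages with empty
#' outputs rather than failing.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  clear_events()
  if (!dir.exists(config$output_dir))
    dir.create(config$output_dir, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, ...)
  inputs <- read_bundle_inputs(config)
  manifest <- list(package_version = as.character(utils::packageVersion("ewdms")),
                   parameters = unclass(config), regions = inputs$regions,
                   counts = list(), files = character())

  # responsiveness: calls per region, any-region union filter
  calls <- NULL
  if (config$apply_responsive_filter) {
    calls <- do.call(rbind, lapply(inputs$regions, function(rg) {
      if (is.null(inputs$sscores[[rg]])) return(NULL)
      responsive_calls(inputs$sscores[[rg]],
                       n_perm = config$responsive_perms,
                       seed = child_seed(config$seed, 21L))
    }))
  }
  if (!is.null(calls)) {
    utils::write.table(calls, out("responsive_calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    responsive_ps <- filter_responsive(calls, config$responsive_q)
    responsive_genes <- unique(inputs$probeset_map$gene[
      inputs$probeset_map$probeset %in% responsive_ps])
    manifest$counts$responsive_probesets <- length(responsive_ps)
    manifest$counts$responsive_genes <- length(responsive_genes)
  } else responsive_genes <- NULL

  results <- list()
  for (rg in inputs$regions) {
    panels <- map_homologs(inputs$expression[[rg]], inputs$homolog_map)
    expr_genes <- rownames(panels$control$values)
    if (!is.null(responsive_genes))
      expr_genes <- intersect(expr_genes, responsive_genes)
    bg <- tryCatch(build_background(inputs$ppi,
                                    names(inputs$gwas_discovery), expr_genes),
                   error = function(e) NULL)
    if (is.null(bg)) {
      log_event("region ", rg, ": empty background; downstream skipped")
      write_modules(structure(list(), class = "ew_module_list"),
                    out(sprintf("modules_%s.tsv", rg)))
      results[[rg]] <- list(n_modules = 0L, n_significant = 0L,
                            n_megamodules = 0L, n_overrepresented = 0L)
      next
    }
    wn <- build_weighted_network(bg, inputs$gwas_discovery,
                                 panels$control, panels$treatment,
                                 edge_mode = config$edge_mode)
    params <- search_params(growth_rate = config$growth_rate,
                            min_module_size = config$min_module_size,
                            seed = child_seed(config$seed, 31L))
    mods <- search_all(wn, params)
    mods <- module_significance(mods, wn, B = config$module_perms,
                                seed = child_seed(config$seed, 32L),
                                q_threshold = config$module_q)
    write_modules(mods, out(sprintf("modules_%s.tsv", rg)))
    sig <- mods[attr(mods, "significant")]
    mms <- merge_modules(sig, threshold = config$overlap_threshold)
    mms <- score_megamodules(mms, wn, B = config$module_perms,
                             seed = child_seed(config$seed, 33L))
    mm_table <- megamodules_to_table(mms, bg, inputs$gwas_discovery,
                                     inputs$gwas_validation)
    utils::write.table(mm_table, out(sprintf("megamodules_%s.tsv", rg)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (config$graphml)
      for (mm in mms)
        write_module_graphml(mm$genes, wn,
                             out(sprintf("megamodule_%s_%s.graphml", rg,
                                         mm$name)))

    # validation against the independent GWAS
    bg_genes <- igraph::V(bg)$name
    nominal <- nominal_genes(inputs$gwas_validation, config$nominal_p,
                             background = bg_genes)
    tested <- Filter(function(mm)
      length(intersect(mm$genes, nominal)) > 1L, mms)
    over <- lapply(tested, function(mm) {
      ot <- overrep_test(mm$genes, nominal, bg_genes, B = config$overrep_B,
                         seed = child_seed(config$seed, 34L))
      list(name = mm$name, observed = ot$observed, p = ot$p)
    })
    over_thr <- if (length(tested)) 0.05 / length(tested) else NA_real_
    over_sig <- Filter(function(o) o$p < over_thr, over)
    reg <- tryCatch(score_regression(mms, inputs$gwas_validation),
                    error = function(e) NULL)

    enrich <- NULL
    if (!is.null(inputs$annotation_sets) && length(over_sig)) {
      enrich <- do.call(rbind, lapply(over_sig, function(o) {
        mm <- mms[[which(vapply(mms, `[[`, "", "name") == o$name)]]
        tab <- ora_enrichment(mm$genes, inputs$annotation_sets, bg_genes)
        if (nrow(tab)) cbind(megamodule = o$name, tab) else NULL
      }))
      if (!is.null(enrich))
        utils::write.table(enrich, out(sprintf("enrichment_%s.tsv", rg)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    val <- list(region = rg, n_nominal = length(nominal),
                n_megamodules_tested = length(tested),
                overrep_threshold = over_thr,
                overrep = over,
                n_overrepresented = length(over_sig),
                regression = if (is.null(reg)) NULL else
                  reg[c("beta", "p", "threshold", "significant", "n")])
    jsonlite::write_json(val, out(sprintf("validation_%s.json", rg)),
                         auto_unbox = TRUE, digits = NA, null = "null")
    results[[rg]] <- list(n_modules = length(mods),
                          n_significant = length(sig),
                          n_megamodules = length(mms),
                          n_overrepresented = length(over_sig),
                          lambda = wn$lambda)
  }
  manifest$counts$regions <- results
  manifest$events <- get_events()
  files <- list.files(config$output_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$files <- lapply(stats::setNames(files, basename(files)),
                           function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
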