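# Synthetic-data generators with planted structure.
#
# The generators emulate the inputs of a cross-species network integration
# study: a scale-free protein-protein interaction (PPI) graph, two gene-level
# GWAS summary tables, a two-condition (control vs treatment) strain-by-gene
# expression panel for one brain region, and a probeset-level S-score panel.
# A "planted" gene set carries all three signals -- low GWAS p-values,
# treatment-specific co-expression, and shifted S-scores -- so every
# downstream stage has ground truth to be scored against.

#' Configuration for the synthetic-data generators
#'
#' Defaults describe the study conditions the generators emulate: a BXD-like
#' panel of 30 strains per condition, a few-thousand-gene scale-free PPI, and
#' a planted module of 40 genes carrying node signal (`gwas_alpha`), edge
#' signal (`delta_rho`) and differential-expression signal (`sscore_shift`).
#'
#' @param n_genes number of genes in the PPI universe.
#' @param attach_m preferential-attachment edges added per new node.
#' @param n_strains_ctrl,n_strains_trt strains per condition (>= 4).
#' @param planted_size number of planted genes.
#' @param planted_density target edge density of the planted subgraph, in
#'   `[0, 1]`.
#' @param gwas_alpha Beta(alpha, 1) shape for planted-gene GWAS p-values, in
#'   `(0, 1]`; `1` is the uniform null.
#' @param rho_base baseline pairwise expression correlation (all gene pairs,
#'   both conditions); must be in `[0, 1)`.
#' @param delta_rho treatment-only correlation increment for planted pairs;
#'   `rho_base + delta_rho` must stay below 1.
#' @param sscore_shift absolute mean S-score of responsive probesets
#'   (non-responsive probesets are standard normal; response direction is
#'   drawn per probeset).
#' @param responsive_frac fraction of all genes that are
#'   treatment-responsive; the planted genes are always responsive and count
#'   towards the fraction. In the emulated study roughly a third of all
#'   probesets were responsive, so responsiveness is common and the planted
#'   disease module is a small subset of it.
#' @param probesets_per_gene probesets mapped to each gene (>= 1).
#' @param region label used for the single synthetic brain region.
#' @param seed integer seed; every generator is deterministic given
#'   `(config, seed)`.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000L, attach_m = 3L,
                             n_strains_ctrl = 30L, n_strains_trt = 30L,
                             planted_size = 40L, planted_density = 0.3,
                             gwas_alpha = 0.1, rho_base = 0.2,
                             delta_rho = 0.6, sscore_shift = 3,
                             responsive_frac = 0.5,
                             probesets_per_gene = 2L, region = "SYN",
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), attach_m = as.integer(attach_m),
              n_strains_ctrl = as.integer(n_strains_ctrl),
              n_strains_trt = as.integer(n_strains_trt),
              planted_size = as.integer(planted_size),
              planted_density = planted_density, gwas_alpha = gwas_alpha,
              rho_base = rho_base, delta_rho = delta_rho,
              sscore_shift = sscore_shift,
              responsive_frac = responsive_frac,
              probesets_per_gene = as.integer(probesets_per_gene),
              region = as.character(region), seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 10L, cfg$attach_m >= 1L,
            cfg$probesets_per_gene >= 1L)
  if (cfg$planted_size > cfg$n_genes)
    stop("planted_size must not exceed n_genes")
  if (cfg$n_strains_ctrl < 4L || cfg$n_strains_trt < 4L)
    stop("at least 4 strains per condition are required")
  if (cfg$planted_density < 0 || cfg$planted_density > 1)
    stop("planted_density must lie in [0, 1]")
  if (cfg$gwas_alpha <= 0 || cfg$gwas_alpha > 1)
    stop("gwas_alpha must lie in (0, 1]")
  if (abs(cfg$rho_base) >= 1 || abs(cfg$rho_base + cfg$delta_rho) >= 1)
    stop("|rho_base| and |rho_base + delta_rho| must be < 1")
  if (cfg$responsive_frac < 0 || cfg$responsive_frac > 1)
    stop("responsive_frac must lie in [0, 1]")
  invisible(cfg)
}

gene_symbols <- function(n) sprintf("G%06d", seq_len(n))

#' Generate a scale-free PPI with a planted dense subgraph
#'
#' Grows a Barabasi-Albert preferential-attachment graph over `n_genes`
#' synthetic gene symbols, then densifies a randomly chosen planted gene set
#' until it induces a connected subgraph of edge density at least
#' `planted_density`.
#'
#' @param config a [synthetic_config()].
#' @return a list with `graph` (an undirected simple connected [igraph]
#'   object with gene-symbol vertex names) and `truth` (class
#'   `synthetic_truth`: the planted gene symbols, the config, and the seed).
#' @export
generate_ppi <- function(config) {
  validate_config(config)
  ps <- config$planted_size
  if (ps < 2L && config$planted_density > 0)
    stop("planted_density is infeasible for planted_size < 2")
  npairs <- ps * (ps - 1) / 2
  need <- ceiling(config$planted_density * npairs)
  with_seed(child_seed(config$seed, 1L), {
    g <- igraph::sample_pa(config$n_genes, m = config$attach_m,
                           directed = FALSE)
    igraph::V(g)$name <- gene_symbols(config$n_genes)
    planted <- sort(sample(igraph::V(g)$name, ps))
    # connect the planted set: link components along a random ordering
    sub <- igraph::induced_subgraph(g, planted)
    comp <- igraph::components(sub)
    if (comp$no > 1L) {
      reps <- vapply(seq_len(comp$no), function(ci) {
        sample(planted[comp$membership == ci], 1L)
      }, character(1))
      reps <- sample(reps)
      for (i in seq_len(length(reps) - 1L))
        if (!igraph::are_adjacent(g, reps[i], reps[i + 1L]))
          g <- igraph::add_edges(g, c(reps[i], reps[i + 1L]))
    }
    # densify to the target planted density
    if (ps >= 2L) {
      sub <- igraph::induced_subgraph(g, planted)
      m_now <- igraph::ecount(sub)
      if (m_now < need) {
        adj <- igraph::as_adjacency_matrix(sub, sparse = FALSE)
        idx <- which(upper.tri(adj) & adj == 0, arr.ind = TRUE)
        rn <- rownames(adj)
        add <- idx[sample.int(nrow(idx), need - m_now), , drop = FALSE]
        g <- igraph::add_edges(g, as.vector(t(cbind(rn[add[, 1]],
                                                    rn[add[, 2]]))))
      }
    }
    g <- igraph::simplify(g)
    truth <- structure(list(planted_genes = planted, config = config,
                            seed = config$seed), class = "synthetic_truth")
    list(graph = g, truth = truth)
  })
}

#' Generate gene-level GWAS p-values with planted signal
#'
#' Planted genes draw p-values from Beta(`alpha`, 1) (right-skewed towards 0
#' for `alpha < 1`); background genes draw from Uniform(0, 1). `alpha = 1`
#' reduces to the global null.
#'
#' @param truth a `synthetic_truth` from [generate_ppi()].
#' @param alpha Beta shape in `(0, 1]`.
#' @param seed integer seed.
#' @return named numeric vector of p-values in `(0, 1)`, one per gene
#'   (a `GwasGeneStats` table).
#' @export
generate_gwas <- function(truth, alpha = truth$config$gwas_alpha,
                          seed = truth$seed) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  genes <- gene_symbols(truth$config$n_genes)
  planted <- genes %in% truth$planted_genes
  with_seed(child_seed(seed, 2L), {
    p <- stats::runif(length(genes))
    p[planted] <- stats::rbeta(sum(planted), alpha, 1)
    # keep strictly inside (0, 1)
    p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
    stats::setNames(p, genes)
  })
}

#' Generate two-condition expression panels with planted differential
#' co-expression
#'
#' A single-factor latent construction: every gene loads `sqrt(rho_base)` on
#' a strain-level global factor (giving all pairs baseline correlation
#' `rho_base`); in the treatment condition only, planted genes additionally
#' load `sqrt(delta_rho)` on a planted factor, raising planted-pair
#' correlations to `rho_base + delta_rho`. The construction is positive
#' semi-definite by design for `rho_base >= 0`, `delta_rho >= 0`,
#' `rho_base + delta_rho < 1`; anything else is rejected as infeasible.
#' Gene means are drawn once on an RMA-like scale (uniform 6-12) and shared
#' by both conditions.
#'
#' @param truth a `synthetic_truth`.
#' @param config a [synthetic_config()] (defaults to the one in `truth`).
#' @return list of two `expression_panel` objects (`control`, `treatment`),
#'   each a genes x strains matrix plus `region` and `condition` labels.
#' @export
generate_expression <- function(truth, config = truth$config) {
  validate_config(config)
  if (config$rho_base < 0 || config$delta_rho < 0 ||
      config$rho_base + config$delta_rho >= 1)
    stop("covariance construction infeasible: need 0 <= rho_base, ",
         "0 <= delta_rho, rho_base + delta_rho < 1")
  genes <- gene_symbols(config$n_genes)
  planted <- genes %in% truth$planted_genes
  with_seed(child_seed(truth$seed, 3L), {
    mu <- stats::runif(length(genes), 6, 12)
    make_panel <- function(n_strains, condition, treat) {
      strains <- sprintf("BXD%03d", seq_len(n_strains))
      gfac <- stats::rnorm(n_strains)                  # global factor
      pfac <- stats::rnorm(n_strains)                  # planted factor
      load_p <- if (treat) sqrt(config$delta_rho) else 0
      resid_sd <- sqrt(1 - config$rho_base -
                         ifelse(planted & treat, config$delta_rho, 0))
      eps <- matrix(stats::rnorm(length(genes) * n_strains),
                    nrow = length(genes))
      x <- mu +
        sqrt(config$rho_base) * matrix(gfac, length(genes), n_strains,
                                       byrow = TRUE) +
        (planted * load_p) * matrix(pfac, length(genes), n_strains,
                                    byrow = TRUE) +
        resid_sd * eps
      dimnames(x) <- list(genes, strains)
      expression_panel(x, region = config$region, condition = condition)
    }
    list(control = make_panel(config$n_strains_ctrl, "control", FALSE),
         treatment = make_panel(config$n_strains_trt, "treatment", TRUE))
  })
}

#' Construct an expression panel object
#'
#' @param values genes x strains numeric matrix with dimnames.
#' @param region region label.
#' @param condition `"control"` or `"treatment"`.
#' @export
expression_panel <- function(values, region, condition) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  condition <- match.arg(condition, c("control", "treatment"))
  structure(list(values = values, region = region, condition = condition),
            class = "expression_panel")
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf("expression_panel: %d genes x %d strains (%s, %s)\n",
              nrow(x$values), ncol(x$values), x$region, x$condition))
  invisible(x)
}

#' Generate a probeset-level S-score panel
#'
#' Each gene receives `probesets_per_gene` probesets. A responsive gene set
#' is drawn: the planted genes plus enough random background genes to make
#' up `responsive_frac` of the universe (treatment response is common in the
#' emulated data; the planted disease module is a small subset of it).
#' Probesets of responsive genes draw per-strain S-scores from
#' `N(+/- sscore_shift, 1)` (direction per probeset); all others are
#' standard normal, the S-score's null reference.
#'
#' @param truth a `synthetic_truth`.
#' @param config a [synthetic_config()].
#' @return list with `panel` (class `sscore_panel`: probesets x strains
#'   matrix plus region), `map` (data.frame `probeset`, `gene`) and
#'   `responsive_genes`.
#' @export
generate_sscores <- function(truth, config = truth$config) {
  validate_config(config)
  genes <- gene_symbols(config$n_genes)
  k <- config$probesets_per_gene
  map <- data.frame(
    probeset = sprintf("%s_ps%d", rep(genes, each = k), rep(seq_len(k),
                                                            length(genes))),
    gene = rep(genes, each = k), stringsAsFactors = FALSE)
  n_str <- config$n_strains_ctrl
  with_seed(child_seed(truth$seed, 4L), {
    n_extra <- max(0L, round(config$responsive_frac * config$n_genes) -
                     length(truth$planted_genes))
    responsive <- sort(c(truth$planted_genes,
                         sample(setdiff(genes, truth$planted_genes),
                                min(n_extra,
                                    config$n_genes -
                                      length(truth$planted_genes)))))
    resp_ps <- map$gene %in% responsive
    s <- matrix(stats::rnorm(nrow(map) * n_str), nrow = nrow(map))
    sign_ps <- sample(c(-1, 1), nrow(map), replace = TRUE)
    s[resp_ps, ] <- s[resp_ps, ] +
      (sign_ps[resp_ps] * config$sscore_shift)
    dimnames(s) <- list(map$probeset, sprintf("BXD%03d", seq_len(n_str)))
    list(panel = sscore_panel(s, region = config$region), map = map,
         responsive_genes = responsive)
  })
}

#' Construct an S-score panel object
#'
#' @param scores probesets x strains numeric matrix with dimnames.
#' @param region region label.
#' @export
sscore_panel <- function(scores, region) {
  stopifnot(is.matrix(scores), !is.null(rownames(scores)),
            !is.null(colnames(scores)))
  if (any(!is.finite(scores))) stop("non-finite S-score in panel")
  structure(list(scores = scores, region = region), class = "sscore_panel")
}

#' Generate synthetic GMT-style annotation sets
#'
#' Random gene sets over the synthetic universe plus one set concentrated in
#' the planted genes, so over-representation analysis has a known positive.
#'
#' @param truth a `synthetic_truth`.
#' @param n_sets number of random background sets.
#' @param set_size_range inclusive range of random set sizes.
#' @param seed integer seed.
#' @return named list of gene-symbol vectors; the planted-enriched set is
#'   named `"PLANTED_PATHWAY"`.
#' @export
generate_annotation_sets <- function(truth, n_sets = 50L,
                                     set_size_range = c(10L, 200L),
                                     seed = truth$seed) {
  genes <- gene_symbols(truth$config$n_genes)
  with_seed(child_seed(seed, 5L), {
    sizes <- sample(seq(set_size_range[1], set_size_range[2]), n_sets,
                    replace = TRUE)
    sets <- lapply(sizes, function(sz) sample(genes, sz))
    names(sets) <- sprintf("RANDOM_SET_%03d", seq_len(n_sets))
    extra <- sample(setdiff(genes, truth$planted_genes),
                    max(5L, length(truth$planted_genes) %/% 4L))
    sets$PLANTED_PATHWAY <- sort(c(truth$planted_genes, extra))
    sets
  })
}

#' Generate and write the full synthetic input bundle
#'
#' Runs every generator and writes the standard TSV/JSON bundle read back by
#' the pipeline: PPI edge list, discovery and validation GWAS tables,
#' control/treatment expression matrices, S-score panel, probeset map, an
#' identity homolog map (so the mapping code path is exercised), annotation
#' sets (GMT) and the ground-truth file.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if missing).
#' @param validation_alpha Beta shape for the validation GWAS (defaults to
#'   the discovery `gwas_alpha`).
#' @return (invisibly) a list with the in-memory objects and `truth`.
#' @export
generate_bundle <- function(config, dir, validation_alpha = config$gwas_alpha) {
  ppi <- generate_ppi(config)
  truth <- ppi$truth
  gwas_disc <- generate_gwas(truth, alpha = config$gwas_alpha,
                             seed = child_seed(config$seed, 11L))
  gwas_val <- generate_gwas(truth, alpha = validation_alpha,
                            seed = child_seed(config$seed, 12L))
  expr <- generate_expression(truth, config)
  ss <- generate_sscores(truth, config)
  gmt <- generate_annotation_sets(truth)
  genes <- gene_symbols(config$n_genes)
  homolog <- data.frame(source = genes, target = genes,
                        stringsAsFactors = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_edge_list(ppi$graph, file.path(dir, "ppi_edges.tsv"))
  write_gwas_table(gwas_disc, file.path(dir, "gwas_discovery.tsv"))
  write_gwas_table(gwas_val, file.path(dir, "gwas_validation.tsv"))
  write_expression_matrix(expr$control,
    file.path(dir, sprintf("expr_%s_control.tsv", config$region)))
  write_expression_matrix(expr$treatment,
    file.path(dir, sprintf("expr_%s_treatment.tsv", config$region)))
  write_sscore_panel(ss$panel,
    file.path(dir, sprintf("sscores_%s.tsv", config$region)))
  utils::write.table(ss$map, file.path(dir, "probeset_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(homolog, file.path(dir, "homolog_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(gmt, file.path(dir, "annotation_sets.gmt"))
  jsonlite::write_json(
    list(planted_genes = truth$planted_genes, seed = truth$seed,
         config = unclass(config)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(graph = ppi$graph, truth = truth, gwas_discovery = gwas_disc,
                 gwas_validation = gwas_val, expression = expr,
                 sscores = ss$panel, probeset_map = ss$map,
                 homolog_map = homolog, annotation_sets = gmt))
}
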