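# Preprocessing: ethanol-responsiveness calls from S-scores, probeset
# collapse, homolog mapping, and construction of the background network as
# the three-way intersection of PPI, GWAS and expression universes.

#' Fisher's combined probability test
#'
#' Combines independent p-values into `X2 = -2 * sum(log(p))`, referred to a
#' chi-square distribution with `2k` degrees of freedom.
#'
#' @param pvals numeric vector of p-values in `(0, 1]`.
#' @return list with `statistic`, `df` and `p` (upper-tail analytic p).
#' @export
fisher_combine <- function(pvals) {
  if (length(pvals) == 0L) stop("empty p-value list")
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]")
  stat <- -2 * sum(log(pvals))
  df <- 2L * length(pvals)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Call ethanol-responsive probesets from an S-score panel
#'
#' Per probeset, per-strain two-sided p-values are taken from the
#' standard-normal reference of the S-score, combined across strains by
#' Fisher's method, and compared against a permutation null in which each
#' strain's column of S-scores is shuffled across probesets (preserving the
#' per-strain empirical S-score distribution while breaking probeset
#' identity). Empirical p-values use the `(b + 1) / (B + 1)` estimator and
#' are BH-adjusted within the region.
#'
#' @param panel an [sscore_panel()].
#' @param n_perm number of permutations (default 1000; below 100 a warning
#'   is logged).
#' @param seed integer seed for the permutation stream.
#' @return data.frame with one row per probeset: `probeset`, `region`,
#'   `statistic`, `df`, `analytic_p`, `empirical_p`, `q`.
#' @export
responsive_calls <- function(panel, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(panel, "sscore_panel"))
  s <- panel$scores
  if (ncol(s) < 2L) stop("at least 2 strains are required")
  if (any(!is.finite(s))) stop("non-finite S-score in panel")
  if (n_perm < 100L) {
    warning("n_perm < 100: empirical p-values will be coarse")
    log_event("responsive_calls: n_perm < 100 (", n_perm, ")")
  }
  # per-entry contribution to the Fisher statistic: -2 log(2 * Phi(-|s|))
  contrib <- -2 * log(pmax(2 * stats::pnorm(-abs(s)), 1e-300))
  obs <- rowSums(contrib)
  df <- 2L * ncol(s)
  analytic_p <- stats::pchisq(obs, df = df, lower.tail = FALSE)
  exceed <- integer(nrow(s))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- apply(contrib, 2L, sample)
      exceed <- exceed + (rowSums(perm) >= obs)
    }
  })
  emp <- (1 + exceed) / (n_perm + 1)
  data.frame(probeset = rownames(s), region = panel$region,
             statistic = obs, df = df, analytic_p = analytic_p,
             empirical_p = emp,
             q = stats::p.adjust(emp, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter probesets by the any-region responsiveness rule
#'
#' A probeset is retained if its BH-adjusted empirical p-value falls strictly
#' below `q_threshold` in at least one region.
#'
#' @param calls data.frame as returned by [responsive_calls()], possibly
#'   row-bound across regions.
#' @param q_threshold FDR threshold (default 0.1).
#' @return character vector of retained probeset ids (union over regions).
#' @export
filter_responsive <- function(calls, q_threshold = 0.1) {
  stopifnot(all(c("probeset", "q") %in% names(calls)))
  sort(unique(calls$probeset[calls$q < q_threshold]))
}

#' Collapse probeset-level expression to gene level
#'
#' For each gene, the single probeset with the highest mean expression --
#' mean taken over all strains of the region, both conditions -- supplies the
#' gene's expression row in both condition panels. Ties are broken by the
#' lexicographically smallest probeset id.
#'
#' @param ctrl,trt `expression_panel` objects with probeset row names
#'   (same region, conditions control/treatment).
#' @param map data.frame with columns `probeset`, `gene`; each probeset must
#'   map to exactly one gene.
#' @return list of two gene-level `expression_panel` objects
#'   (`control`, `treatment`).
#' @export
collapse_probesets <- function(ctrl, trt, map) {
  stopifnot(inherits(ctrl, "expression_panel"),
            inherits(trt, "expression_panel"))
  if (anyDuplicated(map$probeset))
    stop("a probeset maps to multiple genes")
  ps <- intersect(rownames(ctrl$values), map$probeset)
  if (!setequal(rownames(ctrl$values), rownames(trt$values)))
    stop("control and treatment panels must cover the same probesets")
  map <- map[match(ps, map$probeset), , drop = FALSE]
  mean_rma <- (rowSums(ctrl$values[ps, , drop = FALSE]) +
               rowSums(trt$values[ps, , drop = FALSE])) /
    (ncol(ctrl$values) + ncol(trt$values))
  ord <- order(map$gene, -mean_rma, map$probeset)
  keep <- ps[ord][!duplicated(map$gene[ord])]
  genes_kept <- map$gene[match(keep, map$probeset)]
  pick <- function(panel) {
    v <- panel$values[keep, , drop = FALSE]
    rownames(v) <- genes_kept
    expression_panel(v[order(genes_kept), , drop = FALSE],
                     region = panel$region, condition = panel$condition)
  }
  list(control = pick(ctrl), treatment = pick(trt))
}

#' Map gene symbols through a homolog table
#'
#' Renames the rows of gene-level expression panels from source symbols
#' (e.g. mouse) to target symbols (e.g. human). Unmapped genes are dropped.
#' When two or more source genes map to the same target, the source with the
#' higher mean expression (over both condition panels) is kept and the
#' collision is logged.
#'
#' @param panels list of two `expression_panel` objects
#'   (`control`, `treatment`) sharing one region.
#' @param homolog_map data.frame with columns `source`, `target`; source
#'   symbols must be unique.
#' @return list of two renamed `expression_panel` objects.
#' @export
map_homologs <- function(panels, homolog_map) {
  stopifnot(all(c("source", "target") %in% names(homolog_map)))
  if (anyDuplicated(homolog_map$source))
    stop("homolog table has duplicate source symbols")
  ctrl <- panels$control; trt <- panels$treatment
  src <- rownames(ctrl$values)
  hit <- match(src, homolog_map$source)
  keep <- !is.na(hit)
  if (!any(keep)) stop("no gene could be mapped through the homolog table")
  src <- src[keep]
  target <- homolog_map$target[hit[keep]]
  mean_rma <- (rowSums(ctrl$values[src, , drop = FALSE]) +
               rowSums(trt$values[src, , drop = FALSE])) /
    (ncol(ctrl$values) + ncol(trt$values))
  ord <- order(target, -mean_rma, src)
  dup <- duplicated(target[ord])
  if (any(dup))
    log_event("map_homologs: ", sum(dup),
              " source gene(s) dropped in homolog collisions")
  sel <- ord[!dup]
  rename <- function(panel) {
    v <- panel$values[src[sel], , drop = FALSE]
    rownames(v) <- target[sel]
    expression_panel(v[order(target[sel]), , drop = FALSE],
                     region = panel$region, condition = panel$condition)
  }
  list(control = rename(ctrl), treatment = rename(trt))
}

#' Build the background network
#'
#' Induces the PPI subgraph on the genes present in all three universes
#' (PPI, GWAS, expression) and removes nodes whose induced degree is zero --
#' an isolated node can never join an edge-weighted module.
#'
#' @param ppi undirected [igraph] graph with gene-symbol vertex names.
#' @param gwas_genes character vector of genes with GWAS p-values.
#' @param expr_genes character vector of genes with expression rows.
#' @return the induced background graph (igraph).
#' @export
build_background <- function(ppi, gwas_genes, expr_genes) {
  common <- intersect(intersect(igraph::V(ppi)$name, gwas_genes), expr_genes)
  if (length(common) == 0L)
    stop("empty intersection of PPI, GWAS and expression gene universes")
  bg <- igraph::induced_subgraph(ppi, common)
  iso <- igraph::degree(bg) == 0
  if (any(iso))
    log_event("build_background: removed ", sum(iso), " degree-0 node(s)")
  bg <- igraph::delete_vertices(bg, which(iso))
  if (igraph::vcount(bg) == 0L)
    stop("background network is empty after removing isolated nodes")
  log_event("build_background: ", igraph::vcount(bg), " genes, ",
            igraph::ecount(bg), " interactions")
  bg
}
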