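# Cross-GWAS validation: nominal gene sets, permutation overrepresentation,
# score regression, mega-module overlap testing, and local hypergeometric
# over-representation analysis against GMT annotation sets.

#' Nominally significant genes of a validation GWAS
#'
#' Genes with gene-wise p strictly below `threshold`, optionally restricted
#' to a background gene universe.
#'
#' @param gwas named numeric p-value vector.
#' @param threshold nominal threshold (default 0.001, strict `<`).
#' @param background optional character vector restricting the result.
#' @return sorted character vector of nominal genes.
#' @export
nominal_genes <- function(gwas, threshold = 0.001, background = NULL) {
  if (length(gwas) == 0L) stop("empty GWAS table")
  g <- names(gwas)[gwas < threshold]
  if (!is.null(background)) g <- intersect(g, background)
  sort(g)
}

#' Permutation overrepresentation of nominal genes in a mega-module
#'
#' Draws `B` uniform gene sets of the mega-module's size from the background
#' (without replacement) and counts how often they contain at least as many
#' nominal genes as observed; empirical
#' `p = (1 + #{count_null >= count_obs}) / (B + 1)`.
#'
#' @param mm_genes mega-module gene symbols.
#' @param nominal nominal gene set (will be intersected with the
#'   background).
#' @param background character vector: the background gene universe.
#' @param B number of permutations (default 10000).
#' @param seed integer seed.
#' @return list with `observed` (nominal count in the module), `p`
#'   (empirical p) and `B`.
#' @export
overrep_test <- function(mm_genes, nominal, background, B = 10000L,
                         seed = 1L) {
  if (length(mm_genes) > length(background))
    stop("mega-module is larger than the background universe")
  nominal <- intersect(nominal, background)
  obs <- length(intersect(mm_genes, nominal))
  is_nom <- background %in% nominal
  n <- length(mm_genes)
  exceed <- with_seed(seed, sum(vapply(seq_len(B), function(b) {
    sum(is_nom[sample.int(length(background), n)]) >= obs
  }, NA)))
  list(observed = obs, p = (1 + exceed) / (B + 1), B = B)
}

#' Regression of mean validation p-value on mega-module score
#'
#' Ordinary least squares of each mega-module's mean validation-GWAS
#' gene-wise p-value on its standardized score `MM_S_n`. Genes absent from
#' the validation study are excluded from the mean (and logged). The
#' hypothesized direction is negative: higher-scoring modules carry more
#' significant validation signal.
#'
#' @param mms scored `mega_module_list`.
#' @param gwas named validation p-value vector.
#' @param alpha_total family-wise alpha split across regions (default 0.05).
#' @param n_tests number of independent tests (regions; default 3), giving
#'   the Bonferroni threshold `alpha_total / n_tests`.
#' @return list with `beta` (slope), `p` (two-sided t-test), `threshold`,
#'   `significant`, `n` (modules used) and the per-module data.frame `data`.
#' @export
score_regression <- function(mms, gwas, alpha_total = 0.05, n_tests = 3L) {
  if (length(mms) < 3L) stop("need at least 3 mega-modules")
  df <- do.call(rbind, lapply(mms, function(mm) {
    pv <- gwas[intersect(mm$genes, names(gwas))]
    miss <- mm$k - length(pv)
    if (miss > 0)
      log_event("score_regression: ", miss, " gene(s) of ", mm$name,
                " absent from the validation GWAS")
    data.frame(name = mm$name, MM_S_n = mm$S_n,
               mean_p = if (length(pv)) mean(pv) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  df <- df[is.finite(df$mean_p), , drop = FALSE]
  if (nrow(df) < 3L) stop("need at least 3 mega-modules with validation data")
  if (stats::sd(df$MM_S_n) == 0) stop("zero variance in MM_S_n")
  fit <- stats::lm(mean_p ~ MM_S_n, data = df)
  sm <- summary(fit)$coefficients
  thr <- alpha_total / n_tests
  list(beta = unname(sm["MM_S_n", "Estimate"]),
       p = unname(sm["MM_S_n", "Pr(>|t|)"]),
       threshold = thr,
       significant = unname(sm["MM_S_n", "Pr(>|t|)"]) < thr,
       n = nrow(df), data = df)
}

#' Hypergeometric overlap of two mega-modules
#'
#' Upper-tail probability `P(X >= |A intersect B|)` for
#' `X ~ Hypergeometric(N, |A|, |B|)`: the chance that two random gene sets
#' of the same sizes drawn from a background of `N` genes share at least the
#' observed number of genes.
#'
#' @param genes_a,genes_b mega-module gene sets (or their sizes via
#'   `n_a`/`n_b`/`overlap`).
#' @param n_background background universe size `N`.
#' @return upper-tail p-value.
#' @export
overlap_test <- function(genes_a, genes_b, n_background) {
  a <- unique(genes_a); b <- unique(genes_b)
  overlap_test_counts(length(intersect(a, b)), length(a), length(b),
                      n_background)
}

#' @rdname overlap_test
#' @param overlap,n_a,n_b observed overlap and set sizes.
#' @export
overlap_test_counts <- function(overlap, n_a, n_b, n_background) {
  if (n_a > n_background || n_b > n_background)
    stop("set size exceeds the background universe")
  stats::phyper(overlap - 1, n_a, n_background - n_a, n_b,
                lower.tail = FALSE)
}

#' Hypergeometric over-representation analysis
#'
#' For each annotation set, the one-sided hypergeometric tail probability of
#' the observed overlap with the query is computed against the universe.
#' Records are kept if `p < p_max`, the overlap has at least `min_hits`
#' genes, and the (universe-restricted) set has at most `max_set_size`
#' genes. The Bonferroni q multiplies p by the number of sets tested in the
#' set's category (sets with at least one universe member count as tested),
#' capped at 1.
#'
#' @param query character vector of query genes (must be within `universe`).
#' @param sets named list of annotation gene sets.
#' @param universe character vector: the reference universe.
#' @param categories optional named character vector assigning each set to a
#'   category (default: one category for all sets).
#' @param p_max,min_hits,max_set_size report filters (defaults 0.01, 3,
#'   1000).
#' @return data.frame of class `enrichment_table`, sorted by p: `category`,
#'   `set`, `set_size`, `hits`, `p`, `q_bonferroni`, `hit_genes`.
#' @export
ora_enrichment <- function(query, sets, universe, categories = NULL,
                           p_max = 0.01, min_hits = 3L,
                           max_set_size = 1000L) {
  if (length(universe) == 0L) stop("empty universe")
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe)) stop("query genes must lie in the universe")
  if (is.null(categories))
    categories <- stats::setNames(rep("all", length(sets)), names(sets))
  res <- lapply(names(sets), function(nm) {
    sg <- intersect(unique(sets[[nm]]), universe)
    if (length(sg) == 0L) return(NULL)
    hit <- intersect(query, sg)
    p <- stats::phyper(length(hit) - 1, length(sg),
                       length(universe) - length(sg), length(query),
                       lower.tail = FALSE)
    data.frame(category = unname(categories[nm]), set = nm,
               set_size = length(sg), hits = length(hit), p = p,
               hit_genes = paste(sort(hit), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    return(structure(data.frame(category = character(), set = character(),
                                set_size = integer(), hits = integer(),
                                p = numeric(), q_bonferroni = numeric(),
                                hit_genes = character(),
                                stringsAsFactors = FALSE),
                     class = c("enrichment_table", "data.frame")))
  n_tested <- table(res$category)
  res$q_bonferroni <- pmin(res$p * as.integer(n_tested[res$category]), 1)
  keep <- res$p < p_max & res$hits >= min_hits & res$set_size <= max_set_size
  res <- res[keep, c("category", "set", "set_size", "hits", "p",
                     "q_bonferroni", "hit_genes"), drop = FALSE]
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("enrichment_table", "data.frame"))
}
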