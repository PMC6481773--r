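# Mega-modules: iterative merging of redundant significant modules,
# rescoring with the module-search machinery, and hub-gene identification by
# within-module connectivity and eigencentrality.

#' Percent overlap of two gene sets
#'
#' `|A intersect B| / min(|A|, |B|)` -- the overlap as a fraction of the
#' smaller set; symmetric and in `[0, 1]`.
#'
#' @param a,b non-empty character vectors of gene symbols.
#' @return overlap fraction.
#' @export
percent_overlap <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty gene set")
  a <- unique(a); b <- unique(b)
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Iteratively merge overlapping modules into mega-modules
#'
#' All pairwise percent overlaps are computed; while any pair exceeds
#' `threshold` (strictly), the maximal-overlap pair is merged (gene union)
#' and the overlaps recomputed, until no pair exceeds the threshold. Ties on
#' the maximal overlap are broken by the larger summed `S_n` of the pair,
#' then by the lexicographically smallest member gene of the merged set.
#'
#' @param modules list of significant `ew_module` objects.
#' @param threshold merge threshold on percent overlap (default 0.8; a pair
#'   merges only when overlap is strictly greater).
#' @return list of class `mega_module_list`; each element has `constituents`
#'   (indices into the input list), `genes`.
#' @export
merge_modules <- function(modules, threshold = 0.8) {
  if (length(modules) == 0L) return(structure(list(), class = "mega_module_list"))
  mms <- lapply(seq_along(modules), function(i)
    list(constituents = i, genes = unique(modules[[i]]$genes),
         sum_sn = modules[[i]]$S_n))
  nm0 <- length(mms)
  # gene x module incidence; all pairwise overlap counts come from one
  # crossprod. Merging works in place: the merged pair's first slot is
  # overwritten with the union and the second slot deactivated, and only the
  # merged column of the overlap matrix is recomputed -- equivalent to
  # rescanning all pairs after every merge. A running per-row maximum keeps
  # each round's global-max search linear.
  universe <- sort(unique(unlist(lapply(mms, `[[`, "genes"))))
  inc <- matrix(0, length(universe), nm0,
                dimnames = list(universe, NULL))
  for (i in seq_len(nm0)) inc[mms[[i]]$genes, i] <- 1
  sizes <- colSums(inc)
  ov <- crossprod(inc) / outer(sizes, sizes, pmin)
  diag(ov) <- -1
  active <- rep(TRUE, nm0)
  rowmax <- apply(ov, 1L, max)
  while (sum(active) >= 2L) {
    mx <- max(rowmax)
    if (mx <= threshold) break
    rows <- which(rowmax == mx & active)
    hits <- do.call(rbind, lapply(rows, function(r) {
      cs <- which(ov[r, ] == mx & active)
      cs <- cs[cs > r]
      if (length(cs)) cbind(r, cs) else NULL
    }))
    if (is.null(hits)) { # symmetric duplicates only; rescan stale rows
      for (r in rows) rowmax[r] <- max(ov[r, ])
      next
    }
    if (nrow(hits) > 1L) {
      ssn <- vapply(seq_len(nrow(hits)), function(h)
        mms[[hits[h, 1]]]$sum_sn + mms[[hits[h, 2]]]$sum_sn, 0)
      hits <- hits[ssn == max(ssn), , drop = FALSE]
      if (nrow(hits) > 1L) {
        gmin <- vapply(seq_len(nrow(hits)), function(h)
          min(union(mms[[hits[h, 1]]]$genes, mms[[hits[h, 2]]]$genes)), "")
        hits <- hits[order(gmin)[1L], , drop = FALSE]
      }
    }
    i <- as.integer(hits[1L, 1L]); j <- as.integer(hits[1L, 2L])
    mms[[i]] <- list(constituents = c(mms[[i]]$constituents,
                                      mms[[j]]$constituents),
                     genes = sort(union(mms[[i]]$genes, mms[[j]]$genes)),
                     sum_sn = mms[[i]]$sum_sn + mms[[j]]$sum_sn)
    old_i <- ov[, i]; old_j <- ov[, j]
    active[j] <- FALSE
    ov[j, ] <- -1; ov[, j] <- -1; rowmax[j] <- -1
    inc[, i] <- pmax(inc[, i], inc[, j]); inc[, j] <- 0
    sizes[i] <- sum(inc[, i]); sizes[j] <- 0
    val <- as.numeric(crossprod(inc, inc[, i])) / pmin(sizes, sizes[i])
    val[!active] <- -1; val[i] <- -1
    ov[i, ] <- val; ov[, i] <- val
    # rows whose previous maximum sat in a rewritten column are stale
    stale <- which(active & (old_i == rowmax | old_j == rowmax))
    for (r in stale) rowmax[r] <- max(ov[r, ])
    rowmax <- pmax(rowmax, val)
    rowmax[i] <- max(val)
    rowmax[!active] <- -1
  }
  structure(mms[active], class = "mega_module_list")
}

# fixed ordered label list for mega-module names (cosmetic, assigned by
# score rank)
mm_labels <- function(n) {
  base <- c("aliceblue", "cadetblue", "coral", "limegreen", "bisque",
            "gray26", "thistle", "salmon", "orchid", "khaki", "sienna",
            "plum", "tan", "olive", "teal", "maroon", "navy", "ivory",
            "lavender", "crimson")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, sprintf("megamodule%03d", seq_len(n - length(base))))
}

#' Score mega-modules and assess their significance
#'
#' Applies the identical scoring, standardization and permutation machinery
#' of the module search to each merged gene set with its background-induced
#' edges, then assigns rank-based names (highest `S_n` first).
#'
#' @param mms a `mega_module_list` from [merge_modules()].
#' @param wn a `weighted_network`.
#' @param B null draws per `(k, m)`.
#' @param seed integer seed.
#' @param params a [search_params()] controlling the standardization mode.
#' @return list of `mega_module` objects, ordered by decreasing `S_n`, each
#'   with `name`, `genes`, `constituents`, `k`, `m`, `S_m`, `S_n`, `p`, `q`.
#' @export
score_megamodules <- function(mms, wn, B = 1000L, seed = 1L,
                              params = search_params()) {
  if (length(mms) == 0L) return(structure(list(), class = "mega_module_list"))
  cache <- new.env(parent = emptyenv())
  scored <- lapply(mms, function(mm) {
    idx <- match(mm$genes, wn$genes)
    if (anyNA(idx)) stop("mega-module gene(s) absent from the network")
    ein <- induced_edge_ids(wn, idx)
    s_m <- raw_score_from_sums(sum(wn$z[idx]), length(idx),
                               sum(wn$w[ein]), length(ein), wn$lambda)
    s_n <- standardize_score(mm$genes, wn, params, cache = cache)
    list(genes = mm$genes, constituents = mm$constituents,
         k = length(idx), m = length(ein), S_m = s_m, S_n = s_n)
  })
  pcache <- new.env(parent = emptyenv())
  p <- with_seed(seed, vapply(scored, function(mm) {
    key <- paste0("k", mm$k, "m", mm$m)
    draws <- pcache[[key]]
    if (is.null(draws)) {
      draws <- sample_null_scores(wn, mm$k, mm$m, B)
      pcache[[key]] <- draws
    }
    (1 + sum(draws >= mm$S_m)) / (B + 1)
  }, 0))
  q <- stats::p.adjust(p, method = "BH")
  ord <- order(-vapply(scored, `[[`, 0, "S_n"))
  scored <- scored[ord]; p <- p[ord]; q <- q[ord]
  nm <- mm_labels(length(scored))
  out <- lapply(seq_along(scored), function(i) {
    mm <- scored[[i]]
    mm$name <- nm[i]; mm$p <- p[i]; mm$q <- q[i]
    structure(mm, class = "mega_module")
  })
  structure(out, class = "mega_module_list")
}

#' Within-module connectivity and eigencentrality
#'
#' Connectivity `k_i` is the degree of each gene inside the mega-module's
#' background-induced subgraph. Eigencentrality `EC_i` is the leading
#' eigenvector of that subgraph's adjacency matrix, computed by power
#' iteration (on `A + I` to avoid bipartite oscillation, which shares A's
#' Perron vector), normalized so the maximum is 1. For a disconnected
#' subgraph the dominant component carries the mass (logged).
#'
#' @param genes mega-module gene symbols.
#' @param background background [igraph] graph.
#' @param tol power-iteration convergence tolerance (default 1e-10).
#' @return data.frame `gene`, `connectivity`, `eigencentrality`.
#' @export
module_centralities <- function(genes, background, tol = 1e-10) {
  sub <- igraph::induced_subgraph(background, genes)
  if (igraph::ecount(sub) == 0L)
    stop("mega-module has no edges; centralities are undefined")
  a <- igraph::as_adjacency_matrix(sub, sparse = TRUE)
  if (igraph::components(sub)$no > 1L)
    log_event("module_centralities: disconnected subgraph (",
              igraph::components(sub)$no, " components)")
  n <- nrow(a)
  x <- rep(1, n)
  for (it in seq_len(100000L)) {
    x_new <- as.numeric(a %*% x) + x     # (A + I) x
    x_new <- x_new / max(x_new)
    if (max(abs(x_new - x)) < tol) { x <- x_new; break }
    x <- x_new
  }
  data.frame(gene = rownames(a),
             connectivity = as.integer(igraph::degree(sub)[rownames(a)]),
             eigencentrality = x,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Hub genes of a mega-module
#'
#' A gene is a hub if its eigencentrality exceeds `ec_threshold` and its
#' within-module connectivity is at or above the third quartile of the
#' module's degree vector (linear-interpolation quantile).
#'
#' @param centralities data.frame from [module_centralities()].
#' @param ec_threshold eigencentrality cutoff (default 0.2, strict `>`).
#' @return character vector of hub gene symbols.
#' @export
call_hubs <- function(centralities, ec_threshold = 0.2) {
  q3 <- stats::quantile(centralities$connectivity, 0.75, names = FALSE,
                        type = 7)
  sort(centralities$gene[centralities$eigencentrality > ec_threshold &
                           centralities$connectivity >= q3])
}

#' Tabulate a mega-module list
#'
#' One row per gene per mega-module, mirroring the layout of a supplementary
#' mega-module table: name, score columns, per-gene discovery/validation
#' GWAS p-values, and intramodular centralities.
#'
#' @param mms scored `mega_module_list`.
#' @param background background [igraph] graph (for centralities).
#' @param gwas_discovery,gwas_validation optional named p-value vectors.
#' @return data.frame.
#' @export
megamodules_to_table <- function(mms, background, gwas_discovery = NULL,
                                 gwas_validation = NULL) {
  if (length(mms) == 0L)
    return(data.frame(name = character(), gene = character(), k_g = integer(),
                      MM_S_n = numeric(), p = numeric(), q = numeric(),
                      discovery_p = numeric(), validation_p = numeric(),
                      connectivity = integer(), eigencentrality = numeric(),
                      hub = logical(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(mms, function(mm) {
    cent <- module_centralities(mm$genes, background)
    hubs <- call_hubs(cent)
    data.frame(name = mm$name, gene = cent$gene, k_g = mm$k,
               MM_S_n = mm$S_n, p = mm$p, q = mm$q,
               discovery_p = if (is.null(gwas_discovery)) NA_real_
                             else unname(gwas_discovery[cent$gene]),
               validation_p = if (is.null(gwas_validation)) NA_real_
                              else unname(gwas_validation[cent$gene]),
               connectivity = cent$connectivity,
               eigencentrality = cent$eigencentrality,
               hub = cent$gene %in% hubs,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
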