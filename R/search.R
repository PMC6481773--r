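# Greedy edge-weighted dense module search: raw and standardized module
# scores, seed-and-extend growth under the 0.5% improvement rule, and
# permutation-based module significance.

#' Search parameters
#'
#' @param growth_rate minimum relative improvement in the standardized score
#'   required to admit a gene (default 0.005, i.e. 0.5%).
#' @param neighbor_distance candidate distance from the current module
#'   (default 1: immediate neighbors).
#' @param min_module_size smallest module reported by [search_all()]
#'   (default 5).
#' @param standardization `"analytic"` (moment-based, default) or
#'   `"montecarlo"`.
#' @param B permutation count for Monte-Carlo standardization and
#'   significance (>= 100 when montecarlo).
#' @param seed integer seed for any Monte-Carlo draw.
#' @return object of class `search_params`.
#' @export
search_params <- function(growth_rate = 0.005, neighbor_distance = 1L,
                          min_module_size = 5L,
                          standardization = c("analytic", "montecarlo"),
                          B = 1000L, seed = 1L) {
  standardization <- match.arg(standardization)
  if (growth_rate <= 0) stop("growth_rate must be positive")
  if (neighbor_distance != 1L)
    stop("only neighbor_distance = 1 is implemented")
  if (standardization == "montecarlo" && B < 100L)
    stop("B must be >= 100 for montecarlo standardization")
  structure(list(growth_rate = growth_rate,
                 neighbor_distance = as.integer(neighbor_distance),
                 min_module_size = as.integer(min_module_size),
                 standardization = standardization, B = as.integer(B),
                 seed = as.integer(seed)),
            class = "search_params")
}

#' Raw module score
#'
#' `S_m = lambda * sum(z) / sqrt(k) + (1 - lambda) * sum(w) / sqrt(m)` over
#' the module's `k` genes and `m` induced edges; the edge term is 0 when the
#' module has no edges.
#'
#' @param genes character vector of module genes.
#' @param wn a `weighted_network`.
#' @return raw score `S_m`.
#' @export
module_raw_score <- function(genes, wn) {
  if (length(genes) == 0L) stop("empty module")
  idx <- match(genes, wn$genes)
  if (anyNA(idx)) stop("module gene(s) absent from the network")
  ein <- induced_edge_ids(wn, idx)
  raw_score_from_sums(sum(wn$z[idx]), length(idx), sum(wn$w[ein]),
                      length(ein), wn$lambda)
}

raw_score_from_sums <- function(sum_z, k, sum_w, m, lambda) {
  s <- lambda * sum_z / sqrt(k)
  if (m > 0) s <- s + (1 - lambda) * sum_w / sqrt(m)
  s
}

# edge ids (rows of wn$edges) induced by a set of vertex indices
induced_edge_ids <- function(wn, idx) {
  inset <- logical(length(wn$genes))
  inset[idx] <- TRUE
  which(inset[wn$edges[, 1]] & inset[wn$edges[, 2]])
}

# analytic null mean / sd of S_m for a (k, m) module under i.i.d. sampling
# of node and edge weights from the background populations
analytic_null <- function(wn, k, m) {
  list(mean = wn$lambda * sqrt(k) * wn$mu_z +
         (1 - wn$lambda) * sqrt(m) * wn$mu_w,
       sd = sqrt(wn$lambda^2 * wn$sd_z^2 + (1 - wn$lambda)^2 * wn$sd_w^2))
}

#' Raw scores of random null modules
#'
#' Draws `B` random modules of `k` genes and `m` edges -- both sampled
#' uniformly without replacement from the background weight populations,
#' independently of each other and of graph topology -- and returns their raw
#' scores. This sampler defines the null for both Monte-Carlo
#' standardization and permutation significance.
#'
#' @param wn a `weighted_network`.
#' @param k,m module size (genes, edges).
#' @param B number of draws.
#' @return numeric vector of `B` raw scores.
#' @export
sample_null_scores <- function(wn, k, m, B) {
  if (m > length(wn$w)) stop("m exceeds the number of background edges")
  if (k > length(wn$z)) stop("k exceeds the number of background genes")
  zs <- vapply(seq_len(B),
               function(b) sum(wn$z[sample.int(length(wn$z), k)]), 0)
  ws <- if (m > 0)
    vapply(seq_len(B), function(b) sum(wn$w[sample.int(length(wn$w), m)]), 0)
  else numeric(B)
  raw_score_from_sums(zs, k, ws, m, wn$lambda)
}

#' Standardized module score
#'
#' `S_n = (S_m - mean_null) / sd_null`. In `"analytic"` mode (used inside
#' the greedy loop) the null moments treat the module's weights as i.i.d.
#' draws from the background populations, giving
#' `mean = lambda*sqrt(k)*mu_z + (1-lambda)*sqrt(m)*mu_w` and
#' `sd = sqrt(lambda^2*sd_z^2 + (1-lambda)^2*sd_w^2)`. In `"montecarlo"`
#' mode the moments are estimated from `B` random modules of the same
#' `(k, m)` drawn by [sample_null_scores()] (cached per `(k, m)` within a
#' call via `cache`).
#'
#' @param genes module gene symbols.
#' @param wn a `weighted_network`.
#' @param params a [search_params()].
#' @param cache optional environment for Monte-Carlo moment caching.
#' @return standardized score `S_n`.
#' @export
standardize_score <- function(genes, wn, params = search_params(),
                              cache = NULL) {
  idx <- match(genes, wn$genes)
  if (anyNA(idx)) stop("module gene(s) absent from the network")
  k <- length(idx)
  ein <- induced_edge_ids(wn, idx)
  m <- length(ein)
  s_m <- raw_score_from_sums(sum(wn$z[idx]), k, sum(wn$w[ein]), m, wn$lambda)
  if (params$standardization == "analytic") {
    nl <- analytic_null(wn, k, m)
  } else {
    key <- paste0("k", k, "m", m)
    if (!is.null(cache) && !is.null(cache[[key]])) {
      nl <- cache[[key]]
    } else {
      draws <- with_seed(child_seed(params$seed, k * 1000L + m),
                         sample_null_scores(wn, k, m, params$B))
      nl <- list(mean = mean(draws), sd = stats::sd(draws))
      if (!is.null(cache)) cache[[key]] <- nl
    }
  }
  if (!is.finite(nl$sd) || nl$sd <= 0) stop("null sd estimate is zero")
  (s_m - nl$mean) / nl$sd
}

#' Greedy seed-and-extend module search from one seed gene
#'
#' Starting from the seed alone, all background neighbors of the current
#' module are evaluated with every edge they contribute into the module; the
#' neighbor maximizing the new standardized score is admitted if it improves
#' `S_n` by at least the growth rate -- `S_n_new >= S_n_old * (1 + r)` when
#' `S_n_old > 0`, and `S_n_new >= S_n_old + |S_n_old| * r` otherwise (the
#' multiplicative rule is ill-defined at non-positive scores). Ties are
#' broken by the higher node weight, then the lexicographically smaller
#' symbol. The search stops when the best candidate fails the rule.
#' Standardization inside the loop is analytic.
#'
#' @param wn a `weighted_network`.
#' @param seed_gene seed gene symbol.
#' @param params a [search_params()].
#' @return list of class `ew_module`: `seed`, `genes`, `k`, `m`, `S_m`,
#'   `S_n`.
#' @export
greedy_search <- function(wn, seed_gene, params = search_params()) {
  s0 <- match(seed_gene, wn$genes)
  if (is.na(s0)) stop("seed gene '", seed_gene, "' absent from the network")
  r <- params$growth_rate
  lambda <- wn$lambda
  denom <- sqrt(lambda^2 * wn$sd_z^2 + (1 - lambda)^2 * wn$sd_w^2)
  if (!is.finite(denom) || denom <= 0)
    stop("null sd estimate is zero; cannot standardize scores")
  z <- wn$z; n <- length(z)
  member <- logical(n)
  esum <- numeric(n)   # summed weight of a candidate's edges into the module
  edeg <- integer(n)   # number of such edges
  member[s0] <- TRUE
  sum_z <- z[[s0]]; sum_w <- 0; k <- 1L; m <- 0L
  cands <- integer(0)
  add_neighbors <- function(g) {
    nb <- wn$adj[[g]]; nw <- wn$adj_w[[g]]
    keep <- !member[nb]
    nb <- nb[keep]; nw <- nw[keep]
    new <- nb[edeg[nb] == 0L]
    esum[nb] <<- esum[nb] + nw
    edeg[nb] <<- edeg[nb] + 1L
    cands <<- c(cands, new)
  }
  add_neighbors(s0)
  sn_of <- function(s_m, kk, mm) {
    (s_m - (lambda * sqrt(kk) * wn$mu_z +
              (1 - lambda) * sqrt(mm) * wn$mu_w)) / denom
  }
  s_n_old <- sn_of(raw_score_from_sums(sum_z, k, sum_w, m, lambda), k, m)
  while (length(cands) > 0L) {
    ck <- k + 1L
    cm <- m + edeg[cands]
    s_m_new <- lambda * (sum_z + z[cands]) / sqrt(ck)
    pos <- cm > 0L
    s_m_new[pos] <- s_m_new[pos] +
      (1 - lambda) * (sum_w + esum[cands[pos]]) / sqrt(cm[pos])
    s_n_new <- sn_of(s_m_new, ck, cm)
    best <- which(s_n_new == max(s_n_new))
    if (length(best) > 1L) {
      bz <- z[cands[best]]
      best <- best[bz == max(bz)]
      if (length(best) > 1L)
        best <- best[order(wn$genes[cands[best]])[1L]]
    }
    best <- best[1L]
    ok <- if (s_n_old > 0) s_n_new[best] >= s_n_old * (1 + r)
          else s_n_new[best] >= s_n_old + abs(s_n_old) * r
    if (!ok) break
    g <- cands[best]
    member[g] <- TRUE
    sum_z <- sum_z + z[[g]]; sum_w <- sum_w + esum[g]
    k <- ck; m <- m + edeg[g]
    s_n_old <- s_n_new[best]
    cands <- cands[cands != g]
    add_neighbors(g)
  }
  genes <- sort(wn$genes[member])
  structure(list(seed = wn$genes[s0], genes = genes, k = k, m = m,
                 S_m = unname(raw_score_from_sums(sum_z, k, sum_w, m, lambda)),
                 S_n = unname(s_n_old)),
            class = "ew_module")
}

#' @export
print.ew_module <- function(x, ...) {
  cat(sprintf("module [seed %s]: k = %d genes, m = %d edges, S_m = %.4f, S_n = %.4f\n",
              x$seed, x$k, x$m, x$S_m, x$S_n))
  invisible(x)
}

#' Run the greedy search from every gene
#'
#' One module per seed gene; modules smaller than
#' `params$min_module_size` are discarded. The result is ordered by
#' decreasing `S_n`, ties by seed symbol.
#'
#' @param wn a `weighted_network`.
#' @param params a [search_params()].
#' @param seeds optional subset of seed genes (default: all genes).
#' @return list of `ew_module` objects (class `ew_module_list`).
#' @export
search_all <- function(wn, params = search_params(), seeds = wn$genes) {
  mods <- lapply(seeds, function(g) greedy_search(wn, g, params))
  mods <- Filter(function(mo) mo$k >= params$min_module_size, mods)
  ord <- order(-vapply(mods, `[[`, 0, "S_n"),
               vapply(mods, `[[`, "", "seed"))
  structure(mods[ord], class = "ew_module_list")
}

#' Permutation significance of modules
#'
#' For each module, `B` random modules of the same `(k, m)` are drawn by
#' [sample_null_scores()] and the empirical p-value is
#' `(1 + #{S_m_null >= S_m_obs}) / (B + 1)`; q-values are BH-adjusted across
#' all modules. Null draws are cached per `(k, m)`.
#'
#' @param modules an `ew_module_list` (or list of `ew_module`).
#' @param wn a `weighted_network`.
#' @param B number of null draws per distinct `(k, m)` (>= 1000 recommended
#'   for production use).
#' @param seed integer seed.
#' @param q_threshold significance threshold on q (default 0.05).
#' @return the module list with `p` and `q` added to each module and an
#'   attribute `significant` holding the indices with `q < q_threshold`.
#' @export
module_significance <- function(modules, wn, B = 1000L, seed = 1L,
                                q_threshold = 0.05) {
  if (length(modules) == 0L) {
    attr(modules, "significant") <- integer(0)
    return(modules)
  }
  cache <- new.env(parent = emptyenv())
  p <- with_seed(seed, vapply(modules, function(mo) {
    key <- paste0("k", mo$k, "m", mo$m)
    draws <- cache[[key]]
    if (is.null(draws)) {
      draws <- sample_null_scores(wn, mo$k, mo$m, B)
      cache[[key]] <- draws
    }
    (1 + sum(draws >= mo$S_m)) / (B + 1)
  }, 0))
  q <- stats::p.adjust(p, method = "BH")
  for (i in seq_along(modules)) {
    modules[[i]]$p <- p[i]
    modules[[i]]$q <- q[i]
  }
  attr(modules, "significant") <- which(q < q_threshold)
  modules
}

#' Tabulate a module list
#'
#' @param modules an `ew_module_list`.
#' @return data.frame with one row per module: `seed`, `genes` (`;`-joined),
#'   `k`, `m`, `S_m`, `S_n` and, if present, `p`, `q`.
#' @export
modules_to_table <- function(modules) {
  if (length(modules) == 0L)
    return(data.frame(seed = character(), genes = character(), k = integer(),
                      m = integer(), S_m = numeric(), S_n = numeric(),
                      p = numeric(), q = numeric(), stringsAsFactors = FALSE))
  data.frame(
    seed = vapply(modules, `[[`, "", "seed"),
    genes = vapply(modules, function(mo) paste(mo$genes, collapse = ";"), ""),
    k = vapply(modules, `[[`, 0L, "k"),
    m = vapply(modules, `[[`, 0L, "m"),
    S_m = vapply(modules, `[[`, 0, "S_m"),
    S_n = vapply(modules, `[[`, 0, "S_n"),
    p = vapply(modules, function(mo) mo$p %||% NA_real_, 0),
    q = vapply(modules, function(mo) mo$q %||% NA_real_, 0),
    stringsAsFactors = FALSE, row.names = NULL)
}
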