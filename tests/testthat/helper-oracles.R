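# Independent oracles and fixture builders shared across test files.
# These deliberately avoid the package's internal data structures and
# incremental bookkeeping: scores are recomputed from scratch from edge
# lists so that agreement with the package is a real cross-check.

# Build a weighted_network from an explicit edge data.frame (from, to, w)
# and a named z vector, via the package's low-level constructor.
toy_network <- function(edges, z, lambda = NULL) {
  g <- igraph::graph_from_edgelist(as.matrix(edges[, 1:2]), directed = FALSE)
  miss <- setdiff(names(z), igraph::V(g)$name)
  if (length(miss)) g <- igraph::add_vertices(g, length(miss), name = miss)
  # edge weights in igraph edge order
  el <- igraph::as_edgelist(g)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  w <- edges[, 3][match(key(el[, 1], el[, 2]), key(edges[, 1], edges[, 2]))]
  weighted_network(g, unname(z[igraph::V(g)$name]), w, lambda = lambda)
}

# Step-by-step greedy oracle: plain set arithmetic over an edge data.frame,
# full recomputation at every step.
oracle_greedy <- function(edges, z, lambda, mu_z, sd_z, mu_w, sd_w,
                          seed_gene, r = 0.005) {
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ew <- stats::setNames(edges[, 3], ekey(edges[, 1], edges[, 2]))
  nbrs <- function(g) unique(c(edges[, 2][edges[, 1] == g],
                               edges[, 1][edges[, 2] == g]))
  sn <- function(members) {
    k <- length(members)
    pairs <- if (k >= 2) utils::combn(sort(members), 2) else
      matrix(character(), 2, 0)
    keys <- ekey(pairs[1, ], pairs[2, ])
    keys <- keys[keys %in% names(ew)]
    m <- length(keys)
    s_m <- lambda * sum(z[members]) / sqrt(k)
    if (m > 0) s_m <- s_m + (1 - lambda) * sum(ew[keys]) / sqrt(m)
    (s_m - (lambda * sqrt(k) * mu_z + (1 - lambda) * sqrt(m) * mu_w)) /
      sqrt(lambda^2 * sd_z^2 + (1 - lambda)^2 * sd_w^2)
  }
  members <- seed_gene
  s_old <- sn(members)
  repeat {
    cand <- setdiff(unique(unlist(lapply(members, nbrs))), members)
    if (length(cand) == 0) break
    s_new <- vapply(cand, function(g) sn(c(members, g)), 0)
    best_s <- max(s_new)
    best <- cand[s_new == best_s]
    if (length(best) > 1) best <- best[z[best] == max(z[best])]
    if (length(best) > 1) best <- sort(best)[1]
    ok <- if (s_old > 0) best_s >= s_old * (1 + r)
          else best_s >= s_old + abs(s_old) * r
    if (!ok) break
    members <- c(members, best[1])
    s_old <- best_s
  }
  sort(members)
}

# Random connected graph as an edge data.frame with random weights.
random_connected_edges <- function(n, extra_p = 0.3) {
  # random spanning tree, then extra edges
  nodes <- sprintf("n%02d", seq_len(n))
  edges <- NULL
  if (n >= 2)
    for (i in 2:n)
      edges <- rbind(edges, data.frame(a = nodes[sample.int(i - 1, 1)],
                                       b = nodes[i]))
  if (n >= 3) {
    all_pairs <- t(utils::combn(nodes, 2))
    have <- paste(pmin(edges$a, edges$b), pmax(edges$a, edges$b))
    free <- all_pairs[!paste(all_pairs[, 1], all_pairs[, 2]) %in% have, ,
                      drop = FALSE]
    take <- stats::runif(nrow(free)) < extra_p
    if (any(take))
      edges <- rbind(edges, data.frame(a = free[take, 1], b = free[take, 2]))
  }
  edges$w <- abs(stats::rnorm(nrow(edges)))
  edges
}

# Reference BH step-up: q_(i) = min_{j >= i} p_(j) * n / j on sorted p.
bh_reference <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- rev(cummin(rev(p[o] * n / seq_len(n))))
  pmin(q, 1)[order(o)]
}

# Dense eigendecomposition oracle for eigencentrality.
eigen_centrality_oracle <- function(graph) {
  a <- igraph::as_adjacency_matrix(graph, sparse = FALSE)
  e <- eigen(a, symmetric = TRUE)
  v <- abs(e$vectors[, which.max(e$values)])
  stats::setNames(v / max(v), rownames(a))
}

# Exact upper-tail hypergeometric by direct summation of choose() ratios.
hyper_tail_oracle <- function(overlap, n_a, n_b, n_bg) {
  kmax <- min(n_a, n_b)
  if (overlap > kmax) return(0)
  sum(vapply(overlap:kmax, function(k) {
    exp(lchoose(n_a, k) + lchoose(n_bg - n_a, n_b - k) - lchoose(n_bg, n_b))
  }, 0))
}

# Small strong-signal config used by several integration tests.
small_config <- function(seed = 1, ...) {
  args <- list(n_genes = 300L, attach_m = 3L, planted_size = 15L,
               planted_density = 0.4, gwas_alpha = 0.1, rho_base = 0.2,
               delta_rho = 0.6, sscore_shift = 3, probesets_per_gene = 2L,
               seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_config, args)
}
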