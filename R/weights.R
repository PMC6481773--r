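# Node weights, edge weights, the lambda balance factor, and the weighted
# background network object used by the module search.

#' GWAS node weights
#'
#' Converts gene-level GWAS p-values to node weights
#' `z = qnorm(1 - p)` (the upper-tail standard-normal quantile), so that
#' smaller p-values give larger weights. P-values are clipped to
#' `[eps, 1 - eps]` before transformation to keep weights finite.
#'
#' @param gwas named numeric vector of gene-level p-values in `(0, 1]`.
#' @param eps clipping bound (default `1e-16`).
#' @return named numeric vector of node weights.
#' @export
node_weights <- function(gwas, eps = 1e-16) {
  if (any(!is.finite(gwas)) || any(gwas <= 0) || any(gwas > 1))
    stop("GWAS p-values must lie in (0, 1]")
  p <- pmin(pmax(gwas, eps), 1 - eps)
  stats::qnorm(1 - p)
}

#' Differential co-expression edge weights
#'
#' For each background edge (i, j), Pearson correlations of the two genes'
#' expression across strains are computed separately in the control and
#' treatment panels and contrasted on the Fisher-z scale:
#' `w = |atanh(r_trt) - atanh(r_ctrl)| / sqrt(1/(n_trt - 3) + 1/(n_ctrl - 3))`.
#' Correlations are clipped to `+/-(1 - 1e-12)` before `atanh`; a
#' zero-variance gene contributes correlation 0 (logged). `mode = "raw"`
#' gives the unstandardized `|r_trt - r_ctrl|` instead.
#'
#' @param ctrl,trt gene-level `expression_panel` objects covering all
#'   background genes; each condition needs more than 3 strains.
#' @param background background [igraph] graph.
#' @param mode `"fisherz"` (default) or `"raw"`.
#' @return numeric vector of non-negative edge weights, ordered as
#'   `igraph::E(background)`.
#' @export
edge_weights <- function(ctrl, trt, background, mode = c("fisherz", "raw")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ctrl, "expression_panel"),
            inherits(trt, "expression_panel"))
  n_c <- ncol(ctrl$values); n_t <- ncol(trt$values)
  if (n_c <= 3L || n_t <= 3L)
    stop("each condition needs more than 3 strains")
  genes <- igraph::V(background)$name
  if (!all(genes %in% rownames(ctrl$values)) ||
      !all(genes %in% rownames(trt$values)))
    stop("expression panels must cover all background genes")
  scale_rows <- function(m) {
    mu <- rowMeans(m)
    sd <- sqrt(rowSums((m - mu)^2))
    zv <- sd == 0
    if (any(zv))
      log_event("edge_weights: ", sum(zv),
                " zero-variance gene(s); correlations set to 0")
    sd[zv] <- Inf  # rows become 0, correlations with them 0
    (m - mu) / sd
  }
  xc <- scale_rows(ctrl$values[genes, , drop = FALSE])
  xt <- scale_rows(trt$values[genes, , drop = FALSE])
  el <- igraph::as_edgelist(background, names = FALSE)
  r_c <- unname(rowSums(xc[el[, 1], , drop = FALSE] *
                          xc[el[, 2], , drop = FALSE]))
  r_t <- unname(rowSums(xt[el[, 1], , drop = FALSE] *
                          xt[el[, 2], , drop = FALSE]))
  if (mode == "raw") return(abs(r_t - r_c))
  clip <- 1 - 1e-12
  r_c <- pmin(pmax(r_c, -clip), clip)
  r_t <- pmin(pmax(r_t, -clip), clip)
  abs(atanh(r_t) - atanh(r_c)) / sqrt(1 / (n_t - 3) + 1 / (n_c - 3))
}

#' Node/edge balance factor lambda
#'
#' `lambda = mean(|w|) / (mean(|z|) + mean(|w|))`, so that
#' `lambda * mean(|z|) = (1 - lambda) * mean(|w|)`: the expected per-element
#' contributions of nodes and edges to a module score are equalized, which
#' prevents the search from being driven by node weights or edge weights
#' alone. Computed once from the full background before any search.
#'
#' @param z numeric vector of node weights.
#' @param w numeric vector of edge weights.
#' @return lambda in `(0, 1)`.
#' @export
compute_lambda <- function(z, w) {
  if (length(z) == 0L || length(w) == 0L)
    stop("node- and edge-weight sets must be non-empty")
  mz <- mean(abs(z)); mw <- mean(abs(w))
  if (mz + mw == 0) stop("all weights are zero; lambda is undefined")
  if (mz == 0 || mw == 0)
    stop("one weight class is identically zero; lambda would be degenerate")
  mw / (mz + mw)
}

#' Assemble the weighted background network
#'
#' Bundles the background graph with node weights, edge weights, the lambda
#' balance factor and the genome-wide weight moments used for analytic score
#' standardization, plus adjacency structures for the greedy search.
#'
#' @param background background [igraph] graph.
#' @param gwas named p-value vector covering all background genes.
#' @param ctrl,trt gene-level `expression_panel` objects.
#' @param edge_mode `"fisherz"` or `"raw"` (see [edge_weights()]).
#' @param lambda optional fixed lambda; default computed by
#'   [compute_lambda()].
#' @return object of class `weighted_network`.
#' @export
build_weighted_network <- function(background, gwas, ctrl, trt,
                                   edge_mode = "fisherz", lambda = NULL) {
  genes <- igraph::V(background)$name
  if (!all(genes %in% names(gwas)))
    stop("GWAS table must cover all background genes")
  z <- node_weights(gwas[genes])
  w <- edge_weights(ctrl, trt, background, mode = edge_mode)
  weighted_network(background, z, w, lambda = lambda, edge_mode = edge_mode)
}

#' Construct a weighted network from precomputed weights
#'
#' Low-level constructor taking node and edge weights directly; the weight
#' moments are computed over the full background and lambda defaults to
#' [compute_lambda()].
#'
#' @param background background [igraph] graph.
#' @param z numeric node weights, ordered as `igraph::V(background)`.
#' @param w numeric non-negative edge weights, ordered as
#'   `igraph::E(background)`.
#' @param lambda optional fixed balance factor.
#' @param edge_mode label recorded for provenance.
#' @return object of class `weighted_network`.
#' @export
weighted_network <- function(background, z, w, lambda = NULL,
                             edge_mode = "precomputed") {
  genes <- igraph::V(background)$name
  stopifnot(length(z) == length(genes),
            length(w) == igraph::ecount(background))
  lambda <- lambda %||% compute_lambda(z, w)
  el <- igraph::as_edgelist(background, names = FALSE)
  n <- length(genes)
  adj <- vector("list", n); adj_w <- vector("list", n)
  deg <- tabulate(c(el[, 1], el[, 2]), nbins = n)
  for (i in seq_len(n)) {
    adj[[i]] <- integer(deg[i]); adj_w[[i]] <- numeric(deg[i])
  }
  fill <- integer(n)
  for (e in seq_len(nrow(el))) {
    a <- el[e, 1]; b <- el[e, 2]
    fill[a] <- fill[a] + 1L; adj[[a]][fill[a]] <- b; adj_w[[a]][fill[a]] <- w[e]
    fill[b] <- fill[b] + 1L; adj[[b]][fill[b]] <- a; adj_w[[b]][fill[b]] <- w[e]
  }
  # a zero sd is tolerated here (tiny or degenerate graphs); score
  # standardization checks that the combined null sd is positive
  sd_z <- stats::sd(z); sd_w <- if (length(w) > 1L) stats::sd(w) else 0
  if (!is.finite(sd_z)) sd_z <- 0
  if (!is.finite(sd_w)) sd_w <- 0
  structure(list(graph = background, genes = genes, z = stats::setNames(z, genes),
                 edges = el, w = w, lambda = lambda,
                 mu_z = mean(z), sd_z = sd_z, mu_w = mean(w), sd_w = sd_w,
                 adj = adj, adj_w = adj_w, edge_mode = edge_mode),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf(paste0("weighted_network: %d genes, %d edges, lambda = %.4f\n",
                     "  z: mean %.4f sd %.4f | w: mean %.4f sd %.4f\n"),
              length(x$genes), nrow(x$edges), x$lambda,
              x$mu_z, x$sd_z, x$mu_w, x$sd_w))
  invisible(x)
}
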