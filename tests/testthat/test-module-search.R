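# Module search: weights, lambda, scores, standardization, greedy growth
# and permutation significance.

test_that("node weights are the upper-tail normal quantile of p", {
  expect_equal(unname(node_weights(c(g = 0.5))), 0)
  expect_equal(unname(node_weights(c(g = 0.025))), 1.95996, tolerance = 1e-5)
  expect_equal(unname(node_weights(c(g = 0.025))), stats::qnorm(0.975),
               tolerance = 1e-12)
  # p = 1 clips to 1 - eps: large negative but finite
  z1 <- unname(node_weights(c(g = 1)))
  expect_true(is.finite(z1) && z1 < -5)
  expect_error(node_weights(c(g = 0)), "\\(0, 1\\]")
  expect_error(node_weights(c(g = 1.2)), "\\(0, 1\\]")
  # strictly antitone in p
  p <- sort(stats::runif(50, 1e-6, 1 - 1e-6))
  expect_true(all(diff(unname(node_weights(p))) < 0))
})

make_corr_panels <- function(r_ctrl, r_trt, n = 30) {
  # two genes with exactly the requested Pearson correlation per condition,
  # via orthonormalized base vectors
  base <- function(n, r, seed) {
    set.seed(seed)
    x <- scale(stats::rnorm(n))[, 1]
    u <- stats::residuals(stats::lm(stats::rnorm(n) ~ x))
    u <- u / sqrt(sum(u^2) / (n - 1))
    x <- x / sqrt(sum(x^2) / (n - 1))
    rbind(A = x, B = r * x + sqrt(1 - r^2) * u)
  }
  mk <- function(m, cond) {
    dimnames(m) <- list(c("A", "B"), sprintf("s%02d", seq_len(ncol(m))))
    expression_panel(m, "R1", cond)
  }
  list(control = mk(base(n, r_ctrl, 1), "control"),
       treatment = mk(base(n, r_trt, 2), "treatment"))
}

test_that("edge weights standardize the Fisher-z correlation difference", {
  g <- igraph::make_graph(~ A - B)
  pan <- make_corr_panels(0, 0.5, n = 30)
  w <- edge_weights(pan$control, pan$treatment, g)
  expect_equal(w, atanh(0.5) / sqrt(2 / 27), tolerance = 1e-8)
  expect_equal(w, 2.0182, tolerance = 1e-4)
  # identical correlations give zero weight
  pan0 <- make_corr_panels(0.4, 0.4)
  expect_equal(edge_weights(pan0$control, pan0$treatment, g), 0,
               tolerance = 1e-10)
  # raw mode
  expect_equal(edge_weights(pan$control, pan$treatment, g, mode = "raw"),
               0.5, tolerance = 1e-8)
  # near-perfect correlation is clipped to a finite weight
  pan1 <- make_corr_panels(0, 1)
  expect_true(is.finite(edge_weights(pan1$control, pan1$treatment, g)))
  # symmetric in edge orientation
  g2 <- igraph::make_graph(~ B - A)
  expect_equal(edge_weights(pan$control, pan$treatment, g2), w)
  # too few strains
  pan2 <- make_corr_panels(0, 0.5, n = 4)
  pan2$control$values <- pan2$control$values[, 1:3]
  expect_error(edge_weights(pan2$control, pan2$treatment, g), "3 strains")
})

test_that("zero-variance genes contribute correlation zero", {
  g <- igraph::make_graph(~ A - B)
  m <- rbind(A = rep(1, 10), B = stats::rnorm(10))
  colnames(m) <- sprintf("s%02d", 1:10)
  pan <- list(control = expression_panel(m, "R1", "control"),
              treatment = expression_panel(m + 0.1, "R1", "treatment"))
  expect_equal(edge_weights(pan$control, pan$treatment, g), 0)
})

test_that("lambda equalizes expected node and edge contributions", {
  expect_equal(compute_lambda(c(1, -1, 2), c(1, 2, 1)), 0.5)
  lam <- compute_lambda(c(1, 1), c(3, 3))
  expect_equal(lam, 0.75)
  expect_equal(lam * 1, (1 - lam) * 3)  # algebraic balance
  expect_error(compute_lambda(c(1, 2), numeric(0)), "non-empty")
  expect_error(compute_lambda(c(0, 0), c(0, 0)), "zero")
})

test_that("raw module score follows the lambda-weighted sum formula", {
  edges <- data.frame(a = "g1", b = "g2", w = 3)
  wn <- toy_network(edges, c(g1 = 2, g2 = 2, g3 = 1.5), lambda = 0.5)
  expect_equal(module_raw_score(c("g1", "g2"), wn),
               0.5 * 4 / sqrt(2) + 0.5 * 3, tolerance = 1e-12)
  expect_equal(module_raw_score(c("g1", "g2"), wn), 2.9142, tolerance = 1e-4)
  # singleton: edge term vanishes
  expect_equal(module_raw_score("g3", wn), 0.5 * 1.5)
  # insertion order invariance
  expect_equal(module_raw_score(c("g2", "g1"), wn),
               module_raw_score(c("g1", "g2"), wn))
  expect_error(module_raw_score(character(0), wn), "empty")
  # all-zero weights score zero
  wn0 <- toy_network(edges, c(g1 = 0, g2 = 0, g3 = 0), lambda = 0.5)
  wn0$w <- 0
  expect_equal(module_raw_score(c("g1", "g2"), wn0), 0)
})

test_that("adding a zero-weight gene strictly lowers the raw score", {
  set.seed(10)
  for (i in 1:20) {
    n <- sample(4:9, 1)
    edges <- random_connected_edges(n)
    z <- stats::setNames(abs(stats::rnorm(n)) + 0.1, sprintf("n%02d", 1:n))
    wn <- toy_network(edges, z, lambda = 0.5)
    k <- sample(2:(n - 1), 1)
    genes <- sample(names(z), k)
    s0 <- module_raw_score(genes, wn)
    # append an isolated zero-weight gene (same lambda: fixed before search)
    wn2 <- toy_network(edges, c(z, zz = 0), lambda = 0.5)
    expect_lt(module_raw_score(c(genes, "zz"), wn2), s0)
  }
})

test_that("analytic standardization matches the plug-in formula", {
  edges <- data.frame(a = "g1", b = "g2", w = 3)
  wn <- toy_network(edges, c(g1 = 2, g2 = 2), lambda = 0.5)
  # impose unit background moments to check the arithmetic exactly
  wn$mu_z <- 0; wn$sd_z <- 1; wn$mu_w <- 0; wn$sd_w <- 1
  sn <- standardize_score(c("g1", "g2"), wn)
  expect_equal(sn, 2.9142135 / sqrt(0.5), tolerance = 1e-6)
  expect_equal(sn, 4.1213, tolerance = 1e-4)
  # a module scoring exactly its null mean standardizes to zero
  wn$mu_z <- 2; wn$mu_w <- 3 / sqrt(1)  # mean = .5*sqrt(2)*2 + .5*1*3
  s_m <- module_raw_score(c("g1", "g2"), wn)
  expect_equal(s_m, 0.5 * sqrt(2) * 2 + 0.5 * sqrt(1) * 3, tolerance = 1e-12)
  expect_equal(standardize_score(c("g1", "g2"), wn), 0, tolerance = 1e-12)
})

test_that("monte-carlo standardization agrees with the analytic moments", {
  cfg <- small_config(seed = 13)
  res <- generate_ppi(cfg)
  gw <- generate_gwas(res$truth)
  ex <- generate_expression(res$truth)
  bg <- build_background(res$graph, names(gw), rownames(ex$control$values))
  wn <- build_weighted_network(bg, gw, ex$control, ex$treatment)
  set.seed(14)
  gaps <- vapply(1:15, function(i) {
    k <- sample(5:15, 1)
    genes <- sample(wn$genes, k)
    abs(standardize_score(genes, wn, search_params()) -
          standardize_score(genes, wn,
                            search_params(standardization = "montecarlo",
                                          B = 5000, seed = i)))
  }, 0)
  expect_lt(stats::median(gaps), 0.15)
})

test_that("greedy search stops at the seed when no candidate qualifies", {
  edges <- data.frame(a = "s", b = "bad", w = 0)
  wn <- toy_network(edges, c(s = 2, bad = -10), lambda = 0.5)
  mod <- greedy_search(wn, "s")
  expect_identical(mod$genes, "s")
  expect_equal(mod$k, 1L)
  expect_error(greedy_search(wn, "nope"), "absent")
})

test_that("greedy expansion follows the heavy side of a path", {
  # path heavy - seed - light: only the heavy side should be admitted
  edges <- data.frame(a = c("seed", "seed"), b = c("heavy", "light"),
                      w = c(5, 0.01))
  wn <- toy_network(edges, c(seed = 1, heavy = 4, light = -3), lambda = 0.5)
  mod <- greedy_search(wn, "seed")
  expect_true("heavy" %in% mod$genes)
  expect_false("light" %in% mod$genes)
})

test_that("greedy search matches the step-by-step oracle on small graphs", {
  set.seed(15)
  for (i in 1:40) {
    n <- sample(2:8, 1)
    edges <- random_connected_edges(n)
    z <- stats::setNames(stats::rnorm(n), sprintf("n%02d", seq_len(n)))
    wn <- toy_network(edges, z)
    for (seed_gene in wn$genes) {
      mod <- greedy_search(wn, seed_gene)
      orc <- oracle_greedy(edges, z, wn$lambda, wn$mu_z, wn$sd_z,
                           wn$mu_w, wn$sd_w, seed_gene)
      expect_identical(mod$genes, orc)
    }
  }
})

test_that("search_all is deterministic, ordered, and recovers planted signal", {
  cfg <- small_config(seed = 16)
  res <- generate_ppi(cfg)
  gw <- generate_gwas(res$truth)
  ex <- generate_expression(res$truth)
  bg <- build_background(res$graph, names(gw), rownames(ex$control$values))
  wn <- build_weighted_network(bg, gw, ex$control, ex$treatment)
  mods <- search_all(wn)
  expect_identical(modules_to_table(mods), modules_to_table(search_all(wn)))
  sn <- vapply(mods, `[[`, 0, "S_n")
  expect_true(all(diff(sn) <= 1e-12))
  expect_true(all(vapply(mods, `[[`, 0L, "k") >= 5L))
  # strongest module contains mostly planted genes
  top <- mods[[1]]$genes
  expect_gt(length(intersect(top, res$truth$planted_genes)) / length(top), 0.5)
  # modules are connected by construction
  for (mo in mods[seq_len(min(10, length(mods)))])
    expect_true(igraph::is_connected(igraph::induced_subgraph(bg, mo$genes)))
})

test_that("under the full null the top module is not planted-enriched", {
  cfg <- small_config(seed = 17, gwas_alpha = 1, delta_rho = 0,
                      sscore_shift = 0)
  res <- generate_ppi(cfg)
  gw <- generate_gwas(res$truth, alpha = 1)
  ex <- generate_expression(res$truth)
  bg <- build_background(res$graph, names(gw), rownames(ex$control$values))
  wn <- build_weighted_network(bg, gw, ex$control, ex$treatment)
  mods <- search_all(wn)
  if (length(mods)) {
    top <- unique(unlist(lapply(mods[seq_len(min(5, length(mods)))],
                                `[[`, "genes")))
    prec <- length(intersect(top, res$truth$planted_genes)) / length(top)
    # at-chance precision: planted fraction of the background is 15/300
    expect_lt(prec, 0.25)
  }
  succeed()
})

test_that("module significance uses the (b+1)/(B+1) floor and BH", {
  edges <- data.frame(a = c("g1", "g2"), b = c("g2", "g3"), w = c(1, 2))
  wn <- toy_network(edges, c(g1 = 1, g2 = 2, g3 = 0.5))
  mods <- structure(list(greedy_search(wn, "g2")), class = "ew_module_list")
  # an extreme module: inflate its S_m beyond anything samplable
  mods[[1]]$S_m <- 1e6
  out <- module_significance(mods, wn, B = 200, seed = 18)
  expect_equal(out[[1]]$p, 1 / 201)
  expect_gte(out[[1]]$q, out[[1]]$p)
  # empty input passes through
  empty <- module_significance(structure(list(), class = "ew_module_list"),
                               wn, B = 10, seed = 1)
  expect_length(empty, 0)
})
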