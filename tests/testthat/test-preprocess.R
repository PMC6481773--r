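# Preprocessing: Fisher combination, responsiveness calls and their
# permutation null, probeset collapse, homolog mapping, background
# construction.

test_that("fisher_combine matches the chi-square closed form", {
  expect_equal(fisher_combine(c(1, 1))$statistic, 0)
  expect_equal(fisher_combine(c(1, 1))$p, 1)
  f <- fisher_combine(c(0.1, 0.1))
  expect_equal(f$statistic, -2 * log(0.01), tolerance = 1e-12)
  expect_equal(f$statistic, 9.2103, tolerance = 1e-4)
  expect_equal(f$df, 4L)
  # chi-square(4) survival at x: (1 + x/2) exp(-x/2) = 0.01 (1 - log 0.01)
  expect_equal(f$p, 0.01 * (1 - log(0.01)), tolerance = 1e-12)
  expect_equal(f$p, 0.0561, tolerance = 1e-3)
  # Fisher of a single p returns that p
  f1 <- fisher_combine(0.05)
  expect_equal(f1$statistic, -2 * log(0.05), tolerance = 1e-12)
  expect_equal(f1$p, 0.05, tolerance = 1e-12)
  # closed-form agreement on random inputs
  set.seed(1)
  for (i in 1:20) {
    p <- stats::runif(sample(1:10, 1))
    f <- fisher_combine(p)
    expect_equal(f$p, stats::pchisq(-2 * sum(log(p)), 2 * length(p),
                                    lower.tail = FALSE), tolerance = 1e-12)
  }
  expect_error(fisher_combine(numeric(0)), "empty")
  expect_error(fisher_combine(c(0.5, 0)), "0, 1")
})

test_that("responsive_calls handles degenerate and extreme panels", {
  zero <- sscore_panel(matrix(0, 5, 6,
                              dimnames = list(paste0("ps", 1:5),
                                              paste0("s", 1:6))), "R1")
  rc <- responsive_calls(zero, n_perm = 200, seed = 1)
  expect_true(all(rc$empirical_p == 1))
  expect_true(all(rc$analytic_p == 1))
  # one extreme probeset among nulls hits the permutation floor
  set.seed(2)
  m <- matrix(stats::rnorm(50 * 30), 50, 30,
              dimnames = list(sprintf("ps%02d", 1:50), sprintf("s%02d", 1:30)))
  m[7, ] <- 5
  rc <- responsive_calls(sscore_panel(m, "R1"), n_perm = 200, seed = 3)
  expect_equal(rc$empirical_p[rc$probeset == "ps07"], 1 / 201)
  expect_equal(rc$df, rep(60L, 50))
  expect_warning(responsive_calls(sscore_panel(m, "R1"), n_perm = 50,
                                  seed = 1), "coarse")
  m[1, 1] <- NA
  expect_error(sscore_panel(m, "R1"), "finite")
})

test_that("null panels give approximately uniform empirical p-values", {
  set.seed(4)
  m <- matrix(stats::rnorm(1500 * 10), 1500, 10,
              dimnames = list(sprintf("ps%04d", 1:1500), sprintf("s%02d", 1:10)))
  rc <- responsive_calls(sscore_panel(m, "R1"), n_perm = 499, seed = 5)
  ks <- max(abs(sort(rc$empirical_p) - seq_along(rc$empirical_p) / 1500))
  expect_lt(ks, 0.05)
})

test_that("filter_responsive applies the strict any-region rule", {
  calls <- data.frame(probeset = c("a", "a", "a", "b", "b", "b", "c"),
                      region = c("R1", "R2", "R3", "R1", "R2", "R3", "R1"),
                      q = c(0.05, 0.5, 0.5, 0.1, 0.1, 0.1, 0.2))
  expect_identical(filter_responsive(calls, 0.1), "a")  # b at 0.1 exactly: out
  expect_identical(filter_responsive(calls, 0.21), c("a", "b", "c"))
})

test_that("responsive filter respects the nominal FDR under the full null", {
  frac <- vapply(1:5, function(s) {
    set.seed(s)
    m <- matrix(stats::rnorm(800 * 10), 800, 10,
                dimnames = list(sprintf("ps%03d", 1:800), sprintf("s%02d", 1:10)))
    rc <- responsive_calls(sscore_panel(m, "R1"), n_perm = 300, seed = s)
    length(filter_responsive(rc, 0.1)) / 800
  }, 0)
  expect_lte(mean(frac), 2 * 0.1)
})

test_that("collapse_probesets keeps the probeset with maximal mean RMA", {
  mk <- function(vals, cond) {
    m <- matrix(vals, nrow = 4, ncol = 3, byrow = TRUE,
                dimnames = list(c("psA1", "psA2", "psB1", "psC2"),
                                paste0("s", 1:3)))
    expression_panel(m, "R1", cond)
  }
  ctrl <- mk(c(7.1, 7.1, 7.1,  9.3, 9.3, 9.3,  5, 5, 5,  4, 4, 4), "control")
  trt  <- mk(c(7.1, 7.1, 7.1,  9.3, 9.3, 9.3,  5, 5, 5,  4, 4, 4), "treatment")
  map <- data.frame(probeset = c("psA1", "psA2", "psB1", "psC2"),
                    gene = c("GA", "GA", "GB", "GC"))
  out <- collapse_probesets(ctrl, trt, map)
  expect_equal(rownames(out$control$values), c("GA", "GB", "GC"))
  expect_equal(unname(out$control$values["GA", 1]), 9.3)  # max-RMA probeset
  expect_equal(unname(out$control$values["GB", 1]), 5)    # single passthrough
  # tie in mean RMA: lexicographically smallest probeset id wins
  ctrl2 <- mk(c(8, 8, 8,  8, 8, 8,  5, 5, 5,  4, 4, 4), "control")
  trt2  <- mk(c(8, 8, 8,  8, 8, 8,  5, 5, 5,  4, 4, 4), "treatment")
  out2a <- collapse_probesets(ctrl2, trt2, map)
  out2b <- collapse_probesets(ctrl2, trt2, map)
  expect_identical(out2a, out2b)
  # which probeset won is deterministic: psA1 < psA2
  ctrl3 <- ctrl2; ctrl3$values["psA1", ] <- c(8, 8, 8.0)
  expect_equal(unname(out2a$control$values["GA", ]), c(8, 8, 8))
  expect_error(collapse_probesets(ctrl, trt,
                                  rbind(map, data.frame(probeset = "psA1",
                                                        gene = "GX"))),
               "multiple genes")
  # collapse never increases gene count
  expect_lte(nrow(out$control$values), nrow(ctrl$values))
})

test_that("map_homologs renames, drops unmapped, and resolves collisions", {
  m <- matrix(c(1, 1, 1, 2, 2, 2, 9, 9, 9, 3, 3, 3), 4, 3, byrow = TRUE,
              dimnames = list(c("MA", "MB", "MC", "MD"), paste0("s", 1:3)))
  panels <- list(control = expression_panel(m, "R1", "control"),
                 treatment = expression_panel(m + 0.5, "R1", "treatment"))
  ident <- data.frame(source = rownames(m), target = rownames(m))
  out <- map_homologs(panels, ident)
  expect_identical(out$control$values, panels$control$values)
  # 4 genes, 3 mapped -> 3 survive; MB and MC collide on HB, higher RMA wins
  hm <- data.frame(source = c("MA", "MB", "MC"),
                   target = c("HA", "HB", "HB"))
  out2 <- map_homologs(panels, hm)
  expect_setequal(rownames(out2$control$values), c("HA", "HB"))
  expect_equal(unname(out2$control$values["HB", 1]), 9)  # MC (mean 9.25) wins
  expect_identical(map_homologs(panels, hm), out2)       # deterministic
  expect_error(map_homologs(panels, data.frame(source = "ZZ", target = "Y")),
               "no gene")
  expect_error(map_homologs(panels, rbind(hm, hm[1, ])), "duplicate")
})

test_that("build_background intersects universes and drops isolated nodes", {
  tri <- igraph::make_ring(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  bg <- build_background(tri, c("a", "b"), c("a", "b", "c"))
  expect_setequal(igraph::V(bg)$name, c("a", "b"))
  expect_equal(igraph::ecount(bg), 1L)
  # identity: all universes equal -> PPI minus degree-0 nodes
  g <- igraph::make_graph(~ a - b, c - d, e)
  bg2 <- build_background(g, igraph::V(g)$name, igraph::V(g)$name)
  expect_setequal(igraph::V(bg2)$name, c("a", "b", "c", "d"))
  expect_error(build_background(tri, "zz", "a"), "empty")
  # synthetic bundle vs set-arithmetic oracle
  cfg <- small_config(seed = 8)
  res <- generate_ppi(cfg)
  gw <- generate_gwas(res$truth)
  gwas_genes <- names(gw)[seq_len(250)]
  expr_genes <- rownames(generate_expression(res$truth)$control$values)[26:300]
  bg3 <- build_background(res$graph, gwas_genes, expr_genes)
  common <- intersect(intersect(igraph::V(res$graph)$name, gwas_genes),
                      expr_genes)
  sub <- igraph::induced_subgraph(res$graph, common)
  keep <- names(which(igraph::degree(sub) > 0))
  expect_setequal(igraph::V(bg3)$name, keep)
})

test_that("BH q-values match the step-up reference and are monotone", {
  set.seed(9)
  for (i in 1:10) {
    p <- stats::runif(50)
    q <- stats::p.adjust(p, method = "BH")
    expect_equal(q, bh_reference(p), tolerance = 1e-12)
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
    expect_true(all(q <= 1 & q >= p))
  }
})
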