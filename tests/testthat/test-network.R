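test_that("edge normalization merges duplicates with provenance union", {
  e <- data.frame(src = c("b", "A", "A", "C"),
                  dst = c("a", "B", "A", "c"),
                  source = c("textmine", "string", "textmine", "textmine"))
  out <- normalize_edges(e)
  # self-loop A-A dropped, C-c dropped (self after normalization)
  expect_equal(nrow(out), 1)
  expect_equal(out$src, "A")
  expect_equal(out$dst, "B")
  expect_equal(out$source, "both")
  # idempotent
  expect_equal(normalize_edges(out), out)
})

test_that("network assembly places shells and excludes core-disconnected nodes", {
  e <- data.frame(src = c("B", "C"), dst = c("A", "B"))
  net <- assemble_network(e, core_set = "A")
  expect_equal(sort(net$nodes$gene), c("A", "B"))
  expect_equal(net$nodes$shell[net$nodes$gene == "B"], "outer_shell")
  expect_false("C" %in% net$nodes$gene)
  expect_error(assemble_network(e, core_set = character(0)), "non-empty")
})

test_that("packaged synthetic fixture reproduces the 14+16+17 shell arithmetic", {
  edges <- read_edge_list(system.file("extdata",
                                      "synthetic_shell_network.tsv",
                                      package = "clocksig"))
  cats <- gene_set_catalog()
  first16 <- cats$clock_related[1:16]
  net <- assemble_network(edges, core_set = cats$core_clock,
                          first_shell = first16)
  expect_equal(net$summary$n_core, 14)
  expect_equal(net$summary$n_first, 16)
  expect_equal(net$summary$n_outer, 17)
  expect_equal(net$summary$n_nodes, 47)
  expect_equal(net$summary$n_edges, 229)
})

test_that("cross-set counting is symmetric and excludes within-set edges", {
  e <- data.frame(src = c("A1", "A1", "B1"), dst = c("B1", "A2", "B2"))
  expect_equal(cross_set_connections(e, c("A1", "A2"), c("B1", "B2")), 1)
  expect_equal(cross_set_connections(e, c("B1", "B2"), c("A1", "A2")), 1)
  expect_equal(cross_set_connections(e, c("A1", "A2"), character(0)), 0)
  expect_warning(cross_set_connections(e, c("ZZ"), c("B1")), "no overlap")
})

test_that("planted cross-set edges exceed the background expectation", {
  net <- gen_network(n_genes = 300, query_size = 20, target_size = 30,
                     rho = 3, seed = 8)
  n_qt <- cross_set_connections(net$edges, net$query, net$target)
  bg <- net$truth$expected_qt_background
  # generator truth: planted excess is ~3x background; the observed count
  # must clearly exceed background (3 sd of a Poisson at the background)
  expect_gt(n_qt, bg + 3 * sqrt(bg))
  expect_gte(n_qt, 0.6 * net$truth$expected_qt)
})

test_that("citation-bin null preserves bin composition and its p bounds", {
  net <- gen_network(n_genes = 500, query_size = 45, rho = 1, seed = 3)
  bin_of <- floor(log2(net$citations + 1))
  nd <- citation_bin_null(net$citations, net$query, list(net$target),
                          net$edges, B = 50, seed = 1)
  expect_length(nd$counts, 50)
  expect_gte(nd$p_empirical, 1 / 51)
  expect_lte(nd$p_empirical, 1)
  # same seed reproduces counts bit-for-bit
  nd2 <- citation_bin_null(net$citations, net$query, list(net$target),
                           net$edges, B = 50, seed = 1)
  expect_identical(nd$counts, nd2$counts)
  expect_error(citation_bin_null(net$citations, net$query,
                                 list(net$target), net$edges, B = 1,
                                 seed = 1), "B must be")
})

test_that("null replicate sets reproduce the query's bin multiset", {
  net <- gen_network(n_genes = 400, query_size = 30, rho = 1, seed = 21)
  bin_of <- floor(log2(net$citations + 1))
  # re-run the sampler logic through the public API at B = 5 and check
  # the bins by reconstructing one replicate via the seed
  nd <- citation_bin_null(net$citations, net$query, list(net$target),
                          net$edges, B = 5, seed = 7)
  expect_equal(sum(nd$bins), length(setdiff(net$query, net$target)))
})

test_that("planted enrichment is detected: rho = 3 gives z >= 3 at seed 1", {
  net <- gen_network(n_genes = 500, query_size = 45, target_size = 60,
                     rho = 3, seed = 1)
  nd <- citation_bin_null(net$citations, net$query, list(net$target),
                          net$edges, B = 50, seed = 1)
  expect_gte(nd$z, 3)
  expect_equal(nd$p_empirical, 1 / 51)
})

test_that("unenriched networks give calibrated z", {
  zs <- vapply(1:10, function(s) {
    net <- gen_network(n_genes = 400, query_size = 30, rho = 1, seed = s)
    # small universes occasionally exhaust a citation bin; the documented
    # fallback to a neighbouring bin warns, which is expected here
    suppressWarnings(
      citation_bin_null(net$citations, net$query, list(net$target),
                        net$edges, B = 30, seed = s)$z)
  }, 0.0)
  expect_gte(sum(abs(zs) <= 2), 8)
})

test_that("signed-rank test matches exact enumeration for n <= 8", {
  set.seed(99)
  for (n in 5:8) {
    for (rep in 1:3) {
      x <- sample(seq(1, 200, by = 3), n)   # distinct values, no ties
      mu <- sample(setdiff(seq(0, 210), x), 1)
      if (all(x == mu)) next
      p_pkg <- wilcoxon_one_sample(x, mu, alternative = "greater")
      p_orc <- oracle_signrank_greater(x, mu)
      expect_equal(p_pkg, p_orc, tolerance = 1e-12,
                   info = sprintf("n=%d rep=%d", n, rep))
    }
  }
})

test_that("signed-rank edge cases behave", {
  # all six nulls strictly below the observed value: exact one-sided 1/64
  expect_equal(wilcoxon_one_sample(1:6, 100, "greater"), 1 / 64)
  expect_warning(p <- wilcoxon_one_sample(rep(5, 6), 5), "zero")
  expect_equal(p, 1)
  # symmetric nulls around the observed value: one-sided near 0.5
  x <- c(-3, -2, -1, 1, 2, 3) + 10
  expect_gt(wilcoxon_one_sample(x, 10, "greater"), 0.3)
  expect_lt(wilcoxon_one_sample(x, 10, "greater"), 0.7)
  expect_error(wilcoxon_one_sample(1:3, 2), "at least 5")
})

test_that("overlap summary counts per-gene incidence", {
  e <- data.frame(src = c("Q1", "Q1", "Q2", "X"),
                  dst = c("A1", "B1", "A2", "B2"))
  ov <- overlap_summary(e, c("Q1", "Q2", "Q3"), c("A1", "A2"),
                        c("B1", "B2"))
  expect_equal(unname(ov$counts), c(2, 1, 1))
  empty <- overlap_summary(data.frame(src = "Z", dst = "W"),
                           c("Q1"), c("A1"), c("B1"))
  expect_equal(unname(empty$counts), c(0, 0, 0))
})
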