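test_that("correlation matrices capture affine and monotone association", {
  x <- seq(-3, 3, length.out = 63)
  df <- data.frame(nodule_id = rep(1:7, each = 9),
                   algorithm_id = rep(rep(1:3, each = 3), 7),
                   init_id = rep(1:3, 21),
                   f1 = x, f2 = 2 * x + 3, f3 = x^3)
  ft <- feature_table(df)
  P <- correlation_matrix(ft, "pearson")
  S <- correlation_matrix(ft, "spearman")
  expect_equal(unname(P["f1", "f2"]), 1)
  expect_equal(unname(S["f1", "f2"]), 1)
  expect_equal(unname(S["f1", "f3"]), 1)   # monotone nonlinear
  expect_lt(P["f1", "f3"], 1)
  expect_true(isSymmetric(unclass(P)))

  # Spearman invariant under a strictly monotone transform of one column
  df2 <- df; df2$f1 <- exp(df2$f1)
  S2 <- correlation_matrix(feature_table(df2), "spearman")
  expect_equal(unclass(S2), unclass(S), ignore_attr = TRUE)

  # constant features yield undefined (NA) off-diagonal entries
  df3 <- df; df3$f3 <- 5
  M3 <- correlation_matrix(feature_table(df3), "pearson")
  expect_true(all(is.na(M3["f3", ])))
  expect_identical(attr(M3, "constant_features"), "f3")
})

test_that("thresholding keeps every node and respects the >= rule", {
  ft <- make_block_table(seed = 2)
  M <- correlation_matrix(ft, "pearson")
  g0 <- threshold_graph(M, 0)
  expect_equal(igraph::vcount(g0), 5)
  expect_identical(connected_subgroups(g0)$count, 1L)
  g1 <- threshold_graph(M, 1 - 1e-9)
  expect_equal(igraph::ecount(g1), 0)
  expect_identical(connected_subgroups(g1)$count, 5L)
  # exact boundary: an edge with weight exactly T survives
  M2 <- matrix(c(NA, 0.8, 0.8, NA), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  diag(M2) <- 1
  class(M2) <- c("correlation_matrix", "matrix")
  expect_equal(igraph::ecount(threshold_graph(M2, 0.8)), 1)
  expect_equal(igraph::ecount(threshold_graph(M2, 0.8 + 1e-9)), 0)
})

test_that("connected subgroups equal a breadth-first oracle on random graphs", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(2:20, 1)
    p <- runif(1, 0.05, 0.5)
    adj <- matrix(FALSE, n, n)
    adj[upper.tri(adj)] <- runif(n * (n - 1) / 2) < p
    adj <- adj | t(adj)
    dimnames(adj) <- list(paste0("v", 1:n), paste0("v", 1:n))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    fast <- connected_subgroups(g)
    slow <- bfs_components(adj)
    expect_identical(fast$count, slow$count)
    # same partition up to label permutation
    expect_identical(unname(as.integer(table(fast$membership))[
      order(table(fast$membership))],
    ), unname(as.integer(table(slow$membership))[
      order(table(slow$membership))]))
  }
})

test_that("subgroup sweeps are monotone and match the block construction", {
  ft <- make_block_table(seed = 1)
  sw <- subgroup_sweep(ft, thresholds = c(0.75, 0.80, 0.85, 0.90, 0.95, 0.995))
  for (m in unique(sw$method)) {
    counts <- sw$n_subgroups[sw$method == m][order(sw$threshold[sw$method == m])]
    expect_true(all(diff(counts) >= 0))
  }
  # two copied sources: 2 subgroups at 0.75, all 5 singletons at 0.995
  expect_identical(sw$n_subgroups[sw$method == "pearson" & sw$threshold == 0.75], 2L)
  expect_identical(sw$n_subgroups[sw$method == "pearson" & sw$threshold == 0.995], 5L)
  expect_identical(sw$n_subgroups[sw$method == "spearman" & sw$threshold == 0.75], 2L)
  # within-block pairs are tight, between-block pairs are weak
  M <- attr(sw, "matrices")$pearson
  expect_gt(min(M["fA1", "fA2"], M["fA1", "fA3"], M["fB1", "fB2"]), 0.99)
  expect_lt(max(M[c("fA1", "fA2", "fA3"), c("fB1", "fB2")]), 0.3)

  # single feature: one subgroup at every threshold
  single <- feature_table(data.frame(nodule_id = rep(1:5, each = 9),
                                     algorithm_id = rep(rep(1:3, each = 3), 5),
                                     init_id = rep(1:3, 15),
                                     only = rnorm(45)))
  sw1 <- subgroup_sweep(single)
  expect_true(all(sw1$n_subgroups == 1L))
})

test_that("graph export round-trips nodes, edges and attributes", {
  ft <- make_block_table(seed = 3)
  M <- correlation_matrix(ft, "pearson")
  g <- threshold_graph(M, 0.75)
  dict <- feature_dictionary(data.frame(
    name = igraph::V(g)$name,
    feature_class = c("Size", "Size", "Size", "GSD", "GSD")))
  path <- tempfile(fileext = ".graphml")
  csv <- tempfile(fileext = ".csv")
  export_graph(g, dict, path, edges_csv = csv)
  back <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(back), igraph::vcount(g))
  expect_equal(igraph::ecount(back), igraph::ecount(g))
  expect_setequal(igraph::vertex_attr(back, "feature_class"),
                  dict$feature_class)
  # component_id constant within each subgroup
  memb <- connected_subgroups(g)$membership
  expect_identical(unname(igraph::vertex_attr(back, "component_id")[
    match(names(memb), igraph::vertex_attr(back, "name"))]),
    as.numeric(unname(memb)))
  edges <- read.csv(csv)
  expect_identical(nrow(edges), as.integer(igraph::ecount(g)))

  # drop_singletons leaves only components of size >= 2
  g2 <- export_graph(g, dict, tempfile(fileext = ".graphml"),
                     drop_singletons = TRUE)
  cs <- connected_subgroups(g2)
  expect_true(all(cs$sizes >= 2))
  expect_error(export_graph(g, dict[1:3, ], tempfile(fileext = ".graphml")),
               "without dictionary")
})
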