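test_that("density matches its definition", {
  expect_equal(network_density(igraph::make_full_graph(5)), 1)
  expect_equal(network_density(igraph::make_empty_graph(5, directed = FALSE)), 0)
  g <- igraph::graph_from_edgelist(rbind(c(1, 2), c(2, 3), c(3, 4)),
                                   directed = FALSE)
  expect_equal(network_density(g), 0.5)
  expect_error(network_density(igraph::make_empty_graph(1, directed = FALSE)),
               "undefined")
})

test_that("clustering coefficients match exhaustive triplet enumeration", {
  tri <- igraph::make_full_graph(3)
  cl <- clustering_coefficients(tri)
  expect_equal(cl$global, 1)
  expect_equal(unname(cl$local), rep(1, 3))

  path <- igraph::make_ring(3, circular = FALSE)
  cl <- clustering_coefficients(path)
  expect_equal(cl$global, 0)
  expect_equal(unname(cl$local), rep(0, 3))

  set.seed(31)
  for (i in 1:5) {
    adj <- random_small_adj(20, 0.25)
    cl <- clustering_coefficients(adj)
    oc <- oracle_clustering(adj)
    expect_equal(cl$global, oc$global, tolerance = 1e-12)
    expect_equal(unname(cl$local), oc$local, tolerance = 1e-12)
  }
})

test_that("the isolate convention shifts the mean as configured", {
  g <- igraph::graph_from_edgelist(rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 4)),
                                   directed = FALSE)
  incl <- clustering_coefficients(g, isolates = "zero")$mean_local
  excl <- clustering_coefficients(g, isolates = "exclude")$mean_local
  expect_lt(incl, excl)
})

test_that("betweenness equals exhaustive shortest-path enumeration", {
  path <- igraph::make_ring(3, circular = FALSE)
  expect_equal(unname(node_betweenness(path)), c(0, 1, 0))
  expect_equal(unname(node_betweenness(igraph::make_full_graph(5))), rep(0, 5))

  set.seed(32)
  for (i in 1:4) {
    adj <- random_small_adj(8, 0.35)
    expect_equal(unname(node_betweenness(adj)), oracle_betweenness(adj),
                 tolerance = 1e-12)
  }
})

test_that("walktrap modularity is internally consistent and near-optimal", {
  two_cliques <- igraph::disjoint_union(igraph::make_full_graph(5),
                                        igraph::make_full_graph(5))
  cm <- communities_and_modularity(two_cliques)
  expect_equal(cm$modularity, 0.5)
  expect_equal(length(unique(cm$membership$community)), 2)

  cm_full <- communities_and_modularity(igraph::make_full_graph(6))
  expect_equal(cm_full$modularity, 0, tolerance = 1e-12)

  cm_empty <- communities_and_modularity(
    igraph::make_empty_graph(4, directed = FALSE))
  expect_equal(cm_empty$modularity, 0)
  expect_equal(unique(cm_empty$membership$community), 1L)

  set.seed(33)
  for (i in 1:3) {
    adj <- random_small_adj(8, 0.3)
    if (sum(adj) == 0) next
    cm <- communities_and_modularity(adj)
    memb <- cm$membership$community
    # returned Q equals Q recomputed from its own partition ...
    expect_equal(cm$modularity, oracle_modularity(adj, memb),
                 tolerance = 1e-12)
    # ... and cannot beat the exhaustive maximum
    expect_lte(cm$modularity, oracle_max_modularity(adj) + 1e-12)
  }
})

test_that("assortativity matches known configurations and the permutation null", {
  cl1 <- igraph::make_full_graph(5)
  two <- igraph::disjoint_union(cl1, cl1)
  trait <- rep(c(0, 1), each = 5)
  expect_equal(trait_assortativity(two, trait), 1)

  bip <- igraph::make_full_bipartite_graph(3, 3)
  expect_equal(trait_assortativity(bip, rep(c(0, 1), each = 3)), -1)

  expect_error(trait_assortativity(two, rep(1, 10)), "variance")

  # affine invariance
  set.seed(34)
  adj <- random_small_adj(15, 0.3)
  x <- runif(15)
  expect_equal(trait_assortativity(adj, x), trait_assortativity(adj, 3 * x + 2),
               tolerance = 1e-12)

  # permutation-null mean is -1/(N-1)
  nulls <- shuffled_null(adj, trait = x, reps = 1000, seed = 35)$r
  se <- sd(nulls) / sqrt(length(nulls))
  expect_lt(abs(mean(nulls) - (-1 / 14)), 4 * se)
})

test_that("network_metrics summarises a simulated network in one row", {
  net <- simulate_with_traits(40, p_n = 0.8, p_r = 0.05, steps = 400, seed = 36)
  m <- network_metrics(net)
  expect_equal(nrow(m), 1)
  expect_equal(m$n, 40)
  expect_true(m$density >= 0 && m$density <= 1)
  expect_false(is.na(m$assortativity))
})
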