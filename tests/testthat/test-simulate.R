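test_that("random initial networks have the right edge law", {
  tri <- init_random_network(3, 1, seed = 1)
  expect_equal(igraph::ecount(tri$graph), 3)
  empty <- init_random_network(10, 0, seed = 1)
  expect_equal(igraph::ecount(empty$graph), 0)
  expect_error(init_random_network(2, 0.5), "n")

  set.seed(11)
  counts <- replicate(200, igraph::ecount(init_random_network(100, 0.1)$graph))
  expected <- choose(100, 2) * 0.1
  se <- sqrt(choose(100, 2) * 0.1 * 0.9) / sqrt(200)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("a single birth-death event follows the bonding rule", {
  tri <- init_random_network(3, 1, seed = 2)
  out <- birth_death_step(tri, p_n = 1, p_r = 0, p_b = 1)
  expect_equal(igraph::ecount(out$network$graph), 3) # complete again
  expect_equal(igraph::vcount(out$network$graph), 3)

  net <- init_random_network(20, 0.3, seed = 3)
  out <- birth_death_step(net, p_n = 0, p_r = 0, p_b = 1)
  expect_equal(out$record$degree_at_birth, 1L) # mother only
  expect_false(out$record$dead == out$record$newborn)
})

test_that("the process conserves size and graph invariants", {
  set.seed(4)
  net <- init_random_network(15, 0.2)
  for (i in 1:25) {
    net <- birth_death_step(net, p_n = 0.7, p_r = 0.05)$network
    adj <- igraph::as_adjacency_matrix(net$graph, sparse = FALSE)
    expect_equal(igraph::vcount(net$graph), 15)
    expect_true(all(adj == t(adj)))
    expect_true(all(diag(adj) == 0))
  }
  expect_equal(nrow(net$lineage), 25)
  # with p_b = 1 every newborn starts with at least the mother bond
  expect_true(all(net$lineage$degree_at_birth >= 1))
})

test_that("identical parameters and seed give identical edge sets", {
  a <- simulate_network(40, p_n = 0.7, p_r = 0.03, steps = 400, seed = 99)
  b <- simulate_network(40, p_n = 0.7, p_r = 0.03, steps = 400, seed = 99)
  expect_identical(igraph::as_edgelist(a$graph), igraph::as_edgelist(b$graph))
  expect_identical(a$lineage, b$lineage)
})

test_that("degenerate bonding probabilities reach the expected extremes", {
  full <- simulate_network(30, p_n = 1, p_r = 1, p_b = 1, steps = 300, seed = 5)
  expect_equal(network_density(full), 1)

  set.seed(6)
  md <- replicate(30, {
    net <- simulate_network(30, p_n = 0, p_r = 0, p_b = 1, steps = 300)
    mean(igraph::degree(net$graph))
  })
  se <- sd(md) / sqrt(length(md))
  expect_lt(abs(mean(md) - 1), 3 * se) # closed form gives mean degree p_b
})

test_that("short runs warn about not reaching stationarity", {
  expect_warning(simulate_network(50, p_n = 0.5, p_r = 0.1, steps = 100,
                                  seed = 1),
                 "rule of thumb")
})

test_that("stronger social inheritance increases clustering", {
  set.seed(7)
  cc <- function(pn) {
    replicate(15, {
      net <- simulate_network(60, p_n = pn, p_r = 0.1, steps = 600)
      clustering_coefficients(net)$mean_local
    })
  }
  hi <- cc(0.9); lo <- cc(0.3)
  expect_gt(mean(hi), mean(lo))
})

test_that("clustering is non-monotonic in the random-bonding rate", {
  set.seed(8)
  cc_at <- function(pr) {
    mean(replicate(12, {
      net <- simulate_network(100, p_n = 0.9, p_r = pr, steps = 1200)
      clustering_coefficients(net)$mean_local
    }))
  }
  very_low <- cc_at(0.005); mid <- cc_at(0.05); high <- cc_at(0.5)
  expect_lt(mid, very_low)
  expect_lt(mid, high)
})

test_that("two-sex variants run and fail loudly without eligible parents", {
  net <- simulate_two_sex(40, p_n = 0.8, p_r = 0.02, steps = 400, seed = 9)
  expect_true(all(igraph::V(net$graph)$sex %in% c("F", "M")))
  expect_equal(igraph::vcount(net$graph), 40)

  net2 <- simulate_two_sex(40, p_n = 0.8, p_r = 0.02, steps = 400, seed = 10,
                           variant = "two-parents-random")
  expect_false(anyNA(net2$lineage$father))

  expect_error(
    simulate_two_sex(20, p_n = 0.5, p_r = 0.05, steps = 50, seed = 11,
                     variant = "two-parents-pair", init_edge_prob = 0,
                     init_sex = rep("F", 20)),
    "step 1")
  expect_error(
    simulate_two_sex(20, p_n = 0.5, p_r = 0.05, steps = 50, seed = 12,
                     init_sex = rep("M", 20)),
    "female")
})

test_that("copy-mother two-sex networks stay close to the basic model", {
  # mothers drawn among females only yields similar (not identical)
  # networks: females are copied twice as often, which feeds back into a
  # slightly higher stationary degree
  set.seed(13)
  basic <- replicate(30, {
    net <- simulate_network(50, p_n = 0.8, p_r = 0.05, steps = 500)
    st <- clustering_coefficients(net)
    c(mean(igraph::degree(net$graph)), st$mean_local)
  })
  twosex <- replicate(30, {
    net <- simulate_two_sex(50, p_n = 0.8, p_r = 0.05, steps = 500,
                            init_sex = rep("F", 50))
    st <- clustering_coefficients(net)
    c(mean(igraph::degree(net$graph)), st$mean_local)
  })
  expect_lt(abs(mean(twosex[1, ]) - mean(basic[1, ])) / mean(basic[1, ]), 0.25)
  expect_lt(abs(mean(twosex[2, ]) - mean(basic[2, ])) / mean(basic[2, ]), 0.25)
})

test_that("two-parent inheritance leaves networks no more clustered than random", {
  # copying the union of two parents' circles behaves like random
  # connectivity: the clustering excess over the density of an equivalent
  # random graph collapses
  set.seed(14)
  excess <- function(variant) {
    replicate(12, {
      net <- simulate_two_sex(60, p_n = 0.8, p_r = 0.01, steps = 600,
                              variant = variant)
      clustering_coefficients(net)$global - network_density(net)
    })
  }
  one <- excess("copy-mother")
  two_r <- excess("two-parents-random")
  two_p <- excess("two-parents-pair")
  expect_gt(mean(one), mean(two_r))
  expect_gt(mean(one), mean(two_p))
  expect_lt(mean(two_r), 0.05)
})

test_that("varying-size trajectories hit their targets exactly", {
  tr <- simulate_varying_size(p_n = 0.7, p_r = 0.05, regime = "shrink",
                              burn_in = 100, seed = 15)
  expect_equal(tr$size[nrow(tr)], 100)
  expect_equal(igraph::vcount(tr$network[[nrow(tr)]]), 100)

  tr2 <- simulate_varying_size(p_n = 0.7, p_r = 0.05, regime = "grow",
                               burn_in = 100, seed = 16)
  expect_equal(tr2$size[nrow(tr2)], 200)

  # zero mortality: the population grows by exactly one per step
  tr3 <- simulate_varying_size(p_n = 0.7, p_r = 0.05, regime = "grow",
                               death_prob = 0, burn_in = 50, seed = 17)
  expect_equal(diff(tr3$size), rep(1L, nrow(tr3) - 1))
})
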