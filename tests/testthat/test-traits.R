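test_that("trait inheritance follows the mutation-deviation mixture", {
  expect_equal(inherit_trait(0.42, mu = 0, sigma = 0), 0.42)

  set.seed(411)
  pure_mut <- inherit_trait(rep(0.5, 1e5), mu = 1, sigma = 0.05)
  # (RNG-grid ties are measure-zero artefacts; harmless for KS)
  expect_gt(suppressWarnings(stats::ks.test(pure_mut, "punif"))$p.value, 0.01)

  # closed-form mixture CDF at mother trait 0.5 (reflection negligible)
  draws <- inherit_trait(rep(0.5, 1e5), mu = 0.05, sigma = 0.05)
  mix_cdf <- function(x) 0.95 * stats::pnorm(x, 0.5, 0.05) + 0.05 * x
  expect_gt(suppressWarnings(stats::ks.test(draws, mix_cdf))$p.value, 0.01)
  expect_true(all(draws >= 0 & draws <= 1))

  # reflection keeps boundary mass inside [0, 1]
  edge <- inherit_trait(rep(0.01, 1e4), mu = 0, sigma = 0.05)
  expect_true(all(edge >= 0 & edge <= 1))
})

test_that("traits ride on top of unchanged core dynamics", {
  net <- simulate_with_traits(40, p_n = 0.8, p_r = 0.02, steps = 400,
                              mu = 0, sigma = 0, seed = 42)
  tr <- igraph::V(net$graph)$trait
  expect_true(all(tr >= 0 & tr <= 1))
  # mu = 0, sigma = 0: every lineage keeps its founder's trait; all final
  # traits must be among the initial values
  expect_true(all(!is.na(tr)))

  # identical seeds give identical networks and traits
  net2 <- simulate_with_traits(40, p_n = 0.8, p_r = 0.02, steps = 400,
                               mu = 0, sigma = 0, seed = 42)
  expect_identical(igraph::V(net$graph)$trait, igraph::V(net2$graph)$trait)
})

test_that("shuffled nulls expose genuinely assortative structure", {
  two <- igraph::disjoint_union(igraph::make_full_graph(5),
                                igraph::make_full_graph(5))
  trait <- rep(c(0, 1), each = 5)
  observed <- trait_assortativity(two, trait)
  nulls <- shuffled_null(two, trait = trait, reps = 200, seed = 43)
  expect_equal(observed, 1)
  # only a permutation reproducing the exact clique split (probability
  # 2 / choose(10, 5)) can reach the observed coefficient
  expect_lt(mean(nulls$r >= observed), 0.05)
  expect_lt(abs(mean(nulls$r) - (-1 / 9)), 0.15)
})

test_that("null spread shrinks as the square root of the permutation count", {
  set.seed(44)
  adj <- random_small_adj(30, 0.2)
  x <- runif(30)
  spread <- vapply(c(100, 400, 1600), function(reps) {
    sd(shuffled_null(adj, trait = x, reps = reps)$r) / sqrt(reps)
  }, numeric(1))
  expect_gt(spread[1] / spread[2], 1.4) # ~2 expected
  expect_gt(spread[2] / spread[3], 1.4)
})

test_that("social inheritance produces assortativity without preference", {
  ex <- assortativity_experiment(reps = 12, n = 60, steps = 600,
                                 p_n = 0.9, p_r = 0.01, seed = 45)
  expect_equal(nrow(ex), 12)
  expect_gt(mean(ex$r), mean(ex$r_null))
  expect_gt(mean(ex$r), 0.1)
})

test_that("offspring centrality regresses on mother centrality when p_n is high", {
  ex <- heritability_experiment(p_n_values = c(0.1, 0.9), p_r = 0.01,
                                reps = 8, n = 100, steps = 1000, seed = 46)
  hi <- ex$slope[ex$p_n == 0.9]
  lo <- ex$slope[ex$p_n == 0.1]
  expect_gt(mean(hi), mean(lo))
  expect_true(all(ex$n_pairs >= 3))

  # no parental signal when the mother bond is absent and inheritance is
  # indistinguishable from chance
  ex0 <- heritability_experiment(p_n_values = 0.05, p_r = 0.05, p_b = 0,
                                 reps = 15, n = 60, steps = 600, seed = 47)
  se <- sd(ex0$slope) / sqrt(nrow(ex0))
  expect_lt(abs(mean(ex0$slope)), 3 * se)

  # alternative centrality measures run through the same machinery
  for (metric in c("local_clustering", "eigenvector")) {
    exm <- heritability_experiment(p_n_values = 0.8, p_r = 0.01, reps = 2,
                                   n = 50, steps = 500, metric = metric,
                                   seed = 48)
    expect_true(all(is.finite(exm$slope)))
  }
})

test_that("alternative bonding models obey their kernels", {
  # zero kernel: newborns bond only their mother
  net <- explicit_assortativity_simulate(30, steps = 120, kernel_scale = 0,
                                         seed = 49, init_edge_prob = 0)
  expect_true(all(net$lineage$degree_at_birth == 1))

  # vanishing preference scale: newborns accumulate almost no bonds
  gp <- generalized_preference_simulate(30, steps = 120, k = 1e-4,
                                        seed = 50, init_edge_prob = 0)
  expect_lt(mean(gp$lineage$degree_at_birth), 0.1)
  expect_error(generalized_preference_simulate(30, steps = 10, k = 1.5),
               "k")

  # homogeneous limit: identical traits make bonding uniform at rate k
  gp2 <- generalized_preference_simulate(40, steps = 400, k = 0.2, sigma = 0,
                                         seed = 51, init_edge_prob = 0.2,
                                         init_traits = cbind(rep(0.5, 40),
                                                             rep(0.5, 40)))
  expect_lt(abs(mean(gp2$lineage$degree_at_birth) - 0.2 * 39), 1)
})

test_that("kernel calibration reaches a target density", {
  cal <- calibrate_kernel(target_density = 0.15, n = 40, steps = 400,
                          reps = 3, tol = 0.02, seed = 52)
  expect_lt(abs(cal$achieved - 0.15), 0.02)
  net <- explicit_assortativity_simulate(40, steps = 400,
                                         kernel_scale = cal$scale, seed = 53)
  expect_lt(abs(network_density(net) - 0.15), 0.06)
})
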