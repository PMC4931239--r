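test_that("the closed-form mean degree solves the stationarity balance", {
  grid <- expand.grid(p_n = seq(0.05, 0.95, length.out = 10),
                      p_r = seq(0, 0.45, length.out = 10))
  for (i in seq_len(nrow(grid))) {
    closed <- expected_mean_degree(100, grid$p_n[i], grid$p_r[i])
    iterated <- oracle_mean_degree(100, grid$p_n[i], grid$p_r[i], p_b = 1)
    expect_equal(closed, iterated, tolerance = 1e-12)
  }
  # degenerate collapses
  expect_equal(expected_mean_degree(50, 0.2, 0.2, p_b = 0.7), 0.7 + 0.2 * 48)
  expect_equal(expected_mean_degree(100, 0, 0, p_b = 1), 1)
  # the balance denominator stays positive for all valid probabilities,
  # approaching 0 as p_n - p_r -> 1 with growing n
  expect_gt(expected_mean_degree(1000, 1, 0), 998)
})

test_that("the mean degree rises with each bonding probability", {
  base <- expected_mean_degree(100, 0.6, 0.05, p_b = 0.8)
  expect_gt(expected_mean_degree(100, 0.7, 0.05, p_b = 0.8), base)
  expect_gt(expected_mean_degree(100, 0.6, 0.06, p_b = 0.8), base)
  expect_gt(expected_mean_degree(100, 0.6, 0.05, p_b = 0.9), base)
})

test_that("the newborn clustering moment approximation matches Monte Carlo", {
  set.seed(21)
  cases <- list(list(d_p = 10, p_n = 0.8, p_r = 0.02),
                list(d_p = 20, p_n = 0.5, p_r = 0.1),
                list(d_p = 5, p_n = 0.3, p_r = 0.05))
  for (cs in cases) {
    cp <- 0.3; rho <- 0.1; eta <- 0.08
    approx <- socinherit:::newborn_clustering_moments(
      100, 1, cs$p_n, cs$p_r, cs$d_p, cp, rho, eta)
    mc <- oracle_newborn_cc(100, 1, cs$p_n, cs$p_r, cs$d_p, cp, rho, eta)
    expect_lt(abs(approx - mc), 0.02)
  }
})

test_that("the clustering approximation behaves at its known limits", {
  # tree-like limit: no triads can close
  expect_equal(expected_mean_clustering(100, 0, 0, p_b = 1), 0)
  # interior solutions stay in [0, 1] and are deterministic
  a <- expected_mean_clustering(100, 0.9, 0.1)
  b <- expected_mean_clustering(100, 0.9, 0.1)
  expect_identical(a, b)
  expect_true(a > 0 && a < 1)
  # stronger inheritance at fixed p_r clusters more
  expect_gt(expected_mean_clustering(100, 0.9, 0.1),
            expected_mean_clustering(100, 0.3, 0.1))
})

test_that("simulated ensembles match the stationarity approximations", {
  set.seed(22)
  for (pars in list(c(0.6, 0.1), c(0.9, 0.3))) {
    dbar <- expected_mean_degree(100, pars[1], pars[2])
    cbar <- expected_mean_clustering(100, pars[1], pars[2])
    stats <- replicate(20, {
      net <- simulate_network(100, p_n = pars[1], p_r = pars[2], steps = 1000)
      c(mean(igraph::degree(net$graph)),
        clustering_coefficients(net)$mean_local)
    })
    expect_lt(abs(mean(stats[1, ]) - dbar), 3 * sd(stats[1, ]) / sqrt(20))
    expect_lt(abs(mean(stats[2, ]) - cbar), 3 * sd(stats[2, ]) / sqrt(20))
  }
})

test_that("the mean-field degree distribution is a proper distribution", {
  mf <- stationary_degree_distribution(60, p_n = 0.8, p_r = 0.01)
  expect_equal(sum(mf$distribution$phi), 1, tolerance = 1e-9)
  expect_true(all(mf$distribution$phi >= 0))
  expect_equal(sum(mf$distribution$birth), 1, tolerance = 1e-9)
  expect_equal(sum(mf$distribution$post_death), 1, tolerance = 1e-9)

  # complete-network absorbing state
  mf1 <- stationary_degree_distribution(40, p_n = 1, p_r = 1)
  expect_gt(mf1$distribution$phi[40], 0.99)
})

test_that("the mean-field mean degree agrees with the closed form", {
  grid <- expand.grid(p_n = c(0.3, 0.6, 0.9), p_r = c(0.01, 0.1, 0.3))
  for (i in seq_len(nrow(grid))) {
    mf <- stationary_degree_distribution(100, grid$p_n[i], grid$p_r[i])
    mean_mf <- sum(mf$distribution$d * mf$distribution$phi)
    dbar <- expected_mean_degree(100, grid$p_n[i], grid$p_r[i])
    expect_lt(abs(mean_mf - dbar) / dbar, 0.02)
  }
})

test_that("the approximations bundle reports a small residual", {
  ap <- stationary_approx(100, p_n = 0.8, p_r = 0.05)
  expect_lt(abs(ap$residual), 1e-8)
  g <- glance(ap)
  expect_equal(g$mean_degree, ap$mean_degree)
  expect_equal(ap$post_death_degree, ap$mean_degree * 98 / 99)
})
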