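#' Trait inheritance with rare large mutations
#'
#' A newborn draws its trait anew from Uniform(0, 1) with probability
#' `mu` (a large mutation); otherwise it takes a Gaussian deviation of
#' s.d. `sigma` around the mother's value. Draws leaving \[0, 1\] are
#' reflected back into the interval by default, which preserves density
#' mass near the boundaries; `boundary = "clip"` truncates instead.
#'
#' @param mother_trait mother's trait value(s) in \[0, 1\]; vectorised.
#' @param mu large-mutation probability.
#' @param sigma s.d. of the Gaussian deviation (trait units).
#' @param boundary how to map Gaussian draws back into \[0, 1\].
#' @return Trait values in \[0, 1\], same length as `mother_trait`.
#' @examples
#' set.seed(1)
#' inherit_trait(rep(0.5, 5), mu = 0.05, sigma = 0.05)
#' @export
inherit_trait <- function(mother_trait, mu = 0.05, sigma = 0.05,
                          boundary = c("reflect", "clip")) {
  boundary <- match.arg(boundary)
  check_prob(mu, "mu")
  if (sigma < 0) abort("`sigma` must be non-negative")
  if (any(mother_trait < 0 | mother_trait > 1)) {
    abort("`mother_trait` must lie in [0, 1]")
  }
  k <- length(mother_trait)
  out <- mother_trait + rnorm(k, 0, sigma)
  out <- if (boundary == "reflect") reflect_unit(out) else pmin(pmax(out, 0), 1)
  mut <- runif(k) < mu
  out[mut] <- runif(sum(mut))
  out
}

reflect_unit <- function(x) {
  x <- x %% 2
  ifelse(x > 1, 2 - x, x)
}

#' Simulate the social-inheritance model with heritable traits
#'
#' Runs [simulate_network()] unchanged and assigns every individual a
#' trait: the initial population draws Uniform(0, 1) values and every
#' newborn inherits from its mother via [inherit_trait()]. Traits do not
#' influence bonding, so any assortativity in the result emerges from
#' social inheritance alone.
#'
#' @inheritParams simulate_network
#' @inheritParams inherit_trait
#' @return A [si_network][new_si_network] whose vertices carry a `trait`
#'   attribute.
#' @examples
#' net <- simulate_with_traits(50, p_n = 0.8, p_r = 0.02, steps = 500, seed = 1)
#' trait_assortativity(net)
#' @export
simulate_with_traits <- function(n = 100, p_n, p_r, p_b = 1, steps = 10 * n,
                                 mu = 0.05, sigma = 0.05,
                                 boundary = c("reflect", "clip"),
                                 seed = NULL, init_edge_prob = NULL) {
  boundary <- match.arg(boundary)
  if (!is.null(seed)) set.seed(seed)
  net <- simulate_network(n = n, p_n = p_n, p_r = p_r, p_b = p_b,
                          steps = steps, init_edge_prob = init_edge_prob)
  # replay the lineage: traits are assigned at birth and never change
  traits <- c(runif(n), rep(NA_real_, nrow(net$lineage)))
  if (nrow(net$lineage)) {
    for (i in seq_len(nrow(net$lineage))) {
      nb <- net$lineage$newborn[i]
      mo <- net$lineage$mother[i]
      traits[nb] <- inherit_trait(traits[mo], mu = mu, sigma = sigma,
                                  boundary = boundary)
    }
  }
  ids <- as.integer(igraph::V(net$graph)$name)
  net$graph <- igraph::set_vertex_attr(net$graph, "trait", value = traits[ids])
  net$params$mu <- mu
  net$params$sigma <- sigma
  net
}

#' Null distribution of assortativity under trait shuffling
#'
#' Re-assigns the observed trait values uniformly at random across nodes
#' and recomputes the assortativity coefficient, `reps` times. The null
#' expectation of the coefficient is `-1 / (N - 1)`.
#'
#' @inheritParams trait_assortativity
#' @param reps number of random permutations.
#' @param seed optional integer seed.
#' @return A tibble with columns `rep` and `r`.
#' @export
shuffled_null <- function(net, trait = NULL, reps = 100, seed = NULL) {
  reps <- check_count(reps, "reps", min = 1L)
  if (!is.null(seed)) set.seed(seed)
  g <- as_social_graph(net)
  if (is.null(trait)) trait <- igraph::vertex_attr(g, "trait")
  if (is.null(trait)) abort("no trait values supplied and no `trait` vertex attribute")
  r <- vapply(seq_len(reps), function(i) {
    trait_assortativity(g, sample(trait))
  }, numeric(1))
  tibble::tibble(rep = seq_len(reps), r = r)
}

#' Assortativity-emergence experiment
#'
#' Simulates replicate trait-bearing networks with
#' [simulate_with_traits()] and contrasts the observed assortativity of
#' each final network with the coefficient after randomly re-assigning
#' its trait values (`null_shuffles` permutations per replicate,
#' averaged).
#'
#' @inheritParams simulate_with_traits
#' @param reps number of replicate simulations.
#' @param null_shuffles trait permutations per replicate.
#' @return A tibble of class `si_assort_experiment` with one row per
#'   replicate: `rep`, `r` (observed) and `r_null`.
#' @examples
#' ex <- assortativity_experiment(reps = 3, n = 50, steps = 500, seed = 1)
#' dplyr::summarise(ex, mean(r), mean(r_null))
#' @export
assortativity_experiment <- function(reps = 100, n = 100, steps = 2000,
                                     p_n = 0.9, p_r = 0.01, p_b = 1,
                                     mu = 0.05, sigma = 0.05,
                                     null_shuffles = 1, seed = NULL) {
  reps <- check_count(reps, "reps", min = 1L)
  if (!is.null(seed)) set.seed(seed)
  rows <- purrr::map(seq_len(reps), function(i) {
    net <- simulate_with_traits(n = n, p_n = p_n, p_r = p_r, p_b = p_b,
                                steps = steps, mu = mu, sigma = sigma)
    r <- trait_assortativity(net)
    rn <- mean(shuffled_null(net, reps = null_shuffles)$r)
    tibble::tibble(rep = i, r = r, r_null = rn)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "params") <- list(n = n, steps = steps, p_b = p_b, p_n = p_n,
                              p_r = p_r, mu = mu, sigma = sigma)
  class(out) <- c("si_assort_experiment", class(out))
  out
}

# per-node centrality used by the heritability experiment
heritability_metric <- function(g, metric) {
  switch(metric,
    betweenness = node_betweenness(g),
    local_clustering = clustering_coefficients(g)$local,
    eigenvector = setNames(igraph::eigen_centrality(g)$vector, igraph::V(g)$name)
  )
}

#' Apparent heritability of network position
#'
#' For each value of the social-inheritance probability `p_n`, simulates
#' replicate networks, pairs every living individual with its living
#' mother via the lineage log, and regresses offspring centrality on
#' mother centrality (ordinary least squares; the Pearson correlation is
#' reported alongside). Strong social inheritance produces positive
#' slopes -- a pattern of heritability -- although no trait is
#' genetically transmitted.
#'
#' @inheritParams simulate_network
#' @param p_n_values social-inheritance probabilities to scan.
#' @param reps replicate simulations per `p_n` value.
#' @param metric centrality measure regressed between mothers and
#'   offspring.
#' @return A tibble of class `si_herit_experiment` with one row per
#'   replicate: `p_n`, `rep`, `slope`, `correlation` and `n_pairs`.
#'   Replicates with fewer than 3 mother--offspring pairs are dropped
#'   with a warning.
#' @examples
#' ex <- heritability_experiment(p_n_values = c(0.1, 0.9), reps = 2,
#'                               n = 50, steps = 500, seed = 1)
#' @export
heritability_experiment <- function(p_n_values = seq(0.1, 0.9, by = 0.2),
                                    p_r = 0.01, reps = 10, n = 100,
                                    steps = 2000, p_b = 1,
                                    metric = c("betweenness", "local_clustering",
                                               "eigenvector"),
                                    seed = NULL) {
  metric <- match.arg(metric)
  reps <- check_count(reps, "reps", min = 2L)
  if (!is.null(seed)) set.seed(seed)
  dropped <- 0L
  rows <- purrr::map(p_n_values, function(pn) {
    purrr::map(seq_len(reps), function(i) {
      net <- simulate_network(n = n, p_n = pn, p_r = p_r, p_b = p_b,
                              steps = steps)
      pairs <- mother_offspring_pairs(net, metric)
      if (nrow(pairs) < 3) {
        dropped <<- dropped + 1L
        return(NULL)
      }
      fit <- lm(offspring ~ mother, data = pairs)
      tibble::tibble(p_n = pn, rep = i,
                     slope = unname(coef(fit)[2]),
                     correlation = cor(pairs$mother, pairs$offspring),
                     n_pairs = nrow(pairs))
    })
  })
  if (dropped > 0) {
    warn(sprintf("%d replicate(s) dropped: fewer than 3 living mother-offspring pairs",
                 dropped))
  }
  out <- dplyr::bind_rows(purrr::flatten(rows))
  attr(out, "params") <- list(n = n, steps = steps, p_b = p_b, p_r = p_r,
                              reps = reps, metric = metric)
  class(out) <- c("si_herit_experiment", class(out))
  out
}

# pair living individuals with their living mothers and return both
# centralities
mother_offspring_pairs <- function(net, metric = "betweenness") {
  g <- as_social_graph(net)
  vals <- heritability_metric(g, metric)
  ids <- igraph::V(g)$name
  mothers <- as.character(igraph::vertex_attr(g, "mother"))
  alive <- !is.na(mothers) & mothers %in% ids
  tibble::tibble(
    offspring_id = ids[alive],
    mother_id = mothers[alive],
    offspring = unname(vals[ids[alive]]),
    mother = unname(vals[mothers[alive]])
  )
}
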