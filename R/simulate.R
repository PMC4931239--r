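#' Initialise a random social network
#'
#' Draws an Erdos--Renyi graph in which each unordered pair is an edge
#' independently with probability `edge_prob`. Used as the starting state
#' of the birth--death simulations.
#'
#' @param n number of individuals (at least 3).
#' @param edge_prob probability of each pairwise bond.
#' @param seed optional integer seed.
#' @return A [si_network][new_si_network] with fresh node identifiers
#'   `1..n` and no lineage.
#' @examples
#' net <- init_random_network(20, 0.1, seed = 1)
#' @export
init_random_network <- function(n, edge_prob, seed = NULL) {
  n <- check_count(n, "n", min = 3L)
  check_prob(edge_prob, "edge_prob")
  if (!is.null(seed)) set.seed(seed)
  adj <- random_adjacency(n, edge_prob)
  g <- igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected")
  igraph::V(g)$name <- as.character(seq_len(n))
  igraph::V(g)$birth_step <- NA_integer_
  igraph::V(g)$mother <- NA_integer_
  new_si_network(g, params = list(n = n, edge_prob = edge_prob))
}

random_adjacency <- function(n, edge_prob) {
  adj <- matrix(0L, n, n)
  up <- upper.tri(adj)
  adj[up] <- rbinom(sum(up), 1L, edge_prob)
  adj + t(adj)
}

default_init_prob <- function(n, p_n, p_r, p_b) {
  # start at the analytic stationary density when it exists, for faster
  # convergence; otherwise a sparse graph
  d <- tryCatch(expected_mean_degree(n, p_n, p_r, p_b), error = function(e) NULL)
  if (is.null(d)) return(0.05)
  min(max(d / (n - 1), 0), 1)
}

# slot bookkeeping shared by the engine wrappers
engine_state <- function(net) {
  g <- as_social_graph(net)
  adj <- si_adjacency(net) * 1L
  storage.mode(adj) <- "integer"
  ids <- suppressWarnings(as.integer(igraph::V(g)$name))
  if (anyNA(ids)) ids <- seq_len(igraph::vcount(g))
  sex_chr <- igraph::vertex_attr(g, "sex")
  sex <- if (is.null(sex_chr)) rep(0L, length(ids)) else {
    match(sex_chr, c("F", "M"), nomatch = 0L)
  }
  bs <- igraph::vertex_attr(g, "birth_step")
  if (is.null(bs)) bs <- rep(NA_integer_, length(ids))
  mo <- igraph::vertex_attr(g, "mother")
  if (is.null(mo)) mo <- rep(NA_integer_, length(ids))
  list(adj = adj, ids = ids, sex = as.integer(sex),
       birth_step = as.integer(bs), mother = as.integer(mo),
       next_id = max(ids) + 1L)
}

#' Simulate the social-inheritance birth--death process
#'
#' Runs the core model: at each step one individual, chosen uniformly at
#' random, dies with all its bonds; a mother is then chosen uniformly
#' among the `n - 1` survivors and a newborn enters, bonding its mother
#' with probability `p_b`, each of the mother's contacts independently
#' with probability `p_n`, and every other survivor independently with
#' probability `p_r`. Group size is constant.
#'
#' @inheritParams model_params
#' @param init_edge_prob edge probability of the random starting graph.
#'   The default matches the analytic stationary density, which shortens
#'   the burn-in.
#' @return A [si_network][new_si_network]; its `lineage` records every
#'   birth--death event (step, newborn, mother, dead individual and the
#'   newborn's degree at birth).
#' @examples
#' net <- simulate_network(50, p_n = 0.8, p_r = 0.05, steps = 500, seed = 1)
#' network_metrics(net)
#' @seealso [expected_mean_degree()], [expected_mean_clustering()] for the
#'   stationary expectations this process converges to.
#' @export
simulate_network <- function(n = 100, p_n, p_r, p_b = 1, steps = 10 * n,
                             seed = NULL, init_edge_prob = NULL) {
  n <- check_count(n, "n", min = 3L)
  check_prob(p_b, "p_b"); check_prob(p_n, "p_n"); check_prob(p_r, "p_r")
  steps <- check_count(steps, "steps", min = 0L)
  if (steps < 10 * n) {
    warn(sprintf("steps = %d is below the 10 * n = %d rule of thumb for stationarity",
                 steps, 10L * n))
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init_edge_prob)) init_edge_prob <- default_init_prob(n, p_n, p_r, p_b)
  adj <- random_adjacency(n, init_edge_prob)
  out <- cpp_sim_core(adj, steps, p_b, p_n, p_r,
                      rep(0L, n), seq_len(n), rep(NA_integer_, n),
                      rep(NA_integer_, n), n + 1L, 0L, 0L)
  si_from_engine(out, list(n = n, p_b = p_b, p_n = p_n, p_r = p_r,
                           steps = steps, seed = seed,
                           init_edge_prob = init_edge_prob))
}

#' Advance a network by one birth--death event
#'
#' Applies a single step of the process in [simulate_network()] to an
#' existing network: a uniformly chosen individual dies, then a newborn
#' replaces it following the `p_b`/`p_n`/`p_r` bonding rule with a mother
#' drawn uniformly among the survivors.
#'
#' @param net a [si_network][new_si_network], igraph object or adjacency
#'   matrix with at least 3 individuals.
#' @inheritParams model_params
#' @return A list with the updated `network` and the one-row `record`
#'   tibble describing the event.
#' @export
birth_death_step <- function(net, p_n, p_r, p_b = 1) {
  check_prob(p_b, "p_b"); check_prob(p_n, "p_n"); check_prob(p_r, "p_r")
  st <- engine_state(net)
  n <- nrow(st$adj)
  if (n < 3) abort("the network must contain at least 3 individuals")
  prev_steps <- if (inherits(net, "si_network")) nrow(net$lineage) else 0L
  out <- cpp_sim_core(st$adj, 1L, p_b, p_n, p_r, st$sex, st$ids,
                      st$birth_step, st$mother, st$next_id, prev_steps, 0L)
  params <- if (inherits(net, "si_network")) net$params else list(n = n)
  res <- si_from_engine(out, params)
  if (inherits(net, "si_network")) {
    res$lineage <- dplyr::bind_rows(net$lineage, res$lineage)
  }
  list(network = res, record = utils::tail(res$lineage, 1))
}

#' Simulate the two-sex variants of the model
#'
#' Newborns are assigned a sex uniformly at random and only females
#' reproduce. In the `"copy-mother"` variant the newborn applies the
#' usual `p_n`/`p_r` rule to its mother's contacts, so the only change
#' from [simulate_network()] is that mothers are drawn among living
#' females. The two-parent variants give the newborn both a mother and a
#' father and apply `p_n` to the union of both parents' contacts:
#' `"two-parents-random"` draws the parents independently at random,
#' `"two-parents-pair"` draws a connected female--male pair (and fails if
#' none exists).
#'
#' @inheritParams simulate_network
#' @param variant which two-sex variant to run.
#' @param init_sex optional character vector (`"F"`/`"M"`, length `n`) of
#'   initial sexes; drawn uniformly at random when absent.
#' @return A [si_network][new_si_network] whose vertices carry a `sex`
#'   attribute; the lineage gains a `father` column for the two-parent
#'   variants.
#' @export
simulate_two_sex <- function(n = 100, p_n, p_r, p_b = 1, steps = 10 * n,
                             variant = c("copy-mother", "two-parents-random",
                                         "two-parents-pair"),
                             seed = NULL, init_edge_prob = NULL,
                             init_sex = NULL) {
  variant <- match.arg(variant)
  n <- check_count(n, "n", min = 3L)
  check_prob(p_b, "p_b"); check_prob(p_n, "p_n"); check_prob(p_r, "p_r")
  steps <- check_count(steps, "steps", min = 0L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init_edge_prob)) init_edge_prob <- default_init_prob(n, p_n, p_r, p_b)
  adj <- random_adjacency(n, init_edge_prob)
  sex <- if (is.null(init_sex)) 1L + rbinom(n, 1L, 0.5) else {
    if (length(init_sex) != n || !all(init_sex %in% c("F", "M"))) {
      abort("`init_sex` must be a length-n vector of \"F\"/\"M\"")
    }
    match(init_sex, c("F", "M"))
  }
  mode <- match(variant, c("copy-mother", "two-parents-random", "two-parents-pair"))
  out <- cpp_sim_core(adj, steps, p_b, p_n, p_r, sex, seq_len(n),
                      rep(NA_integer_, n), rep(NA_integer_, n), n + 1L, 0L, mode)
  si_from_engine(out, list(n = n, p_b = p_b, p_n = p_n, p_r = p_r,
                           steps = steps, seed = seed, variant = variant))
}

#' Simulate a shrinking or growing population
#'
#' Starts from constant-size dynamics (one birth and one death per step)
#' for `burn_in` steps, then switches to a regime in which every
#' individual dies independently each step with the regime's mortality
#' (0.05 when shrinking, 0.001 when growing) while exactly one newborn
#' enters per step under the usual bonding rule. The shrinking run starts
#' at 200 individuals and stops at 100; the growing run starts at 100 and
#' stops at 200. Deaths in the final step are capped so the trajectory
#' ends exactly on the target size.
#'
#' @inheritParams simulate_network
#' @param regime `"shrink"` or `"grow"`.
#' @param death_prob per-individual, per-step death probability in the
#'   varying phase; defaults to the regime's value.
#' @param burn_in constant-size steps before the regime starts.
#' @param snapshot_every keep one network snapshot every this many steps
#'   of the varying phase (the final state is always kept).
#' @param max_steps safety cap on varying-phase steps.
#' @return A tibble of class `si_trajectory` with columns `step`, `size`
#'   and a `network` list-column of igraph snapshots.
#' @export
simulate_varying_size <- function(p_n, p_r, p_b = 1,
                                  regime = c("shrink", "grow"),
                                  death_prob = NULL, burn_in = 1000,
                                  snapshot_every = 1, seed = NULL,
                                  max_steps = 100000) {
  regime <- match.arg(regime)
  check_prob(p_b, "p_b"); check_prob(p_n, "p_n"); check_prob(p_r, "p_r")
  if (!is.null(seed)) set.seed(seed)
  n0 <- if (regime == "shrink") 200L else 100L
  target <- if (regime == "shrink") 100L else 200L
  if (is.null(death_prob)) death_prob <- if (regime == "shrink") 0.05 else 0.001
  check_prob(death_prob, "death_prob")

  adj <- random_adjacency(n0, default_init_prob(n0, p_n, p_r, p_b))
  out <- cpp_sim_core(adj, as.integer(burn_in), p_b, p_n, p_r, rep(0L, n0),
                      seq_len(n0), rep(NA_integer_, n0), rep(NA_integer_, n0),
                      n0 + 1L, 0L, 0L)
  adj <- out$adj
  next_id <- out$next_id
  ids <- out$ids

  snaps <- list()
  sizes <- integer()
  steps <- integer()
  step <- as.integer(burn_in)
  record <- function(step) {
    g <- igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected")
    igraph::V(g)$name <- as.character(ids)
    snaps[[length(snaps) + 1]] <<- g
    sizes[length(sizes) + 1] <<- nrow(adj)
    steps[length(steps) + 1] <<- step
  }
  record(step)

  repeat {
    n <- nrow(adj)
    if (n == target) break
    if (step - burn_in >= max_steps) {
      abort("population did not reach the target size within `max_steps`")
    }
    step <- step + 1L
    # independent deaths, capped so the size never passes the target
    dies <- which(runif(n) < death_prob)
    if (regime == "shrink") {
      max_deaths <- (n + 1L) - target
      if (length(dies) > max_deaths) {
        dies <- dies[sample.int(length(dies), max_deaths)]
      }
    }
    if (n - length(dies) < 2) {
      abort(sprintf("population collapsed to fewer than 2 individuals at step %d", step))
    }
    if (length(dies)) {
      adj <- adj[-dies, -dies, drop = FALSE]
      ids <- ids[-dies]
      n <- nrow(adj)
    }
    # one birth
    mother <- sample.int(n, 1)
    p <- ifelse(adj[mother, ] != 0, p_n, p_r)
    p[mother] <- p_b
    links <- as.integer(runif(n) < p)
    adj <- rbind(cbind(adj, links, deparse.level = 0), c(links, 0L))
    dimnames(adj) <- NULL
    ids <- c(ids, next_id)
    next_id <- next_id + 1L
    n <- nrow(adj)
    if (n == target || (step - burn_in) %% snapshot_every == 0) record(step)
  }

  out <- tibble::tibble(step = steps, size = sizes, network = snaps)
  class(out) <- c("si_trajectory", class(out))
  out
}
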