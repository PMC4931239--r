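#' Network density
#'
#' Fraction of realised bonds, `2T / (N (N - 1))` for `T` edges among
#' `N` individuals.
#'
#' @param net a [si_network][new_si_network], igraph object or adjacency
#'   matrix.
#' @return A single number in \[0, 1\].
#' @export
network_density <- function(net) {
  g <- as_social_graph(net)
  n <- igraph::vcount(g)
  if (n < 2) abort("density is undefined for networks with fewer than 2 nodes")
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' Global and local clustering coefficients
#'
#' The global coefficient is the ratio of closed to connected triplets
#' (3 triangles / triplets); the local coefficient of a node is the
#' fraction of its neighbour pairs that are themselves bonded. Nodes of
#' degree below 2 have no neighbour pair; by default their coefficient
#' is set to 0 and included in the mean (set `isolates = "exclude"` to
#' drop them instead -- the choice measurably shifts the mean in sparse
#' networks).
#'
#' @inheritParams network_density
#' @param isolates how to treat nodes of degree < 2 in the mean local
#'   coefficient.
#' @return A list with `global`, the named per-node `local` vector, and
#'   `mean_local`.
#' @examples
#' clustering_coefficients(igraph::make_full_graph(4))
#' @export
clustering_coefficients <- function(net, isolates = c("zero", "exclude")) {
  isolates <- match.arg(isolates)
  g <- as_social_graph(net)
  glob <- igraph::transitivity(g, type = "global")
  if (is.nan(glob)) glob <- 0
  loc <- igraph::transitivity(g, type = "local", isolates = "NaN")
  names(loc) <- igraph::V(g)$name
  low <- is.nan(loc)
  loc[low] <- 0
  mean_local <- if (isolates == "zero") mean(loc) else {
    if (all(low)) 0 else mean(loc[!low])
  }
  list(global = glob, local = loc, mean_local = mean_local)
}

#' Betweenness centrality
#'
#' Unnormalised shortest-path betweenness of every node: the sum over
#' unordered pairs `(s, t)` (excluding the focal node) of the fraction
#' of shortest `s`--`t` paths passing through it; disconnected pairs
#' contribute 0.
#'
#' @inheritParams network_density
#' @return A named numeric vector.
#' @export
node_betweenness <- function(net) {
  g <- as_social_graph(net)
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  names(b) <- igraph::V(g)$name
  b
}

#' Walktrap communities and modularity
#'
#' Detects communities by agglomerative merging driven by short random
#' walks (walktrap) and cuts the dendrogram at the partition maximising
#' Newman's modularity `Q = sum_i (e_ii - a_i^2)`, where `e_ii` is the
#' fraction of edges inside module `i` and `a_i` the fraction incident
#' to it. An edgeless network yields a single community with `Q = 0`.
#'
#' @inheritParams network_density
#' @param walk_length random-walk length driving the merge distances.
#' @return A list with `membership` (a tibble `node`, `community`) and
#'   the maximal `modularity`.
#' @export
communities_and_modularity <- function(net, walk_length = 4) {
  g <- as_social_graph(net)
  if (igraph::vcount(g) == 0) abort("the network is empty")
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(g)))
  if (igraph::ecount(g) == 0) {
    return(list(membership = tibble::tibble(node = nodes, community = 1L),
                modularity = 0))
  }
  wt <- igraph::cluster_walktrap(g, steps = walk_length)
  memb <- igraph::membership(wt)
  list(membership = tibble::tibble(node = nodes, community = as.integer(memb)),
       modularity = igraph::modularity(g, memb))
}

#' Continuous-trait assortativity coefficient
#'
#' Newman's assortativity for a real-valued trait: the Pearson
#' correlation of trait values across edge endpoints, each undirected
#' edge contributing both orientations.
#'
#' @inheritParams network_density
#' @param trait per-node trait values, in vertex order; defaults to the
#'   graph's `trait` vertex attribute.
#' @return The assortativity coefficient in \[-1, 1\].
#' @export
trait_assortativity <- function(net, trait = NULL) {
  g <- as_social_graph(net)
  if (is.null(trait)) trait <- igraph::vertex_attr(g, "trait")
  if (is.null(trait)) abort("no trait values supplied and no `trait` vertex attribute")
  if (length(trait) != igraph::vcount(g)) {
    abort("`trait` must have one value per node")
  }
  if (igraph::ecount(g) == 0) abort("assortativity is undefined without edges")
  ends <- igraph::as_edgelist(g, names = FALSE)
  x <- trait[c(ends[, 1], ends[, 2])]
  y <- trait[c(ends[, 2], ends[, 1])]
  if (var(x) == 0) abort("assortativity is undefined: zero trait variance over edge endpoints")
  cor(x, y)
}

#' Standard summary metrics of a social network
#'
#' One-row tibble with the measures used throughout the package:
#' density, mean degree, global and mean local clustering, maximal
#' walktrap modularity and (when a trait is available) assortativity.
#'
#' @inheritParams trait_assortativity
#' @inheritParams clustering_coefficients
#' @return A one-row tibble.
#' @examples
#' net <- simulate_network(30, p_n = 0.8, p_r = 0.05, steps = 300, seed = 1)
#' network_metrics(net)
#' @export
network_metrics <- function(net, trait = NULL, isolates = c("zero", "exclude")) {
  g <- as_social_graph(net)
  cl <- clustering_coefficients(g, isolates = isolates)
  if (is.null(trait)) trait <- igraph::vertex_attr(g, "trait")
  r <- if (!is.null(trait) && igraph::ecount(g) > 0) {
    tryCatch(trait_assortativity(g, trait), error = function(e) NA_real_)
  } else NA_real_
  tibble::tibble(
    n = igraph::vcount(g),
    edges = igraph::ecount(g),
    density = network_density(g),
    mean_degree = mean(igraph::degree(g)),
    global_clustering = cl$global,
    mean_local_clustering = cl$mean_local,
    modularity = communities_and_modularity(g)$modularity,
    assortativity = r
  )
}
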