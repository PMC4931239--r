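#' Social network container
#'
#' A `si_network` bundles the binary undirected social network (an
#' [igraph][igraph::igraph-package] graph whose vertices carry stable
#' identifiers and, when available, `sex`, `trait`, `mother` and
#' `birth_step` attributes) with the lineage log of the birth--death
#' process that produced it and the parameters of that run.
#'
#' @param graph an igraph object, undirected and simple.
#' @param lineage a tibble with one row per birth--death event
#'   (`step`, `newborn`, `mother`, `father`, `dead`, `degree_at_birth`).
#' @param params a named list of the run parameters.
#'
#' @return An object of class `si_network` with elements `graph`,
#'   `lineage` and `params`.
#' @keywords internal
new_si_network <- function(graph, lineage = NULL, params = list()) {
  if (is.null(lineage)) {
    lineage <- tibble::tibble(
      step = integer(), newborn = integer(), mother = integer(),
      father = integer(), dead = integer(), degree_at_birth = integer()
    )
  }
  structure(list(graph = graph, lineage = lineage, params = params),
            class = "si_network")
}

#' Extract the igraph graph from a network-like object
#'
#' Most functions in the package accept either a [si_network][new_si_network]
#' (as returned by [simulate_network()] and friends), a plain igraph object,
#' or a binary adjacency matrix; this coercion hides the difference.
#'
#' @param x a `si_network`, igraph object, or square 0/1 matrix.
#' @return An undirected simple igraph object.
#' @export
as_social_graph <- function(x) {
  if (inherits(x, "si_network")) return(x$graph)
  if (igraph::is_igraph(x)) {
    if (igraph::is_directed(x)) abort("social networks must be undirected")
    return(x)
  }
  if (is.matrix(x)) {
    if (nrow(x) != ncol(x)) abort("adjacency matrix must be square")
    if (any(x != t(x))) abort("adjacency matrix must be symmetric")
    return(igraph::graph_from_adjacency_matrix(x != 0, mode = "undirected"))
  }
  abort("cannot interpret `x` as a social network")
}

si_adjacency <- function(x) {
  g <- as_social_graph(x)
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) != 0
}

#' @export
print.si_network <- function(x, ...) {
  g <- x$graph
  cat(sprintf("<si_network> %d nodes, %d edges", igraph::vcount(g),
              igraph::ecount(g)))
  p <- x$params
  if (length(p)) {
    shown <- intersect(c("n", "p_b", "p_n", "p_r", "steps"), names(p))
    cat(" | ", paste(sprintf("%s=%s", shown, unlist(p[shown])), collapse = ", "))
  }
  cat("\n")
  if (nrow(x$lineage)) {
    cat(sprintf("  lineage: %d birth-death events\n", nrow(x$lineage)))
  }
  invisible(x)
}

# build an si_network from an engine result
si_from_engine <- function(out, params, extra_attrs = list()) {
  adj <- out$adj
  g <- igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected")
  igraph::V(g)$name <- as.character(out$ids)
  if (!is.null(out$sex) && any(out$sex > 0L)) {
    igraph::V(g)$sex <- c(NA_character_, "F", "M")[out$sex + 1L]
  }
  igraph::V(g)$birth_step <- out$birth_step
  igraph::V(g)$mother <- out$mother_id
  for (nm in names(extra_attrs)) {
    g <- igraph::set_vertex_attr(g, nm, value = extra_attrs[[nm]])
  }
  lin <- out$lineage
  lineage <- tibble::tibble(
    step = lin[, 1], newborn = lin[, 2], mother = lin[, 3],
    father = lin[, 4], dead = lin[, 5], degree_at_birth = lin[, 6]
  )
  new_si_network(g, lineage, params)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1]", name))
  }
  x
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

#' Bundle model parameters
#'
#' Convenience constructor validating the parameter quadruple of the
#' social-inheritance model: group size `n`, the probability `p_b` that a
#' newborn bonds its mother, the social-inheritance probability `p_n`
#' (per maternal contact) and the random-bonding probability `p_r`
#' (per non-contact), plus run controls.
#'
#' @param n group size (constant through the birth--death process); at least 3.
#' @param p_n probability the newborn bonds each of its mother's contacts.
#' @param p_r probability the newborn bonds each individual not connected
#'   to its mother.
#' @param p_b probability the newborn bonds its mother (default 1).
#' @param steps number of birth--death events; 10 population turnovers
#'   (`10 * n`) is the default rule of thumb for reaching stationarity.
#' @param seed optional integer seed.
#'
#' @return A one-row tibble of class `si_params`.
#' @examples
#' model_params(100, p_n = 0.9, p_r = 0.01)
#' @export
model_params <- function(n, p_n, p_r, p_b = 1, steps = 10 * n, seed = NULL) {
  n <- check_count(n, "n", min = 3L)
  check_prob(p_b, "p_b"); check_prob(p_n, "p_n"); check_prob(p_r, "p_r")
  steps <- check_count(steps, "steps", min = 0L)
  out <- tibble::tibble(n = n, p_b = p_b, p_n = p_n, p_r = p_r, steps = steps,
                        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  class(out) <- c("si_params", class(out))
  out
}
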