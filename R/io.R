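#' Read a binary social network from file
#'
#' Supports a two-column CSV edge list (header `source,target`), a
#' labelled CSV adjacency matrix, and GraphML. Directed or weighted
#' inputs are rejected rather than silently coerced; duplicate edges are
#' collapsed and self-loops dropped, each with a warning.
#'
#' @param path file to read.
#' @param format input format; `"auto"` guesses from the extension
#'   (`.graphml` for GraphML, otherwise the CSV is inspected: a square
#'   labelled matrix is treated as an adjacency matrix).
#' @return An undirected simple igraph object with character node names.
#' @export
read_network <- function(path, format = c("auto", "edgelist", "adjacency",
                                          "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml"
    else {
      hdr <- utils::read.csv(path, nrows = 1, check.names = FALSE)
      if (ncol(hdr) == 2) "edgelist" else "adjacency"
    }
  }
  g <- switch(format,
    graphml = {
      gg <- igraph::read_graph(path, format = "graphml")
      if (igraph::is_directed(gg)) abort("directed GraphML input rejected")
      if ("weight" %in% igraph::edge_attr_names(gg)) {
        abort("weighted GraphML input rejected")
      }
      gg
    },
    edgelist = {
      df <- utils::read.csv(path, colClasses = "character")
      if (ncol(df) != 2) {
        abort(sprintf("edge list must have exactly 2 columns, found %d", ncol(df)))
      }
      if (any(!stats::complete.cases(df)) || any(df == "")) {
        bad <- which(!stats::complete.cases(df) | df[[1]] == "" | df[[2]] == "")[1]
        abort(sprintf("malformed edge list at data line %d", bad))
      }
      igraph::graph_from_data_frame(df, directed = FALSE)
    },
    adjacency = {
      m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
      if (nrow(m) != ncol(m)) abort("adjacency matrix must be square")
      if (anyNA(suppressWarnings(storage.mode(m) <- "numeric")) || anyNA(m)) {
        abort("adjacency matrix contains non-numeric entries")
      }
      if (any(m != t(m))) {
        bad <- which(m != t(m), arr.ind = TRUE)[1, ]
        abort(sprintf("asymmetric adjacency entry at (%s, %s)",
                      rownames(m)[bad[1]], colnames(m)[bad[2]]))
      }
      if (!all(m %in% c(0, 1))) {
        abort("adjacency entries must be 0/1; weighted input rejected")
      }
      gg <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                                diag = TRUE)
      gg
    }
  )
  if (anyDuplicated(rownames(igraph::as_adjacency_matrix(g)))) {
    abort("node labels must be unique")
  }
  loops <- sum(igraph::which_loop(g))
  if (loops > 0) warn(sprintf("%d self-loop(s) dropped", loops))
  dups <- sum(igraph::which_multiple(g))
  if (dups > 0) warn(sprintf("%d duplicate edge(s) collapsed", dups))
  igraph::simplify(g)
}

#' Write a social network to file
#'
#' @param net a network (anything [as_social_graph()] accepts).
#' @param path output file.
#' @param format `"graphml"` (carrying any `sex`, `trait`, `mother` and
#'   `birth_step` vertex attributes), `"edgelist"` (CSV
#'   `source,target`), or `"adjacency"` (labelled CSV matrix); `"auto"`
#'   picks GraphML for `.graphml`, edge list otherwise.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("auto", "graphml", "edgelist",
                                                "adjacency")) {
  format <- match.arg(format)
  g <- as_social_graph(net)
  if (format == "auto") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml"
    else "edgelist"
  }
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  switch(format,
    graphml = igraph::write_graph(g, path, format = "graphml"),
    edgelist = {
      el <- igraph::as_edgelist(g)
      utils::write.csv(data.frame(source = el[, 1], target = el[, 2]),
                       path, row.names = FALSE, quote = FALSE)
    },
    adjacency = {
      m <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
      utils::write.csv(m, path, quote = FALSE)
    }
  )
  invisible(path)
}

#' Read an association-index matrix
#'
#' Reads a labelled CSV matrix of non-negative association indices and
#' validates it: symmetric within `1e-9`, zero diagonal, unique labels.
#'
#' @param path CSV file with row and column labels.
#' @return A symmetric numeric matrix with dimnames.
#' @export
read_association_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  storage.mode(m) <- "numeric"
  if (nrow(m) != ncol(m)) abort("association matrix must be square")
  if (anyNA(m)) abort("association matrix contains missing values")
  if (any(m < 0)) abort("association indices must be non-negative")
  if (max(abs(m - t(m))) > 1e-9) abort("association matrix must be symmetric")
  if (any(abs(diag(m)) > 1e-9)) abort("association matrix must have a zero diagonal")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    abort("node labels must be unique")
  }
  m
}

#' Threshold an association matrix into a binary network
#'
#' Retains the upper quartile of association values: pair `(i, j)`
#' becomes an edge when its association strictly exceeds the `quantile`
#' (default 0.75, linear interpolation) of the unordered-pair values.
#' Pairs with zero association are excluded from the quantile by default
#' (set `include_zeros = TRUE` to keep them).
#'
#' @param assoc a symmetric association matrix (see
#'   [read_association_matrix()]).
#' @param quantile quantile of pair values above which an edge is kept.
#' @param include_zeros include zero associations in the quantile
#'   computation.
#' @return An undirected igraph object on the matrix's labels.
#' @export
threshold_binary <- function(assoc, quantile = 0.75, include_zeros = FALSE) {
  if (!is.matrix(assoc) || nrow(assoc) != ncol(assoc)) {
    abort("`assoc` must be a square matrix")
  }
  if (nrow(assoc) < 2) abort("`assoc` must cover at least 2 nodes")
  check_prob(quantile, "quantile")
  vals <- assoc[upper.tri(assoc)]
  pool <- if (include_zeros) vals else vals[vals > 0]
  labels <- rownames(assoc)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(assoc)))
  if (!length(pool) || length(unique(pool)) == 1) {
    warn("all association values equal; returning an empty network")
    g <- igraph::make_empty_graph(nrow(assoc), directed = FALSE)
    igraph::V(g)$name <- labels
    return(g)
  }
  thr <- stats::quantile(pool, quantile, names = FALSE)
  adj <- assoc > thr
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- labels
  g
}

#' Generate plain-text fixtures with known ground truth
#'
#' `"assoc-matrix"` simulates a social-inheritance network and overlays
#' noisy positive association indices, larger on edges than on
#' non-edges, so that thresholding approximately recovers the generating
#' network; the written manifest records the exact quantile at which
#' recovery of a noiseless overlay is perfect. `"ensemble"` writes `m`
#' simulated networks as edge-list CSVs plus a manifest of the true
#' `(p_n, p_r, seed)` per network.
#'
#' @param kind fixture type.
#' @param dir output directory (created if needed).
#' @inheritParams simulate_network
#' @param noise_sd s.d. of the Gaussian noise added to the association
#'   overlay.
#' @param m number of networks in the ensemble.
#' @param p_n,p_r bonding probabilities of the generating model; for the
#'   ensemble these are drawn uniformly when `NULL`.
#' @return Invisibly, a list with the written `files` and the `manifest`
#'   tibble; the generating network is attached for `"assoc-matrix"`.
#' @export
generate_fixture <- function(kind = c("assoc-matrix", "ensemble"), dir,
                             n = 50, p_n = 0.8, p_r = 0.02, steps = 10 * n,
                             noise_sd = 0.05, m = 5, seed = NULL) {
  kind <- match.arg(kind)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(seed)) set.seed(seed)
  if (kind == "assoc-matrix") {
    net <- simulate_network(n = n, p_n = p_n, p_r = p_r, steps = steps)
    adj <- si_adjacency(net)
    labels <- igraph::V(net$graph)$name
    base <- ifelse(adj, 0.75, 0.25)
    noise <- matrix(rnorm(n * n, 0, noise_sd), n, n)
    noise[lower.tri(noise, diag = TRUE)] <- 0
    noise <- noise + t(noise)
    assoc <- pmax(base + noise, 0)
    diag(assoc) <- 0
    dimnames(assoc) <- list(labels, labels)
    path <- file.path(dir, "association_matrix.csv")
    utils::write.csv(assoc, path, quote = FALSE)
    n_edges <- sum(adj) / 2
    n_pairs <- n * (n - 1) / 2
    manifest <- tibble::tibble(file = basename(path), n = n, p_n = p_n,
                               p_r = p_r, steps = steps, noise_sd = noise_sd,
                               n_edges = n_edges,
                               exact_quantile = 1 - n_edges / n_pairs)
    mpath <- file.path(dir, "manifest.csv")
    utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
    return(invisible(list(files = c(path, mpath), manifest = manifest,
                          network = net)))
  }
  if (is.null(p_n)) p_n <- runif(m)
  if (is.null(p_r)) p_r <- runif(m)
  p_n <- rep_len(p_n, m); p_r <- rep_len(p_r, m)
  seeds <- sample.int(1e6, m)
  files <- character(m)
  for (i in seq_len(m)) {
    net <- simulate_network(n = n, p_n = p_n[i], p_r = p_r[i], steps = steps,
                            seed = seeds[i])
    files[i] <- file.path(dir, sprintf("network_%03d.csv", i))
    write_network(net, files[i], format = "edgelist")
  }
  manifest <- tibble::tibble(file = basename(files), n = n, p_n = p_n,
                             p_r = p_r, steps = steps, seed = seeds)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  invisible(list(files = c(files, mpath), manifest = manifest))
}

#' Write a JSON run record next to an output file
#'
#' Records the parameters, seed and package version of a run so that
#' identical records imply identical outputs.
#'
#' @param out_path the output file the record describes.
#' @param params named list of run parameters.
#' @return The record path, invisibly.
#' @export
write_run_record <- function(out_path, params) {
  rec <- list(
    output = basename(out_path),
    params = params,
    package = "socinherit",
    version = as.character(utils::packageVersion("socinherit")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  path <- paste0(out_path, ".run.json")
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
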