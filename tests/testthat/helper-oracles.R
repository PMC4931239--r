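# Independent brute-force oracles used to check the package's faster
# implementations on small inputs.

# stationarity balance for the mean degree, iterated to its fixed point
oracle_mean_degree <- function(n, p_n, p_r, p_b, iters = 20000) {
  d <- 0
  for (i in seq_len(iters)) {
    dp <- d * (n - 2) / (n - 1)
    d <- p_b + p_n * dp + p_r * (n - 2 - dp)
  }
  d
}

# exhaustive triplet enumeration for clustering coefficients
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  closed <- 0L; triplets <- 0L
  local <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] != 0)
    k <- length(nb)
    if (k < 2) { local[v] <- 0; next }
    pairs <- utils::combn(nb, 2)
    conn <- sum(adj[t(pairs)] != 0)
    local[v] <- conn / ncol(pairs)
    triplets <- triplets + ncol(pairs)  # open or closed triplets centred at v
    closed <- closed + conn             # each triangle counted once per centre
  }
  list(global = if (triplets == 0) 0 else closed / triplets, local = local)
}

# betweenness by exhaustive enumeration of simple paths (small graphs only)
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  all_paths <- function(from, to, maxlen) {
    # all simple paths up to maxlen edges, as a list of vertex vectors
    res <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == to) { res[[length(res) + 1]] <<- path; return() }
      if (length(path) > maxlen) return()
      for (nx in which(adj[last, ] != 0)) {
        if (!(nx %in% path)) walk(c(path, nx))
      }
    }
    walk(from)
    res
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- all_paths(s, t, n)
    if (!length(paths)) next
    lens <- vapply(paths, length, integer(1))
    shortest <- paths[lens == min(lens)]
    sigma <- length(shortest)
    inner <- unlist(lapply(shortest, function(p) p[-c(1, length(p))]))
    if (length(inner)) {
      counts <- table(inner)
      idx <- as.integer(names(counts))
      btw[idx] <- btw[idx] + as.vector(counts) / sigma
    }
  }
  btw
}

# all set partitions of 1..n (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  grow <- function(code, mx) {
    i <- length(code) + 1
    if (i > n) { out[[length(out) + 1]] <<- code; return() }
    for (b in seq_len(mx + 1)) grow(c(code, b), max(mx, b))
  }
  grow(integer(), 0L)
  out
}

# Newman modularity of a given membership vector
oracle_modularity <- function(adj, membership) {
  m <- sum(adj) / 2
  if (m == 0) return(0)
  q <- 0
  for (com in unique(membership)) {
    inside <- membership == com
    e_ii <- sum(adj[inside, inside]) / 2 / m
    a_i <- sum(adj[inside, ]) / 2 / m
    q <- q + e_ii - a_i^2
  }
  q
}

oracle_max_modularity <- function(adj) {
  parts <- all_partitions(nrow(adj))
  max(vapply(parts, function(p) oracle_modularity(adj, p), numeric(1)))
}

# Monte-Carlo estimate of the newborn's expected clustering coefficient
# E[T_c / T_t] given integer mother degree d_p (0 when fewer than 2 bonds)
oracle_newborn_cc <- function(n, p_b, p_n, p_r, d_p, cp, rho, eta,
                              draws = 200000) {
  x_p <- rbinom(draws, 1, p_b)
  x_pc <- rbinom(draws, d_p, p_n)
  x_npc <- rbinom(draws, n - d_p - 2, p_r)
  s <- x_p + x_pc + x_npc
  tt <- s * (s - 1) / 2
  tc <- x_p * x_pc + cp * x_pc * (x_pc - 1) / 2 + rho * x_pc * x_npc +
    eta * x_npc * (x_npc - 1) / 2
  mean(ifelse(tt > 0, tc / tt, 0))
}

random_small_adj <- function(n, p) {
  adj <- matrix(0L, n, n)
  up <- upper.tri(adj)
  adj[up] <- rbinom(sum(up), 1, p)
  adj + t(adj)
}
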