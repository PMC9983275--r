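# Independent graph-topology oracle: plain-R BFS distances and shortest-path
# counting over an adjacency matrix, with betweenness summed pair by pair.

oracle_bfs <- function(adj, s) {
  n <- nrow(adj)
  dist <- rep(Inf, n); sigma <- rep(0, n)
  dist[s] <- 0; sigma[s] <- 1
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (u in frontier) {
      for (v in which(adj[u, ] > 0)) {
        if (is.infinite(dist[v])) {
          dist[v] <- dist[u] + 1
          nxt <- c(nxt, v)
        }
        if (dist[v] == dist[u] + 1) sigma[v] <- sigma[v] + sigma[u]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

# degree, total path length, closeness, pair-dependency betweenness
# (normalized per component), all from first principles
oracle_topology <- function(adj) {
  n <- nrow(adj)
  bfs <- lapply(seq_len(n), function(s) oracle_bfs(adj, s))
  D <- vapply(bfs, function(b) b$dist, numeric(n))  # D[v, s] = dist(s, v)
  S <- vapply(bfs, function(b) b$sigma, numeric(n)) # S[v, s] = sigma_s(v)
  comp_sizes <- vapply(seq_len(n), function(v) sum(is.finite(D[, v])), 1)
  L <- vapply(seq_len(n), function(v) {
    d <- D[, v]; sum(d[is.finite(d)])
  }, 1)
  B <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t || !is.finite(D[t, s])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(D[v, s]) && D[v, s] + D[t, v] == D[t, s]) {
        B[v] <- B[v] + S[v, s] * S[t, v] / S[t, s]
      }
    }
  }
  denom <- (comp_sizes - 1) * (comp_sizes - 2) / 2
  tibble::tibble(
    node_id = as.character(seq_len(n)),
    degree = rowSums(adj > 0),
    n_component = comp_sizes,
    L = L,
    closeness = ifelse(comp_sizes > 1, (comp_sizes - 1) / L, NA_real_),
    betweenness = ifelse(denom > 0, B / denom,
                         ifelse(comp_sizes > 1, 0, NA_real_)),
    singleton = comp_sizes == 1)
}

random_adjacency <- function(n, p) {
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  adj + t(adj)
}

igraph_from_adj <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- as.character(seq_len(nrow(adj)))
  g
}
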