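# Independent brute-force oracles used to cross-check the implementation.

# clustering coefficient by direct neighbor-pair enumeration
oracle_clustering <- function(g) {
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    nb <- which(A[v, ])
    k <- length(nb)
    if (k < 2) return(0)
    e <- sum(A[nb, nb]) / 2
    e / (k * (k - 1) / 2)
  }, numeric(1))
}

# all-pairs hop distances by hand-rolled BFS
oracle_bfs_distances <- function(g) {
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    lev <- 0
    while (length(frontier)) {
      lev <- lev + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(A[v, ]))))
      nxt <- nxt[dist[nxt] == Inf]
      dist[nxt] <- lev
      frontier <- nxt
    }
    d[s, ] <- dist
  }
  d
}

# effective resistance via the Moore-Penrose pseudoinverse quadratic form
oracle_resistance <- function(g, iu, iv) {
  L <- graph_laplacian(g)
  Lp <- MASS::ginv(L)
  e <- numeric(nrow(L))
  e[iu] <- 1
  e[iv] <- -1
  drop(t(e) %*% Lp %*% e)
}

# degree-class census of the level-m gasket clustering (closed form):
# 3 corners with c = 1, 3^m vertices with c = 1/2, (3^m - 3)/2 with c = 1/3
gasket_closed_form_clustering <- function(level) {
  n <- (3^(level + 1) + 3) / 2
  (3 * 1 + 3^level * (1 / 2) + (3^level - 3) / 2 * (1 / 3)) / n
}

# small connected random graph for property tests
random_connected_graph <- function(n, p, seed) {
  g <- random_gnp(n, p, seed = seed)
  giant_component(g)
}
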