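#' Erdos-Renyi random graph G(n, p)
#'
#' Each of the n(n-1)/2 unordered vertex pairs becomes an edge independently
#' with probability `p`. Reproducible for a fixed `seed`.
#'
#' @param n Number of vertices (>= 1).
#' @param p Connection probability in \eqn{[0, 1]}.
#' @param seed Optional integer seed for the pseudo-random stream.
#' @return An undirected simple `igraph` with vertices labeled `"1" ... "n"`.
#' @examples
#' igraph::ecount(random_gnp(5, 1)) # complete graph: 10 edges
#' @export
random_gnp <- function(n, p, seed = NULL) {
  if (n < 1) stop("`n` must be at least 1")
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1], got ", p)
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_gnp(n, p, directed = FALSE, loops = FALSE)
  igraph::set_vertex_attr(g, "name", value = as.character(seq_len(n)))
}

#' Random branching tree
#'
#' Grows a tree on exactly `n` vertices in breadth order: each branch-point,
#' visited in label order, draws a number of children uniformly from
#' `1:max_children`, capped by the remaining vertex budget, and its children
#' are the smallest-labeled vertices not yet attached. The result is
#' connected and acyclic with n - 1 edges and maximum degree
#' `max_children + 1` (children plus the parent link); no looping exists in
#' the structure.
#'
#' @param n Number of vertices (>= 1).
#' @param max_children Maximum number of children from any branch-point
#'   (B >= 1). `max_children = 1` forces a path graph.
#' @param seed Optional integer seed.
#' @return An undirected tree as `igraph`, vertices labeled `"1" ... "n"`.
#' @export
random_tree <- function(n, max_children, seed = NULL) {
  if (n < 1) stop("`n` must be at least 1")
  if (max_children < 1) stop("`max_children` must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  edges <- integer(0)
  next_child <- 2L
  v <- 1L
  while (next_child <= n) {
    b <- sample.int(max_children, 1L)
    b <- min(b, n - next_child + 1L) # never add more vertices than n
    kids <- seq.int(next_child, length.out = b)
    edges <- c(edges, rbind(rep(v, b), kids))
    next_child <- next_child + b
    v <- v + 1L
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::set_vertex_attr(g, "name", value = as.character(seq_len(n)))
}

#' Sierpinski gasket graph approximation
#'
#' Level-m graph approximation of the Sierpinski gasket: level 0 is a
#' triangle; level m consists of three level-(m-1) copies with the touching
#' outer corners identified pairwise. The level-m graph has
#' \eqn{(3^{m+1} + 3)/2} vertices and \eqn{3^{m+1}} edges. Vertices are
#' labeled `"1" ... "n"` in a canonical coordinate order (dyadic lattice
#' positions, stored in vertex attributes `x` and `y`), so repeated calls
#' are bit-identical.
#'
#' @param level Approximation depth m >= 0.
#' @return An undirected simple `igraph`.
#' @examples
#' g <- sierpinski_gasket(1)
#' igraph::vcount(g) # 6
#' igraph::ecount(g) # 9
#' @export
sierpinski_gasket <- function(level) {
  if (length(level) != 1L || is.na(level) || level < 0) {
    stop("`level` must be a nonnegative integer")
  }
  level <- as.integer(level)
  s <- 2L^level
  n_cells <- 3L^level
  # accumulate the corner triples of all level-0 cells by recursion on
  # integer lattice coordinates (exact: corners of cells at depth k are
  # multiples of 2^(level-k))
  cells <- matrix(0L, nrow = n_cells, ncol = 6L) # x1 y1 x2 y2 x3 y3
  idx <- 0L
  rec <- function(p1, p2, p3, m) {
    if (m == 0L) {
      idx <<- idx + 1L
      cells[idx, ] <<- c(p1, p2, p3)
    } else {
      m12 <- (p1 + p2) %/% 2L
      m13 <- (p1 + p3) %/% 2L
      m23 <- (p2 + p3) %/% 2L
      rec(p1, m12, m13, m - 1L)
      rec(m12, p2, m23, m - 1L)
      rec(m13, m23, p3, m - 1L)
    }
  }
  rec(c(0L, 0L), c(s, 0L), c(0L, s), level)
  key <- function(x, y) paste0(x, ",", y)
  corner_keys <- cbind(key(cells[, 1], cells[, 2]),
                       key(cells[, 3], cells[, 4]),
                       key(cells[, 5], cells[, 6]))
  el <- rbind(corner_keys[, c(1, 2)], corner_keys[, c(1, 3)], corner_keys[, c(2, 3)])
  # canonical vertex order: by (y, x)
  coords <- unique(rbind(cells[, 1:2], cells[, 3:4], cells[, 5:6]))
  coords <- coords[order(coords[, 2], coords[, 1]), , drop = FALSE]
  vkeys <- key(coords[, 1], coords[, 2])
  lookup <- stats::setNames(seq_along(vkeys), vkeys)
  g <- igraph::make_empty_graph(length(vkeys), directed = FALSE)
  g <- igraph::add_edges(g, rbind(lookup[el[, 1]], lookup[el[, 2]]))
  g <- igraph::simplify(g)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(seq_along(vkeys)))
  g <- igraph::set_vertex_attr(g, "x", value = coords[, 1])
  igraph::set_vertex_attr(g, "y", value = coords[, 2])
}

#' Hexacarpet graph approximation
#'
#' Level-m hexacarpet: the face-adjacency graph of the m-fold repeated
#' barycentric subdivision of a triangle. Vertices are the \eqn{6^m} faces;
#' two faces are joined when they share a 1-dimensional boundary (an edge of
#' the subdivision). Level 1 is a 6-cycle. Labeling is canonical (faces
#' sorted by their vertex coordinates), so repeated calls are bit-identical.
#'
#' @param level Subdivision depth m >= 1.
#' @return An undirected simple `igraph` on `6^level` vertices.
#' @export
hexacarpet <- function(level) {
  if (length(level) != 1L || is.na(level) || level < 1) {
    stop("`level` must be a positive integer (level 0 has no face adjacency)")
  }
  level <- as.integer(level)
  s <- 6^level # scale so midpoints (/2) and centroids (/3) stay integral
  tris <- list(rbind(c(0, 0), c(s, 0), c(0, s)))
  for (k in seq_len(level)) {
    out <- vector("list", 6L * length(tris))
    i <- 0L
    for (tr in tris) {
      a <- tr[1, ]; b <- tr[2, ]; cc <- tr[3, ]
      mab <- (a + b) %/% 2L
      mbc <- (b + cc) %/% 2L
      mca <- (cc + a) %/% 2L
      ctr <- (a + b + cc) %/% 3L
      for (f in list(rbind(a, mab, ctr), rbind(mab, b, ctr), rbind(b, mbc, ctr),
                     rbind(mbc, cc, ctr), rbind(cc, mca, ctr), rbind(mca, a, ctr))) {
        i <- i + 1L
        out[[i]] <- f
      }
    }
    tris <- out
  }
  vkey <- function(p) paste0(p[1], ",", p[2])
  face_keys <- vapply(tris, function(tr) {
    paste(sort(apply(tr, 1, vkey)), collapse = ";")
  }, character(1))
  ord <- order(face_keys)
  tris <- tris[ord]
  # faces sharing a subdivision edge are adjacent
  edge_faces <- new.env(parent = emptyenv())
  for (i in seq_along(tris)) {
    vk <- sort(apply(tris[[i]], 1, vkey))
    for (pr in list(c(1L, 2L), c(1L, 3L), c(2L, 3L))) {
      ek <- paste(vk[pr], collapse = "|")
      edge_faces[[ek]] <- c(edge_faces[[ek]], i)
    }
  }
  pairs <- Filter(function(x) length(x) == 2L, as.list(edge_faces))
  el <- do.call(rbind, pairs)
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  g <- igraph::make_empty_graph(length(tris), directed = FALSE)
  g <- igraph::add_edges(g, t(el))
  igraph::set_vertex_attr(g, "name", value = as.character(seq_along(tris)))
}

#' Probabilistic edge rewiring
#'
#' Visits every edge \{i, j\} (with i < j in label order) once and rewires
#' it with probability `p`: the connection to the lower-labeled endpoint i
#' is kept, and the other endpoint moves to a vertex k chosen uniformly
#' among the vertices not currently adjacent to i (and distinct from i).
#' Edge count and simplicity are preserved. If i is adjacent to every other
#' vertex the rewire is skipped (and counted in attribute `skipped`).
#'
#' @param g An undirected simple `igraph`.
#' @param p Rewiring probability in \eqn{[0, 1]}. `p = 0` returns the input.
#' @param seed Optional integer seed.
#' @return The rewired `igraph`, with graph attributes `rewired` and
#'   `skipped` recording how many edges moved / could not move.
#' @export
rewire_edges <- function(g, p, seed = NULL) {
  g <- ensure_names(g)
  check_graph(g)
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1], got ", p)
  if (!is.null(seed)) set.seed(seed)
  labels <- igraph::V(g)$name
  n <- length(labels)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  el <- igraph::as_edgelist(g, names = FALSE)
  # canonical order: endpoints sorted within the edge, edges sorted
  el <- t(apply(el, 1, sort))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  rewired <- 0L
  skipped <- 0L
  for (e in seq_len(nrow(el))) {
    if (stats::runif(1) >= p) next
    i <- el[e, 1]
    j <- el[e, 2]
    candidates <- which(!adj[i, ])
    candidates <- candidates[candidates != i]
    if (length(candidates) == 0L) {
      skipped <- skipped + 1L
      next
    }
    k <- candidates[sample.int(length(candidates), 1L)]
    adj[i, j] <- adj[j, i] <- FALSE
    adj[i, k] <- adj[k, i] <- TRUE
    el[e, ] <- sort(c(i, k))
    rewired <- rewired + 1L
  }
  dimnames(adj) <- list(labels, labels)
  out <- igraph::graph_from_adjacency_matrix(adj * 1L, mode = "undirected")
  out <- igraph::set_graph_attr(out, "rewired", rewired)
  igraph::set_graph_attr(out, "skipped", skipped)
}

#' Matched Erdos-Renyi random graph
#'
#' Generates G(n, p) with the same vertex count as `g` and edge probability
#' equal to `g`'s edge density, p = |E| / (n(n-1)/2) -- the probability that
#' two random vertices of `g` are connected. Used as the random control in
#' small-world comparisons.
#'
#' @param g An undirected simple `igraph` with at least 2 vertices.
#' @param seed Optional integer seed.
#' @return A `igraph` with graph attribute `matched_p` recording p.
#' @export
matched_random <- function(g, seed = NULL) {
  check_graph(g)
  n <- igraph::vcount(g)
  if (n < 2) stop("`g` must have at least 2 vertices")
  p <- igraph::ecount(g) / (n * (n - 1) / 2)
  out <- random_gnp(n, p, seed = seed)
  igraph::set_graph_attr(out, "matched_p", p)
}
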