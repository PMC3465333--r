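#' Graph energy of a vertex function
#'
#' \eqn{E(f) = \sum_{\{u,v\} \in E} (f(u) - f(v))^2}, the Laplacian
#' quadratic form. For a unit-norm eigenfunction with eigenvalue
#' \eqn{\lambda}, \eqn{E(f) = \lambda}.
#'
#' @param g An undirected simple `igraph`.
#' @param f Numeric vertex function, in vertex order or named by vertex.
#' @return A single nonnegative number.
#' @export
graph_energy <- function(g, f) {
  g <- ensure_names(g)
  check_graph(g)
  f <- match_vertex_function(g, f)
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) == 0) return(0)
  sum((f[el[, 1]] - f[el[, 2]])^2)
}

match_vertex_function <- function(g, f) {
  n <- igraph::vcount(g)
  if (!is.null(names(f))) {
    miss <- setdiff(igraph::V(g)$name, names(f))
    if (length(miss)) stop("`f` is missing vertices: ", paste(head(miss, 3), collapse = ", "))
    f <- f[igraph::V(g)$name]
  }
  if (length(f) != n) {
    stop("`f` has length ", length(f), " but the graph has ", n, " vertices")
  }
  as.numeric(f)
}

#' Harmonic function between two boundary vertices
#'
#' Solves the discrete Laplace equation `L h = e_u - e_v`: h is harmonic at
#' every vertex except the source `u` and sink `v`. The singular system is
#' made solvable by grounding one vertex (fixing its value to 0); any choice
#' of ground yields the same potential differences. The effective
#' resistance between u and v is `h(u) - h(v)`, the energy of h.
#'
#' @param g A connected undirected simple `igraph`.
#' @param u,v Vertex names or indices (distinct).
#' @return Named numeric vector h with attributes `resistance` and `energy`.
#' @export
harmonic_function <- function(g, u, v) {
  g <- ensure_names(g)
  check_graph(g)
  iu <- as_vertex_index(g, u)
  iv <- as_vertex_index(g, v)
  if (iu == iv) stop("`u` and `v` must be distinct")
  comp <- igraph::components(g)
  if (comp$membership[iu] != comp$membership[iv]) {
    stop("`u` and `v` lie in different components: infinite resistance")
  }
  # restrict to the component carrying u, v
  keep <- which(comp$membership == comp$membership[iu])
  sub <- igraph::induced_subgraph(g, keep)
  iu_s <- match(igraph::V(g)$name[iu], igraph::V(sub)$name)
  iv_s <- match(igraph::V(g)$name[iv], igraph::V(sub)$name)
  L <- graph_laplacian(sub)
  n <- nrow(L)
  b <- numeric(n)
  b[iu_s] <- 1
  b[iv_s] <- -1
  ground <- if (n >= 2) setdiff(seq_len(n), c(iu_s, iv_s))[1] else 1L
  if (is.na(ground)) ground <- iv_s # two-vertex graph: ground the sink
  free <- setdiff(seq_len(n), ground)
  h <- numeric(n)
  h[free] <- solve(L[free, free, drop = FALSE], b[free])
  h <- h - h[ground] # ground at exactly 0
  res <- h[iu_s] - h[iv_s]
  out <- stats::setNames(rep(NA_real_, igraph::vcount(g)), igraph::V(g)$name)
  out[igraph::V(sub)$name] <- h
  attr(out, "resistance") <- res
  attr(out, "energy") <- res # E(h) = h(u) - h(v) for unit current
  out
}

as_vertex_index <- function(g, v) {
  if (is.character(v)) {
    i <- match(v, igraph::V(g)$name)
    if (is.na(i)) stop("vertex '", v, "' not found")
    return(i)
  }
  i <- as.integer(v)
  if (i < 1 || i > igraph::vcount(g)) stop("vertex index out of range")
  i
}

#' Effective resistance between two vertices
#'
#' Treats every edge as a unit resistor and returns the electrical
#' resistance between `u` and `v`, computed by solving the Laplacian linear
#' system of the corresponding harmonic function.
#'
#' @inheritParams harmonic_function
#' @return A positive number.
#' @examples
#' g <- random_tree(5, 1, seed = 1) # path graph
#' effective_resistance(g, "1", "5") # 4 unit edges in series
#' @export
effective_resistance <- function(g, u, v) {
  h <- harmonic_function(g, u, v)
  attr(h, "resistance")
}

#' All-pairs effective resistance matrix
#'
#' Computed in one shot from the Moore-Penrose pseudoinverse of the
#' Laplacian: \eqn{R(u,v) = L^+_{uu} + L^+_{vv} - 2 L^+_{uv}}. The
#' pseudoinverse is assembled from the eigendecomposition, dropping the null
#' space. Requires a connected graph. R is symmetric with zero diagonal,
#' satisfies the triangle inequality, and never exceeds the hop distance.
#'
#' @param g A connected undirected simple `igraph`.
#' @return Dense symmetric matrix with vertex labels as dimnames.
#' @export
resistance_matrix <- function(g) {
  g <- ensure_names(g)
  check_graph(g)
  if (!igraph::is_connected(g)) {
    stop("graph is disconnected: resistances between components are infinite")
  }
  s <- graph_spectrum(g, normalized = FALSE)
  pos <- s$values > .SPECTRAL_TOL
  V <- s$vectors[, pos, drop = FALSE]
  Lp <- V %*% (t(V) / s$values[pos])
  dg <- diag(Lp)
  R <- outer(dg, dg, "+") - 2 * Lp
  R[R < 0] <- 0 # clip rounding noise
  diag(R) <- 0
  R <- (R + t(R)) / 2
  dimnames(R) <- list(s$labels, s$labels)
  R
}

#' Spacial variance of a vertex function
#'
#' Resistance-weighted spread of the squared function values about its best
#' center: \deqn{Var_c(f) = \min_y \sum_x R(x, y)^c f(x)^2,} with `f`
#' unit-normalized. A low spacial variance means the function's mass sits in
#' a small resistance-ball -- the function is localized. The minimizing
#' center vertex is recorded (first index on ties). The value is invariant
#' under a global sign flip of `f` and under vertex relabeling.
#'
#' @param g A connected undirected simple `igraph`.
#' @param f Numeric vertex function (unit-normalized; otherwise normalized
#'   internally with a message).
#' @param c_exponent Positive exponent applied to the resistance (default 1).
#' @param R Optional precomputed [resistance_matrix()] (saves the dominant
#'   cost when scoring many functions on one graph).
#' @return A list with `variance`, `center` (vertex label), `energy`.
#' @export
spacial_variance <- function(g, f, c_exponent = 1, R = NULL) {
  g <- ensure_names(g)
  check_graph(g)
  if (c_exponent <= 0) stop("`c_exponent` must be positive")
  f <- match_vertex_function(g, f)
  nrm <- sqrt(sum(f^2))
  if (nrm == 0) stop("`f` is identically zero")
  if (abs(nrm - 1) > 1e-8) {
    message("normalizing `f` to unit norm (|f| was ", format(nrm, digits = 4), ")")
    f <- f / nrm
  }
  if (is.null(R)) R <- resistance_matrix(g)
  scores <- as.vector((R^c_exponent) %*% f^2) # one score per candidate center
  ctr <- which.min(scores)
  list(variance = scores[ctr],
       center = igraph::V(g)$name[ctr],
       energy = graph_energy(g, f))
}

#' Spacial-variance distribution over all eigenfunctions
#'
#' Eigendecomposes the graph Laplacian, computes the all-pairs resistance
#' matrix once, and scores every non-constant eigenfunction with
#' [spacial_variance()]. The resulting table is the histogram-ready
#' localization profile of the graph: fractal-like graphs concentrate at
#' low variances, random graphs spread to high ones.
#'
#' @param g A connected undirected simple `igraph`.
#' @param c_exponent Positive resistance exponent (default 1).
#' @param normalized Use eigenfunctions of the degree-normalized Laplacian
#'   instead of the plain Laplacian (default `FALSE`).
#' @return Tibble with one row per non-constant eigenfunction: `index`,
#'   `eigenvalue`, `energy`, `variance`, `center`.
#' @export
variance_distribution <- function(g, c_exponent = 1, normalized = FALSE) {
  g <- ensure_names(g)
  check_graph(g)
  if (!igraph::is_connected(g)) {
    stop("graph is disconnected; analyze its giant_component() instead")
  }
  s <- graph_spectrum(g, normalized = normalized)
  R <- resistance_matrix(g)
  Rc <- if (c_exponent == 1) R else R^c_exponent
  keep <- which(s$values > .SPECTRAL_TOL) # drop the constant eigenfunction
  FF <- s$functions[, keep, drop = FALSE]
  # normalize functions (normalized-Laplacian back-transform changes norms)
  FF <- sweep(FF, 2, sqrt(colSums(FF^2)), "/")
  scores <- Rc %*% FF^2 # centers x functions
  ctr <- apply(scores, 2, which.min)
  energies <- vapply(seq_along(keep), function(j) graph_energy(g, FF[, j]), numeric(1))
  tibble::tibble(
    index = keep,
    eigenvalue = s$values[keep],
    energy = energies,
    variance = scores[cbind(ctr, seq_along(keep))],
    center = igraph::V(g)$name[ctr]
  )
}
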