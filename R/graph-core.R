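#' Assemble a simple undirected graph from chemical and gap-junction matrices
#'
#' Combines a (possibly asymmetric) chemical-synapse adjacency matrix with a
#' symmetric gap-junction matrix into one simple undirected graph: the
#' chemical matrix is added to its own transpose to discard directionality,
#' the gap-junction matrix is added on top, all non-zero entries of the
#' combined matrix are set to 1 (no connection multiplicities), and diagonal
#' entries are dropped (no self-loops).
#'
#' @param chem Square numeric matrix of chemical-synapse multiplicities;
#'   may be asymmetric (directed counts). Row/column names, if present, are
#'   used as vertex labels.
#' @param gap Square numeric matrix of gap-junction multiplicities; must be
#'   symmetric and share the dimension (and labeling) of `chem`.
#' @param labels Optional character vector of vertex labels overriding the
#'   matrix dimnames; defaults to dimnames, else `"1" ... "n"`.
#'
#' @return An undirected simple `igraph` with vertex attribute `name`.
#' @examples
#' chem <- matrix(c(0, 2, 0, 0), 2, 2, byrow = TRUE)
#' gap <- matrix(0, 2, 2)
#' g <- assemble_connectome(chem, gap)
#' igraph::ecount(g) # 1
#' @export
assemble_connectome <- function(chem, gap, labels = NULL) {
  chem <- as.matrix(chem)
  gap <- as.matrix(gap)
  if (nrow(chem) != ncol(chem)) {
    stop("`chem` must be square, got ", nrow(chem), "x", ncol(chem))
  }
  if (nrow(gap) != ncol(gap)) {
    stop("`gap` must be square, got ", nrow(gap), "x", ncol(gap))
  }
  if (nrow(chem) != nrow(gap)) {
    stop("`chem` (", nrow(chem), " vertices) and `gap` (", nrow(gap),
         " vertices) must share dimension")
  }
  if (any(chem < 0) || any(gap < 0)) {
    stop("adjacency entries must be nonnegative connection counts")
  }
  if (!isSymmetric(unname(gap))) {
    stop("`gap` must be symmetric (gap junctions are bidirectional)")
  }
  n <- nrow(chem)
  if (is.null(labels)) {
    labels <- rownames(chem)
    if (is.null(labels)) labels <- rownames(gap)
    if (is.null(labels)) labels <- as.character(seq_len(n))
  }
  if (length(labels) != n) stop("`labels` must have length ", n)
  combined <- chem + t(chem) + gap
  diag(combined) <- 0
  adj <- (combined > 0) * 1L
  dimnames(adj) <- list(labels, labels)
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

#' Extract the giant (largest connected) component
#'
#' Returns the induced subgraph on the largest connected component, with
#' vertex labels preserved. When several components tie in size the one
#' containing the smallest vertex label is kept, so the result is
#' deterministic.
#'
#' @param g An undirected `igraph`.
#' @return The induced subgraph on the giant component.
#' @export
giant_component <- function(g) {
  g <- ensure_names(g)
  check_graph(g)
  if (igraph::vcount(g) == 0L) stop("cannot take the giant component of an empty graph")
  comp <- igraph::components(g)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    # tie: pick the component holding the smallest vertex label
    min_label <- vapply(best, function(k) {
      min(igraph::V(g)$name[comp$membership == k])
    }, character(1))
    best <- best[order(min_label)][1L]
  }
  igraph::induced_subgraph(g, which(comp$membership == best))
}

#' Vertex degrees
#'
#' @param g An undirected `igraph`.
#' @return A tibble with columns `vertex` and `degree`.
#' @export
degrees <- function(g) {
  g <- ensure_names(g)
  check_graph(g)
  tibble::tibble(vertex = igraph::V(g)$name, degree = igraph::degree(g))
}

#' Graph Laplacian L = D - A
#'
#' Builds the combinatorial Laplacian of a simple undirected graph: the
#' diagonal carries vertex degrees, off-diagonal entries are -1 exactly on
#' edges. Rows sum to zero and the matrix is positive semi-definite.
#'
#' @param g An undirected simple `igraph`.
#' @return A dense symmetric numeric matrix with vertex labels as dimnames.
#' @examples
#' graph_laplacian(sierpinski_gasket(0)) # the triangle: 2 on the diagonal
#' @export
graph_laplacian <- function(g) {
  g <- ensure_names(g)
  check_graph(g)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  A <- (A > 0) * 1
  L <- diag(rowSums(A), nrow = nrow(A)) - A
  dimnames(L) <- list(igraph::V(g)$name, igraph::V(g)$name)
  L
}

#' Degree-normalized Laplacian
#'
#' Symmetric normalization `S = D^(-1/2) L D^(-1/2)`, whose eigenvalues lie
#' in \eqn{[0, 2]}. `S` is similar to the generalized problem
#' \eqn{L f = \lambda D f}: its eigenvectors `v` map back to generalized
#' eigenfunctions `f = D^(-1/2) v` on vertices, so the eigenfunction of
#' eigenvalue 0 becomes constant. The back-transform weights are attached as
#' attribute `inv_sqrt_degree`.
#'
#' @param g An undirected `igraph` in which every vertex has degree at least
#'   one (run [giant_component()] first if needed).
#' @return A dense symmetric matrix with attribute `inv_sqrt_degree`.
#' @export
normalized_laplacian <- function(g) {
  g <- ensure_names(g)
  check_graph(g)
  d <- igraph::degree(g)
  if (any(d == 0)) {
    stop("graph has isolated (degree-0) vertices; extract the giant ",
         "component with giant_component() before normalizing")
  }
  L <- graph_laplacian(g)
  inv_sqrt <- 1 / sqrt(d)
  S <- L * tcrossprod(inv_sqrt)
  S <- (S + t(S)) / 2 # exact symmetry against rounding
  attr(S, "inv_sqrt_degree") <- inv_sqrt
  S
}

# ---- internal validation ----------------------------------------------------

check_graph <- function(g) {
  if (!igraph::is_igraph(g)) stop("expected an igraph object")
  if (igraph::is_directed(g)) stop("expected an undirected graph")
  if (igraph::any_multiple(g)) stop("graph has duplicate edges; expected a simple graph")
  if (any(igraph::which_loop(g))) stop("graph has self-loops; expected a simple graph")
  invisible(TRUE)
}

# ensure a graph has name labels, returning the (possibly relabeled) graph
ensure_names <- function(g) {
  if (is.null(igraph::V(g)$name) && igraph::vcount(g) > 0L) {
    g <- igraph::set_vertex_attr(g, "name", value = as.character(seq_len(igraph::vcount(g))))
  }
  g
}
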