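#' Per-vertex and average clustering coefficients
#'
#' The clustering coefficient of a vertex is the probability that two of its
#' neighbors are themselves connected: `c_v = e_v / (k_v (k_v - 1) / 2)`,
#' where `e_v` counts edges among the neighbors and `k_v` is the degree.
#' Vertices of degree 0 or 1 have no neighbor pair and are assigned
#' `c_v = 0`; they are included in the average, which matters for sparse
#' random controls.
#'
#' @param g An undirected simple `igraph`.
#' @return Tibble with columns `vertex`, `degree`, `neighbor_edges`,
#'   `clustering`.
#' @seealso [average_clustering()]
#' @export
clustering_stats <- function(g) {
  g <- ensure_names(g)
  check_graph(g)
  k <- igraph::degree(g)
  e_v <- igraph::count_triangles(g)
  c_v <- ifelse(k < 2, 0, e_v / (k * (k - 1) / 2))
  tibble::tibble(vertex = igraph::V(g)$name, degree = unname(k),
                 neighbor_edges = unname(e_v), clustering = unname(c_v))
}

#' Average clustering coefficient
#'
#' Mean of the per-vertex clustering coefficients over all vertices
#' (degree < 2 vertices contributing 0).
#'
#' @inheritParams clustering_stats
#' @return A single number in \eqn{[0, 1]}.
#' @examples
#' average_clustering(sierpinski_gasket(0)) # triangle: 1
#' @export
average_clustering <- function(g) {
  mean(clustering_stats(g)$clustering)
}

#' All-pairs shortest paths and average path length
#'
#' Breadth-first search from every vertex (Dijkstra's algorithm on unit
#' weights) yields the matrix of shortest hop counts. The average path
#' length is the arithmetic mean over unordered pairs of distinct vertices;
#' on disconnected graphs unreachable pairs are excluded and counted.
#'
#' @param g An undirected simple `igraph`.
#' @return An object of class `path_stats`: list with `distances` (matrix),
#'   `mean_path_length`, `diameter` (largest finite distance),
#'   `n_unreachable_pairs`, `n`.
#' @examples
#' path_stats(sierpinski_gasket(0))$mean_path_length # triangle: 1
#' @export
path_stats <- function(g) {
  g <- ensure_names(g)
  check_graph(g)
  d <- igraph::distances(g, algorithm = "unweighted")
  ut <- d[upper.tri(d)]
  finite <- is.finite(ut)
  structure(
    list(distances = d,
         mean_path_length = mean(ut[finite]),
         diameter = if (any(finite)) max(ut[finite]) else NA_real_,
         n_unreachable_pairs = sum(!finite),
         n = nrow(d)),
    class = "path_stats"
  )
}

#' @exportS3Method
print.path_stats <- function(x, ...) {
  cat("<path_stats> n =", x$n,
      " mean path length =", format(x$mean_path_length, digits = 6),
      " diameter =", x$diameter, "\n")
  if (x$n_unreachable_pairs > 0) {
    cat("  ", x$n_unreachable_pairs, "unreachable pairs excluded\n")
  }
  invisible(x)
}

#' @describeIn path_stats glance(): one-row tibble of the summary numbers.
#' @param x A `path_stats` object.
#' @param ... Unused.
#' @export
glance.path_stats <- function(x, ...) {
  tibble::tibble(n = x$n, mean_path_length = x$mean_path_length,
                 diameter = x$diameter,
                 n_unreachable_pairs = x$n_unreachable_pairs)
}

#' Small-world comparison against matched random graphs
#'
#' Computes average clustering and path length for `g` and for matched
#' Erdos-Renyi controls (same n, same edge density; one per seed), and
#' reports the ratios. Following Watts and Strogatz, a network is read as
#' small-world when its clustering is much higher than the random control's
#' while its average path length stays comparable; the verdict fields apply
#' the heuristic thresholds `clustering_ratio > 2` and
#' `path_length_ratio < 2`.
#'
#' Disconnected random realizations have their statistics computed on the
#' full vertex set for clustering (degree < 2 vertices contribute 0) and on
#' reachable pairs for path length, and are flagged in the per-seed table.
#'
#' @param g A connected undirected simple `igraph` (take the
#'   [giant_component()] first if needed).
#' @param seeds Integer vector of seeds, one matched random graph per seed.
#' @return An object of class `small_world_report`: list with `graph`
#'   (one-row tibble for `g`), `random` (per-seed tibble), `summary`
#'   (one-row tibble with means, ratios, matched p and verdicts).
#' @export
small_world_report <- function(g, seeds = 1:20) {
  g <- ensure_names(g)
  check_graph(g)
  if (!igraph::is_connected(g)) {
    stop("`g` is disconnected; analyze its giant_component() instead")
  }
  n <- igraph::vcount(g)
  p_matched <- igraph::ecount(g) / (n * (n - 1) / 2)
  c_g <- average_clustering(g)
  l_g <- path_stats(g)$mean_path_length
  graph_row <- tibble::tibble(n = n, edges = igraph::ecount(g),
                              clustering = c_g, mean_path_length = l_g)
  random <- purrr::map_dfr(seeds, function(s) {
    r <- matched_random(g, seed = s)
    ps <- path_stats(r)
    tibble::tibble(
      seed = s,
      clustering = average_clustering(r),
      mean_path_length = ps$mean_path_length,
      connected = ps$n_unreachable_pairs == 0
    )
  })
  c_r <- mean(random$clustering)
  l_r <- mean(random$mean_path_length)
  summary <- tibble::tibble(
    matched_p = p_matched,
    clustering = c_g, clustering_random = c_r,
    clustering_ratio = c_g / c_r,
    mean_path_length = l_g, mean_path_length_random = l_r,
    path_length_ratio = l_g / l_r,
    n_seeds = length(seeds),
    clustering_elevated = c_g / c_r > 2,
    path_length_comparable = l_g / l_r < 2,
    small_world = c_g / c_r > 2 & l_g / l_r < 2
  )
  structure(list(graph = graph_row, random = random, summary = summary),
            class = "small_world_report")
}

#' @exportS3Method
print.small_world_report <- function(x, ...) {
  s <- x$summary
  cat("<small_world_report> n =", x$graph$n, " |E| =", x$graph$edges,
      " matched p =", format(s$matched_p, digits = 4), "\n")
  cat(sprintf("  clustering      %.4f vs random %.4f  (ratio %.2f)\n",
              s$clustering, s$clustering_random, s$clustering_ratio))
  cat(sprintf("  path length     %.4f vs random %.4f  (ratio %.2f)\n",
              s$mean_path_length, s$mean_path_length_random, s$path_length_ratio))
  cat("  small-world:", if (s$small_world) "yes" else "no", "\n")
  invisible(x)
}

#' @describeIn small_world_report tidy(): the per-seed random-control table.
#' @param x A `small_world_report`.
#' @param ... Unused.
#' @export
tidy.small_world_report <- function(x, ...) x$random

#' @describeIn small_world_report glance(): the one-row summary tibble.
#' @export
glance.small_world_report <- function(x, ...) x$summary
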