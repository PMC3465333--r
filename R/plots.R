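#' Plot an eigenvalue counting curve
#'
#' Step plot of N(x) against x; fractal graph approximations show wide flat
#' steps (spectral gaps).
#'
#' @param spectrum A `graph_spectrum`.
#' @param log_x Logarithmic x axis (default `FALSE`).
#' @return A ggplot object.
#' @export
plot_counting_curve <- function(spectrum, log_x = FALSE) {
  dat <- counting_curve(spectrum)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$eigenvalue, y = .data$count)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "eigenvalue x", y = "N(x)",
                  title = "Eigenvalue counting function")
  if (log_x) p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot a Weyl ratio curve
#'
#' W(x) = N(x)/x^alpha on a logarithmic x axis; log-periodic oscillation is
#' the self-similarity signature.
#'
#' @param weyl Tibble from [weyl_curve()].
#' @return A ggplot object.
#' @export
plot_weyl_curve <- function(weyl) {
  ggplot2::ggplot(weyl, ggplot2::aes(x = .data$x, y = .data$weyl)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "x (log scale)", y = expression(N(x) / x^alpha),
                  title = "Weyl ratio")
}

#' Plot eigen-projection coordinates
#'
#' Draws the graph in eigenfunction coordinates: vertices at
#' `(f_i(v), f_j(v))` with edges as segments, optionally colored by a
#' vertex category (e.g. neuron type).
#'
#' @param g The graph that was projected.
#' @param projection Tibble from [eigen_projection()] on `g` (2-D); built
#'   with defaults when omitted.
#' @return A ggplot object.
#' @export
plot_eigen_projection <- function(g, projection = eigen_projection(g)) {
  coord_cols <- grep("^f[0-9]+$", names(projection), value = TRUE)[1:2]
  el <- igraph::as_edgelist(ensure_names(g), names = TRUE)
  idx <- match(el, projection$vertex)
  seg <- data.frame(
    x = projection[[coord_cols[1]]][idx[seq_len(nrow(el))]],
    y = projection[[coord_cols[2]]][idx[seq_len(nrow(el))]],
    xend = projection[[coord_cols[1]]][idx[nrow(el) + seq_len(nrow(el))]],
    yend = projection[[coord_cols[2]]][idx[nrow(el) + seq_len(nrow(el))]]
  )
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      linewidth = 0.2, alpha = 0.4
    )
  if ("category" %in% names(projection)) {
    p <- p + ggplot2::geom_point(
      data = projection,
      ggplot2::aes(x = .data[[coord_cols[1]]], y = .data[[coord_cols[2]]],
                   color = .data$category), size = 1)
  } else {
    p <- p + ggplot2::geom_point(
      data = projection,
      ggplot2::aes(x = .data[[coord_cols[1]]], y = .data[[coord_cols[2]]]),
      size = 1)
  }
  p + ggplot2::labs(x = coord_cols[1], y = coord_cols[2],
                    title = "Eigen-projection")
}

#' Plot a spacial-variance distribution
#'
#' Histogram of per-eigenfunction spacial variances (log10 x axis);
#' localization shows up as mass at low variance.
#'
#' @param localization Tibble from [variance_distribution()].
#' @param bins Histogram bin count (default 30).
#' @return A ggplot object.
#' @export
plot_variance_distribution <- function(localization, bins = 30) {
  ggplot2::ggplot(localization, ggplot2::aes(x = .data$variance)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "spacial variance (log scale)", y = "eigenfunctions",
                  title = "Eigenfunction localization profile")
}
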