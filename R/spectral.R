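#' Eigendecomposition of a graph Laplacian
#'
#' Full dense symmetric eigendecomposition, eigenvalues in ascending order,
#' with a deterministic sign convention: each eigenvector is flipped so that
#' its largest-magnitude entry is positive (first index on ties). For the
#' degree-normalized Laplacian the generalized eigenfunctions
#' `f = D^(-1/2) v` are also stored, so the eigenfunction of eigenvalue 0 is
#' constant on vertices.
#'
#' @param x An undirected `igraph`, or a symmetric Laplacian matrix as built
#'   by [graph_laplacian()] / [normalized_laplacian()].
#' @param normalized When `x` is a graph: use the degree-normalized
#'   Laplacian (default `FALSE`).
#' @return An object of class `graph_spectrum`: a list with `values`
#'   (ascending eigenvalues), `vectors` (orthonormal eigenvectors in
#'   columns), `functions` (vertex eigenfunctions; equals `vectors` for the
#'   un-normalized Laplacian, `D^(-1/2) vectors` for the normalized one),
#'   `source` (`"laplacian"` or `"normalized"`), `labels`, `n`.
#' @examples
#' s <- graph_spectrum(sierpinski_gasket(0)) # triangle: eigenvalues 0, 3, 3
#' round(s$values, 10)
#' @export
graph_spectrum <- function(x, normalized = FALSE) {
  if (igraph::is_igraph(x)) {
    m <- if (normalized) normalized_laplacian(x) else graph_laplacian(x)
  } else {
    m <- as.matrix(x)
    if (nrow(m) != ncol(m) || !isSymmetric(unname(m), tol = 1e-10)) {
      stop("expected a symmetric square matrix or an igraph object")
    }
    normalized <- !is.null(attr(m, "inv_sqrt_degree"))
  }
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(m)))
  eig <- eigen((m + t(m)) / 2, symmetric = TRUE)
  ord <- seq(ncol(eig$vectors), 1) # eigen() returns descending order
  values <- eig$values[ord]
  vectors <- eig$vectors[, ord, drop = FALSE]
  vectors <- fix_signs(vectors)
  functions <- vectors
  inv_sqrt <- attr(m, "inv_sqrt_degree")
  if (normalized && !is.null(inv_sqrt)) {
    functions <- vectors * inv_sqrt
  }
  rownames(vectors) <- rownames(functions) <- labels
  structure(
    list(values = values, vectors = vectors, functions = functions,
         source = if (normalized) "normalized" else "laplacian",
         labels = labels, n = length(values)),
    class = "graph_spectrum"
  )
}

# deterministic sign: largest-|entry| positive, first index on ties
fix_signs <- function(vectors) {
  for (j in seq_len(ncol(vectors))) {
    v <- vectors[, j]
    if (v[which.max(abs(v))] < 0) vectors[, j] <- -v
  }
  vectors
}

#' @exportS3Method
print.graph_spectrum <- function(x, ...) {
  cat("<graph_spectrum> ", x$n, " eigenvalues of the ",
      if (x$source == "normalized") "degree-normalized " else "",
      "Laplacian\n", sep = "")
  cat("  range [", format(min(x$values)), ", ", format(max(x$values)), "]\n", sep = "")
  invisible(x)
}

#' @describeIn graph_spectrum tibble of `index`, `eigenvalue`.
#' @param ... Unused.
#' @export
tidy.graph_spectrum <- function(x, ...) {
  tibble::tibble(index = seq_len(x$n), eigenvalue = x$values)
}

#' @describeIn graph_spectrum one-row summary (n, source, extreme
#'   eigenvalues, multiplicity of 0).
#' @export
glance.graph_spectrum <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    source = x$source,
    lambda_min = min(x$values),
    lambda_max = max(x$values),
    n_zero = sum(abs(x$values) <= .SPECTRAL_TOL)
  )
}

#' Eigenvalue counting function N(x)
#'
#' `N(x)` is the number of eigenvalues less than or equal to `x` -- a
#' right-continuous cumulative frequency function on the spectrum. A tie
#' tolerance of 1e-9 absorbs floating-point noise in computed eigenvalues.
#'
#' @param spectrum A `graph_spectrum`.
#' @param x Numeric vector of evaluation points.
#' @return Integer vector, `N(x)` per evaluation point.
#' @examples
#' s <- graph_spectrum(sierpinski_gasket(0))
#' counting_function(s, c(2, 3)) # 1, 3
#' @export
counting_function <- function(spectrum, x) {
  stopifnot(inherits(spectrum, "graph_spectrum"))
  vapply(x, function(xx) sum(spectrum$values <= xx + .SPECTRAL_TOL), integer(1))
}

#' Counting curve as a step-function table
#'
#' One row per eigenvalue with the value of N there; plotted with
#' [ggplot2::geom_step()] this is the eigenvalue counting function.
#'
#' @param spectrum A `graph_spectrum`.
#' @return A tibble with columns `eigenvalue` and `count`.
#' @export
counting_curve <- function(spectrum) {
  stopifnot(inherits(spectrum, "graph_spectrum"))
  tibble::tibble(
    eigenvalue = spectrum$values,
    count = counting_function(spectrum, spectrum$values)
  )
}

#' Detect spectral gaps in the counting function
#'
#' A spectral gap is a flat step of the counting function: an interval free
#' of eigenvalues. Fractal graph approximations show wide flat steps, while
#' comparable random graphs do not. A step counts as a gap when it lies in
#' the interior of the spectrum (by index) and its width exceeds
#' `min_rel_width` times the spectral range; the interior restriction keeps
#' edge effects (the trivial gap below the spectral bulk, outlier top
#' eigenvalues) out of the report.
#'
#' @param spectrum A `graph_spectrum`.
#' @param min_rel_width Minimum gap width as a fraction of the spectral
#'   range (default 0.025).
#' @param interior Index quantile band searched for gaps (default the
#'   central 90 percent, `c(0.05, 0.95)`).
#' @return Tibble with columns `lower`, `upper`, `width` (one row per gap).
#' @export
spectral_gaps <- function(spectrum, min_rel_width = 0.025, interior = c(0.05, 0.95)) {
  stopifnot(inherits(spectrum, "graph_spectrum"))
  ev <- spectrum$values
  n <- length(ev)
  rng <- ev[n] - ev[1]
  if (n < 3 || rng <= 0) {
    return(tibble::tibble(lower = numeric(0), upper = numeric(0), width = numeric(0)))
  }
  lo <- max(1L, ceiling(interior[1] * n))
  hi <- min(n - 1L, floor(interior[2] * n))
  idx <- seq.int(lo, hi)
  width <- ev[idx + 1L] - ev[idx]
  keep <- width > min_rel_width * rng
  tibble::tibble(lower = ev[idx[keep]], upper = ev[idx[keep] + 1L],
                 width = width[keep])
}

#' Fit the power-law growth exponent of the counting function
#'
#' The counting function of many graph families grows approximately as a
#' power law, \eqn{N(x) \approx const \cdot x^\alpha}; on logarithmic axes
#' the relevant portion appears linear. This fits ordinary least squares of
#' \eqn{\log N(\lambda_i)} on \eqn{\log \lambda_i} over an index interval
#' and returns the slope as the exponent.
#'
#' @param spectrum A `graph_spectrum`.
#' @param interval Integer index range (into the ascending eigenvalues) used
#'   for the fit. Default: indices from `ceiling(0.05 n)` to
#'   `floor(0.95 n)`, keeping the fit off both spectral edges. Zero
#'   eigenvalues inside the interval are excluded with a warning.
#' @return An object of class `alpha_fit` with fields `alpha` (slope),
#'   `intercept`, `r_squared`, `interval`, `n_points`, and `data` (the
#'   fitted log-log table).
#' @examples
#' # exact power law N(x) = n x^(1/2): eigenvalues (i/n)^2
#' s <- structure(list(values = (seq_len(200) / 200)^2, n = 200,
#'                     source = "laplacian"), class = "graph_spectrum")
#' fit_alpha(s)$alpha # 0.5
#' @export
fit_alpha <- function(spectrum, interval = NULL) {
  stopifnot(inherits(spectrum, "graph_spectrum"))
  n <- spectrum$n
  if (is.null(interval)) {
    interval <- seq.int(max(1L, ceiling(0.05 * n)), max(1L, floor(0.95 * n)))
  } else {
    interval <- seq.int(min(interval), max(interval))
    if (min(interval) < 1 || max(interval) > n) stop("`interval` out of range 1..", n)
  }
  lambda <- spectrum$values[interval]
  zero <- lambda <= .SPECTRAL_TOL
  if (any(zero)) {
    warning("excluding ", sum(zero), " zero eigenvalue(s) from the log-log fit")
    interval <- interval[!zero]
    lambda <- lambda[!zero]
  }
  if (length(unique(signif(lambda, 12))) < 3) {
    stop("need at least 3 distinct positive eigenvalues in the fit interval")
  }
  counts <- counting_function(spectrum, lambda)
  dat <- tibble::tibble(
    index = interval, eigenvalue = lambda, count = counts,
    log_lambda = log(lambda), log_count = log(counts)
  )
  fit <- stats::lm(log_count ~ log_lambda, data = dat)
  resid <- stats::residuals(fit)
  sst <- sum((dat$log_count - mean(dat$log_count))^2)
  r2 <- if (sst > 0) 1 - sum(resid^2) / sst else 1
  structure(
    list(alpha = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = r2, interval = range(interval), n_points = nrow(dat),
         data = dat),
    class = "alpha_fit"
  )
}

#' @exportS3Method
print.alpha_fit <- function(x, ...) {
  cat("<alpha_fit> N(x) ~ x^alpha, alpha =", format(x$alpha, digits = 6),
      " (r^2 =", format(x$r_squared, digits = 4), ")\n")
  cat("  fitted on eigenvalue indices", x$interval[1], "..", x$interval[2],
      "(", x$n_points, "points )\n")
  invisible(x)
}

#' @describeIn fit_alpha tidy(): one row per fitted point
#'   (index, eigenvalue, count and their logs).
#' @param x An `alpha_fit`.
#' @param ... Unused.
#' @export
tidy.alpha_fit <- function(x, ...) x$data

#' @describeIn fit_alpha glance(): one-row summary with `alpha`,
#'   `intercept`, `r_squared`, `n_points`.
#' @export
glance.alpha_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, intercept = x$intercept,
                 r_squared = x$r_squared, n_points = x$n_points)
}

#' Weyl ratio curve W(x) = N(x) / x^alpha
#'
#' Divides the counting function by its fitted power-law growth; for exactly
#' power-law spectra the ratio is constant, while log-periodic oscillation
#' of W against log x is a signature of self-similarity.
#'
#' @param spectrum A `graph_spectrum`.
#' @param fit An `alpha_fit` (or a bare positive number used as the
#'   exponent).
#' @param grid_points Number of log-spaced sample points between the first
#'   positive eigenvalue and the largest one (default 200). Zero is never
#'   sampled.
#' @return Tibble with columns `x`, `count`, `weyl`.
#' @export
weyl_curve <- function(spectrum, fit = fit_alpha(spectrum), grid_points = 200) {
  stopifnot(inherits(spectrum, "graph_spectrum"))
  alpha <- if (inherits(fit, "alpha_fit")) fit$alpha else as.numeric(fit)
  if (!is.finite(alpha) || alpha <= 0) stop("`alpha` must be positive")
  pos <- spectrum$values[spectrum$values > .SPECTRAL_TOL]
  if (length(pos) < 2) stop("spectrum has fewer than 2 positive eigenvalues")
  grid <- exp(seq(log(min(pos)), log(max(pos)), length.out = grid_points))
  counts <- counting_function(spectrum, grid)
  tibble::tibble(x = grid, count = counts, weyl = counts / grid^alpha)
}

#' Eigen-projection coordinates ("plotting in eigenfunction coordinates")
#'
#' Embeds vertices in 2- or 3-dimensional space using eigenfunctions of the
#' degree-normalized Laplacian as a coordinate basis: vertex v is placed at
#' `(f_i(v), f_j(v)[, f_k(v)])`. The first eigenfunction is constant
#' (eigenvalue 0) and carries no information, so only indices >= 2 are
#' allowed; defaults are `(2, 3)` for 2-D, pass `(2, 3, 4)` for 3-D.
#'
#' @param g A connected undirected `igraph` (run [giant_component()] on
#'   disconnected input first).
#' @param indices Two or three eigenfunction indices, all >= 2.
#' @param categories Optional per-vertex category tags (named character
#'   vector or vector in vertex order) carried through for color-coding.
#' @param normalized Use the degree-normalized Laplacian (default `TRUE`,
#'   as in spectral graph drawing).
#' @return Tibble with columns `vertex`, one coordinate column per index
#'   (`f2`, `f3`, ...), and optionally `category`.
#' @export
eigen_projection <- function(g, indices = c(2, 3), categories = NULL,
                             normalized = TRUE) {
  g <- ensure_names(g)
  check_graph(g)
  if (!igraph::is_connected(g)) {
    stop("graph is disconnected; extract the giant component with ",
         "giant_component() before projecting")
  }
  if (!length(indices) %in% c(2L, 3L)) stop("`indices` must have length 2 or 3")
  if (any(indices < 2)) {
    stop("eigenfunction 1 is constant; projection indices must be >= 2")
  }
  if (any(indices > igraph::vcount(g))) stop("`indices` out of range")
  s <- graph_spectrum(g, normalized = normalized)
  coords <- s$functions[, indices, drop = FALSE]
  out <- tibble::as_tibble(coords, .name_repair = ~ paste0("f", indices))
  out <- tibble::add_column(out, vertex = s$labels, .before = 1)
  if (!is.null(categories)) {
    if (!is.null(names(categories))) {
      out$category <- unname(categories[out$vertex])
    } else {
      if (length(categories) != nrow(out)) {
        stop("`categories` must be named or have one entry per vertex")
      }
      out$category <- categories
    }
  }
  out
}
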