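test_that("spectra of small benchmark graphs are exact", {
  # triangle: {0, 3, 3}
  expect_equal(graph_spectrum(sierpinski_gasket(0))$values, c(0, 3, 3),
               tolerance = 1e-10)
  # star on 4 vertices: {0, 1, 1, 4}
  star <- igraph::make_star(4, mode = "undirected")
  expect_equal(graph_spectrum(star)$values, c(0, 1, 1, 4), tolerance = 1e-10)
  # two disjoint triangles: eigenvalue 0 with multiplicity 2
  two_tri <- igraph::disjoint_union(igraph::make_ring(3), igraph::make_ring(3))
  ev <- graph_spectrum(two_tri)$values
  expect_equal(sum(abs(ev) < 1e-9), 2)
})

test_that("spectrum rejects asymmetric matrices and returns orthonormal vectors", {
  expect_error(graph_spectrum(matrix(c(1, 2, 0, 1), 2, 2)), "symmetric")
  s <- graph_spectrum(random_connected_graph(25, 0.2, seed = 3))
  G <- crossprod(s$vectors)
  expect_lt(max(abs(G - diag(s$n))), 1e-8)
  expect_true(all(diff(s$values) >= -1e-12))
})

test_that("counting function matches hand values and ends at n", {
  s3 <- graph_spectrum(sierpinski_gasket(0))
  expect_equal(counting_function(s3, 2), 1L)
  expect_equal(counting_function(s3, 3), 3L)
  star <- graph_spectrum(igraph::make_star(4, mode = "undirected"))
  expect_equal(counting_function(star, 1), 3L)
  g <- random_gnp(40, 0.2, seed = 5)
  s <- graph_spectrum(g)
  expect_equal(counting_function(s, max(s$values)), 40L)
  expect_equal(counting_function(s, -1), 0L)
  cc <- counting_curve(s)
  expect_equal(max(cc$count), 40L)
  expect_true(all(diff(cc$count) >= 0))
})

test_that("alpha fit recovers exact power-law exponents to 1e-6", {
  n <- 400
  for (alpha_true in c(0.5, 1, 1.7)) {
    values <- (seq_len(n) / n)^(1 / alpha_true) # N(x) = n * x^alpha
    s <- structure(list(values = values, n = n, source = "laplacian"),
                   class = "graph_spectrum")
    fit <- fit_alpha(s)
    expect_equal(fit$alpha, alpha_true, tolerance = 1e-6)
    expect_gt(fit$r_squared, 1 - 1e-10)
  }
})

test_that("alpha of a long path is the 1-D Weyl exponent 1/2", {
  # lambda_k = 2 - 2 cos(pi k / n) ~ (pi k / n)^2 for small k => N(x) ~ x^(1/2)
  path <- random_tree(100, 1, seed = 1)
  s <- graph_spectrum(path)
  fit <- fit_alpha(s, interval = c(10, 90)) # middle 80%
  expect_lt(abs(fit$alpha - 0.5), 0.1)
})

test_that("alpha fit rejects degenerate intervals and warns on zeros", {
  path6 <- graph_spectrum(random_tree(6, 1, seed = 1))
  expect_warning(fit_alpha(path6, interval = c(1, 6)), "zero eigenvalue")
  s <- graph_spectrum(sierpinski_gasket(0))
  expect_error(suppressWarnings(fit_alpha(s, interval = c(1, 3))), "distinct")
})

test_that("Weyl ratio is constant for exact power laws and piecewise decreasing", {
  n <- 300
  s <- structure(list(values = (seq_len(n) / n)^2, n = n, source = "laplacian"),
                 class = "graph_spectrum")
  fit <- fit_alpha(s)
  # evaluated on the spectrum itself, W(lambda_i) = i / lambda_i^alpha = n
  w_at_ev <- counting_function(s, s$values) / s$values^fit$alpha
  expect_true(all(abs(w_at_ev - n) < n * 1e-6))

  # between eigenvalue jumps W(x) = N/x^alpha strictly decreases
  g <- random_connected_graph(30, 0.2, seed = 2)
  sg <- graph_spectrum(g)
  w2 <- weyl_curve(sg, 1, grid_points = 500)
  same_step <- diff(w2$count) == 0
  expect_true(all(diff(w2$weyl)[same_step] < 0))
  expect_true(all(w2$weyl > 0))
})

test_that("gasket counting curve has spectral gaps, matched G(n,p) does not", {
  gasket <- sierpinski_gasket(5)
  s_gasket <- graph_spectrum(gasket)
  expect_gt(nrow(spectral_gaps(s_gasket)), 0)
  for (seed in c(1, 2, 3)) {
    rnd <- matched_random(gasket, seed = seed)
    expect_equal(nrow(spectral_gaps(graph_spectrum(rnd))), 0)
  }
})

test_that("eigen-projection coordinates behave as the symmetry dictates", {
  # path on 3 vertices: f2 antisymmetric about the middle vertex
  path <- random_tree(3, 1, seed = 1)
  pr <- eigen_projection(path, indices = c(2, 3))
  expect_equal(pr$f2[1], -pr$f2[3], tolerance = 1e-8)

  # D-orthogonality of non-constant eigenfunctions to constants
  g <- random_connected_graph(40, 0.15, seed = 9)
  s <- graph_spectrum(g, normalized = TRUE)
  d <- igraph::degree(g)
  for (i in 2:5) {
    expect_lt(abs(sum(s$functions[, i] * d * s$functions[, 1])), 1e-8)
  }

  # C6 is vertex-transitive: projected points lie on a circle
  cyc <- igraph::make_ring(6)
  prc <- eigen_projection(cyc, indices = c(2, 3))
  radii <- sqrt(prc$f2^2 + prc$f3^2)
  expect_lt(diff(range(radii)), 1e-8)
})

test_that("eigen-projection validates input and carries categories", {
  two <- igraph::disjoint_union(igraph::make_ring(3), igraph::make_ring(3))
  expect_error(eigen_projection(two), "giant_component")
  expect_error(eigen_projection(sierpinski_gasket(1), indices = c(1, 2)), ">= 2")

  g <- sierpinski_gasket(1)
  cats <- setNames(rep(c("corner", "mid"), 3), igraph::V(g)$name)
  pr <- eigen_projection(g, categories = cats)
  expect_equal(pr$category, unname(cats[pr$vertex]))
})

test_that("two runs produce bit-identical spectra and coordinates", {
  g <- sierpinski_gasket(3)
  s1 <- graph_spectrum(g)
  s2 <- graph_spectrum(g)
  expect_identical(s1$values, s2$values)
  expect_identical(s1$vectors, s2$vectors)
  p1 <- eigen_projection(g)
  p2 <- eigen_projection(g)
  expect_identical(p1, p2)
})
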