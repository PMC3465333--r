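test_that("graph energy: constants, single edge, quadratic-form identity", {
  tri <- sierpinski_gasket(0)
  expect_equal(graph_energy(tri, rep(5, 3)), 0)

  edge <- igraph::graph_from_edgelist(rbind(c("u", "v")), directed = FALSE)
  expect_equal(graph_energy(edge, c(1, 0)), 1)

  g <- random_connected_graph(30, 0.15, seed = 6)
  f <- rnorm(igraph::vcount(g))
  L <- graph_laplacian(g)
  expect_equal(graph_energy(g, f), drop(t(f) %*% L %*% f), tolerance = 1e-10)
  expect_error(graph_energy(g, f[-1]), "length")
})

test_that("unit eigenfunctions have energy equal to their eigenvalue", {
  g <- random_connected_graph(40, 0.15, seed = 8)
  s <- graph_spectrum(g)
  for (i in seq_len(s$n)) {
    expect_equal(graph_energy(g, s$vectors[, i]), s$values[i], tolerance = 1e-8)
  }
})

test_that("effective resistance: series, parallel, component error", {
  path5 <- random_tree(5, 1, seed = 1)
  expect_equal(effective_resistance(path5, "1", "5"), 4, tolerance = 1e-10)

  edge <- igraph::graph_from_edgelist(rbind(c("u", "v")), directed = FALSE)
  expect_equal(effective_resistance(edge, "u", "v"), 1, tolerance = 1e-12)

  tri <- sierpinski_gasket(0)
  expect_equal(effective_resistance(tri, "1", "2"), 2 / 3, tolerance = 1e-10)

  two <- igraph::disjoint_union(igraph::make_ring(3), igraph::make_ring(3))
  two <- igraph::set_vertex_attr(two, "name", value = as.character(1:6))
  expect_error(effective_resistance(two, "1", "4"), "components")
})

test_that("harmonic functions are harmonic off the boundary pair", {
  g <- random_connected_graph(25, 0.2, seed = 12)
  nm <- igraph::V(g)$name
  h <- harmonic_function(g, nm[1], nm[10])
  L <- graph_laplacian(g)
  residual <- L %*% h
  interior <- setdiff(seq_along(nm), c(1, 10))
  expect_lt(max(abs(residual[interior])), 1e-9)
  expect_equal(residual[1], 1, tolerance = 1e-9)
  expect_equal(residual[10], -1, tolerance = 1e-9)
})

test_that("pairwise solves agree with the pseudoinverse oracle and matrix", {
  for (s in 1:30) {
    g <- random_connected_graph(18, 0.25, seed = 200 + s)
    n <- igraph::vcount(g)
    R <- resistance_matrix(g)
    iu <- 1 + (s %% (n - 1))
    iv <- n
    nm <- igraph::V(g)$name
    r_solve <- effective_resistance(g, nm[iu], nm[iv])
    r_oracle <- oracle_resistance(g, iu, iv)
    expect_equal(r_solve, r_oracle, tolerance = 1e-8)
    expect_equal(R[iu, iv], r_oracle, tolerance = 1e-8)
  }
})

test_that("resistance is a metric bounded by hop distance", {
  g <- random_connected_graph(35, 0.15, seed = 21)
  R <- resistance_matrix(g)
  d <- path_stats(g)$distances
  expect_equal(R, t(R))
  expect_true(all(diag(R) == 0))
  expect_true(all(R <= d + 1e-9))
  n <- nrow(R)
  for (k in seq_len(n)) {
    expect_true(all(R <= outer(R[, k], R[k, ], "+") + 1e-9))
  }
})

test_that("grounding choice does not change the resistance", {
  # harmonic solve grounds an arbitrary vertex; compare against the
  # pseudoinverse route on graphs where the ground lands differently
  g <- random_connected_graph(12, 0.3, seed = 31)
  nm <- igraph::V(g)$name
  R <- resistance_matrix(g)
  for (iu in 1:3) {
    for (iv in (iu + 1):5) {
      expect_equal(effective_resistance(g, nm[iu], nm[iv]), R[iu, iv],
                   tolerance = 1e-9)
    }
  }
})

test_that("spacial variance: indicators, symmetry, sign and relabel invariance", {
  tri <- sierpinski_gasket(0)
  R <- resistance_matrix(tri)
  # indicator of one vertex: zero variance, centered there
  sv <- spacial_variance(tri, c(1, 0, 0), R = R)
  expect_equal(sv$variance, 0)
  expect_equal(sv$center, "1")

  # vertex-transitive C6 with constant |f|: every center scores the same
  cyc <- igraph::make_ring(6)
  f <- rep(1 / sqrt(6), 6)
  Rc <- resistance_matrix(cyc)
  scores <- (Rc %*% f^2)[, 1]
  expect_lt(diff(range(scores)), 1e-10)

  # sign flip of f leaves the variance unchanged
  g <- random_connected_graph(20, 0.25, seed = 41)
  Rg <- resistance_matrix(g)
  s <- graph_spectrum(g)
  f2 <- s$vectors[, 2]
  v_plus <- spacial_variance(g, f2, R = Rg)
  v_minus <- spacial_variance(g, -f2, R = Rg)
  expect_equal(v_plus$variance, v_minus$variance)

  # vertex relabeling permutes but does not change variances
  perm <- sample(igraph::vcount(g))
  gp <- igraph::permute(g, perm)
  fp <- numeric(length(f2))
  fp[perm] <- f2
  v_perm <- spacial_variance(gp, fp, R = resistance_matrix(gp))
  expect_equal(v_perm$variance, v_plus$variance, tolerance = 1e-9)
})

test_that("non-normalized functions are normalized with a message", {
  tri <- sierpinski_gasket(0)
  expect_message(sv <- spacial_variance(tri, c(2, 0, 0)), "normalizing")
  expect_equal(sv$variance, 0)
})

test_that("variance distribution: non-negative, deterministic, scale-aware", {
  # path on 50 vertices: only non-negativity and determinism are asserted
  path50 <- random_tree(50, 1, seed = 1)
  vd1 <- variance_distribution(path50)
  vd2 <- variance_distribution(path50)
  expect_identical(vd1, vd2)
  expect_true(all(vd1$variance >= 0))
  expect_equal(nrow(vd1), 49)

  # the variance is bounded by the largest resistance from the best center
  gasket <- sierpinski_gasket(3)
  vg <- variance_distribution(gasket)
  R <- resistance_matrix(gasket)
  expect_true(all(vg$variance <= min(apply(R, 2, max)) + 1e-9))
  expect_true(all(vg$variance >= 0))
})

test_that("variance distribution rows align with the spectrum", {
  g <- random_connected_graph(25, 0.2, seed = 51)
  vd <- variance_distribution(g)
  s <- graph_spectrum(g)
  expect_equal(vd$eigenvalue, s$values[vd$index])
  expect_equal(vd$energy, vd$eigenvalue, tolerance = 1e-8)
})
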