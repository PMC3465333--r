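# selfsim

Spectral self-similarity and small-world analysis of networks.

selfsim is an R toolbox for asking what kind of graph a network is:
fractal-like, random, tree-like, or small-world. It was built around the
analysis of the *C. elegans* connectome — 302 neurons whose chemical
synapses and gap junctions collapse, once direction and multiplicity are
discarded, into a simple undirected graph with a 279-neuron giant
component — but every instrument applies to any simple graph, and the
package generates its own comparison panel (Erdős–Rényi graphs, random
branching trees, Sierpinski gasket and hexacarpet pre-fractals, rewired
fractals, density-matched random controls) so the whole analysis runs
without any external data.

The instruments all derive from the graph Laplacian `L = D − A` and its
degree-normalized form `D^(−1/2) L D^(−1/2)`:

* **Eigenvalue counting function** `N(x) = #{i : λ_i ≤ x}` and its flat
  steps (**spectral gaps**), the signature of fractal spectra.
* **Weyl ratios** `W(x) = N(x)/x^α`, with `α` fitted by log–log least
  squares; log-periodic oscillation of `W` indicates self-similarity.
* **Eigen-projection**: drawing the graph with vertices at
  `(f_2(v), f_3(v))`, the low-order eigenfunctions of the normalized
  Laplacian.
* **Small-world statistics**: average clustering coefficient
  `c_v = e_v / C(k_v, 2)` and BFS average path length, compared against
  matched Erdős–Rényi controls (Watts–Strogatz criterion).
* **Eigenfunction localization**: graph energy `E(f) = f' L f`, effective
  resistance via harmonic functions / the Laplacian pseudoinverse, and the
  spacial variance `Var_c(f) = min_y Σ_x R(x,y)^c f(x)²` of each
  eigenfunction.

Graphs are `igraph` objects; analysis results are tibbles, and fitted
objects provide `tidy()` / `glance()` plus `plot_*()` helpers built on
ggplot2.

## Worked example

The level-5 Sierpinski gasket graph approximation — 366 vertices, 729
edges — is the package's canonical fractal control:

```r
library(selfsim)

g <- sierpinski_gasket(5) |> giant_component()
small_world_report(g, seeds = 1:25)
#> <small_world_report> n = 366  |E| = 729  matched p = 0.01091
#>   clustering      0.4495 vs random 0.0098  (ratio 45.85)
#>   path length     16.9244 vs random 4.3392  (ratio 3.90)
#>   small-world: no
```

The gasket clusters 46× more than its matched random graph but its paths
are ~4× longer: high clustering *without* short paths, so it is not
small-world (rewiring it with `rewire_edges()` makes it one). The
clustering value is exact — a degree-class census of the gasket gives
`164.5/366 = 0.4495`.

```r
s <- graph_spectrum(g)
fit_alpha(s)
#> <alpha_fit> N(x) ~ x^alpha, alpha = 0.941941  (r^2 = 0.9228 )
#>   fitted on eigenvalue indices 19 .. 347 ( 329 points )
spectral_gaps(s)
#> # A tibble: 9 × 3
#>   lower upper width
#>   <dbl> <dbl> <dbl>
#> 1 0.294 0.637 0.344
#> 2 0.697 0.878 0.180
#> 3 1.10  1.26  0.153
#> # ℹ 6 more rows
```

Nine interior spectral gaps — wide eigenvalue-free intervals — mark the
spectrum as fractal; a matched `G(366, 0.0109)` random graph reports none
(`spectral_gaps(graph_spectrum(matched_random(g, seed = 1)))` is empty).
`weyl_curve(s, fit_alpha(s))` and `plot_weyl_curve()` expose the
log-periodic structure, `eigen_projection(g)` the self-similar geometry,
and `variance_distribution(g)` the per-eigenfunction localization profile.

For connectome-style input, `assemble_connectome(chem, gap)` folds a
directed chemical-synapse count matrix and a symmetric gap-junction matrix
into the analysis graph, and `run_full_analysis()` chains every stage
(giant component → spectrum → counting/Weyl → projection → small-world →
localization) into one reproducible report.

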