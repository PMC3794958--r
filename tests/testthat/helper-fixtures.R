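# shared fixtures, memoised so expensive spectral bases are built once
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# regular tetrahedron, edge length 2
tetra_mesh <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  suppressMessages(
    triangle_mesh(v, rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))))
}

fix_template <- function(tag = "hippocampus_L", subdiv = 2, semi_axes = NULL) {
  cached(paste("tpl", tag, subdiv, paste(semi_axes, collapse = "x")),
         make_template(tag, subdiv, semi_axes))
}

fix_basis <- function(tag = "hippocampus_L", subdiv = 2, K = 30) {
  cached(paste("basis", tag, subdiv, K),
         compute_harmonics(fix_template(tag, subdiv), K))
}

# geometry (templates + bases) for small test cohorts
fix_geometry <- function(subdiv = 2, K = 30) {
  cached(paste("geom", subdiv, K), {
    spec <- cohort_spec(subdivision_level = subdiv, seed = 1)
    cohort_geometry(spec, K = K)
  })
}

# standard small planted-effect cohort at the clinical 45/23 split
fix_cohort <- function(seed = 1, effect_amplitude = 1.0, ...) {
  simulate_cohort(
    cohort_spec(subdivision_level = 2, seed = seed,
                effect_amplitude = effect_amplitude, ...),
    fix_geometry())
}

# two-class gaussian toy problem for classifier tests
gaussian_problem <- function(n_per = 30, p = 5, delta = 3, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p), n_per),
             matrix(rnorm(n_per * p, mean = delta / sqrt(p)), n_per))
  y <- rep(pib_levels(), each = n_per)
  list(X = X, y = y)
}
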