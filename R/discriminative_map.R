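#' Back-project the LDA axis to per-vertex discriminative maps
#'
#' The discriminant axis w lives in the PCA space of the spectral features.
#' To see *where* on the structures the classifier looks, w is mapped back
#' to feature (coefficient) space via the PCA component matrix, split into
#' per-structure coefficient blocks, and each block is synthesised on its
#' template with the inverse manifold harmonic transform. Each per-vertex
#' map is normalised to unit Euclidean norm for display; the squared-norm
#' share of each coefficient block before normalisation is reported as the
#' structure's energy share. Positive map values mean that greater outward
#' deformity at that vertex votes for the PiB(+) class.
#'
#' @param state a trained `classifier_state` whose features were built by
#'   [build_feature_matrix()] (block layout inferred from feature names, or
#'   supply `N_c`).
#' @param bases named list of [compute_harmonics()] bases keyed by tag.
#' @param feature_set `"hippocampal"`, `"amygdalar"` or `"combined"`.
#' @param N_c per-structure cut-offs; defaults to equal split of the state's
#'   feature length over the feature set's structures.
#' @return named list of `discriminative_map` objects (`structure_tag`,
#'   `values` with unit L2 norm, `energy_share`).
#' @export
backproject_axis <- function(state, bases, feature_set = "combined", N_c = NULL) {
  if (is.null(state$pca) || is.null(state$lda))
    stop("classifier state is untrained")
  structs <- feature_structures(feature_set)
  if (is.null(N_c)) {
    if (state$p %% length(structs) != 0)
      stop("cannot infer per-structure N_c; supply it explicitly")
    N_c <- stats::setNames(rep(state$p / length(structs), length(structs)), structs)
  } else if (is.null(names(N_c))) {
    N_c <- stats::setNames(rep(N_c, length.out = length(structs)), structs)
  }
  if (sum(N_c[structs]) != state$p)
    stop(sprintf("feature layout mismatch: blocks sum to %d but state has p = %d",
                 sum(N_c[structs]), state$p))
  v <- as.numeric(state$pca$components %*% state$lda$w)  # axis in feature space
  total_energy <- sum(v^2)
  offset <- 0L
  maps <- list()
  for (s in structs) {
    if (is.null(bases[[s]]))
      stop("no harmonic basis supplied for structure ", s)
    block <- v[offset + seq_len(N_c[[s]])]
    offset <- offset + N_c[[s]]
    if (N_c[[s]] > bases[[s]]$K)
      stop(sprintf("basis for %s has K = %d < N_c = %d", s, bases[[s]]$K, N_c[[s]]))
    vals <- mht_inverse(block, bases[[s]])
    nrm <- sqrt(sum(vals^2))
    if (nrm == 0) stop("all-zero discriminative map for ", s)
    maps[[s]] <- structure(
      list(structure_tag = s, values = vals / nrm,
           energy_share = sum(block^2) / total_energy),
      class = "discriminative_map")
  }
  maps
}

#' @export
print.discriminative_map <- function(x, ...) {
  cat(sprintf("discriminative_map [%s]: %d vertices, energy share %.1f%%\n",
              x$structure_tag, length(x$values), 100 * x$energy_share))
  invisible(x)
}

#' Export a discriminative map as a mesh with a per-vertex scalar
#'
#' Writes the structure's template with the map values as the PLY `quality`
#' property so the map can be rendered in standard mesh viewers. The
#' unit-norm invariant is enforced before writing.
#'
#' @param map a `discriminative_map`.
#' @param template the matching template [triangle_mesh()].
#' @param path output `.ply` path.
#' @return `path`, invisibly.
#' @export
export_map <- function(map, template, path) {
  if (length(map$values) != n_vertices(template))
    stop("map length does not match template vertex count")
  if (abs(sqrt(sum(map$values^2)) - 1) > 1e-6)
    stop("discriminative map must have unit Euclidean norm")
  write_mesh(template, path, quality = map$values)
  invisible(path)
}
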