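#' Forward manifold harmonic transform of a deformity field
#'
#' Projects a per-vertex deformity field onto the first `N_c` manifold
#' harmonics of its structure's template using the mass-weighted inner
#' product: beta_k = sum_i m_i phi_k(i) x_i. Because the basis is
#' mass-orthonormal, truncation at N_c is the optimal (least-squares)
#' low-pass approximation, which is what removes high-spatial-frequency
#' noise from the fields before classification.
#'
#' @param field a [deformity_field()] (or bare numeric vector).
#' @param basis the structure's [compute_harmonics()] basis.
#' @param N_c cut-off frequency: number of coefficients retained
#'   (default: all `basis$K`).
#' @return An object of class `spectral_coefficients`: `structure_tag`,
#'   `coefficients` (length N_c), `N_c`.
#' @export
mht_forward <- function(field, basis, N_c = basis$K) {
  x <- if (is.numeric(field)) field else field$values
  if (length(x) != nrow(basis$eigenvectors))
    stop("field length does not match basis vertex count")
  if (N_c < 1 || N_c > basis$K)
    stop(sprintf("N_c = %d exceeds basis size K = %d", N_c, basis$K))
  beta <- as.numeric(crossprod(basis$eigenvectors[, seq_len(N_c), drop = FALSE],
                               basis$mass * x))
  structure(list(structure_tag = basis$structure_tag,
                 coefficients = beta, N_c = N_c),
            class = "spectral_coefficients")
}

#' Inverse manifold harmonic transform
#'
#' Reconstructs the (low-pass filtered) per-vertex field x_hat =
#' sum_k beta_k phi_k from a truncated coefficient vector.
#'
#' @param coeffs a `spectral_coefficients` object or numeric vector.
#' @param basis the matching [compute_harmonics()] basis.
#' @return numeric per-vertex field of length `nrow(basis$eigenvectors)`.
#' @export
mht_inverse <- function(coeffs, basis) {
  beta <- if (is.numeric(coeffs)) coeffs else coeffs$coefficients
  if (length(beta) > basis$K) stop("more coefficients than basis functions")
  as.numeric(basis$eigenvectors[, seq_along(beta), drop = FALSE] %*% beta)
}

#' Choose the spectral cut-off by goodness of fit
#'
#' Smallest `N_c` whose truncated reconstructions capture at least
#' `energy_fraction` of the mass-weighted field energy, averaged over the
#' supplied (training) fields.
#'
#' @param fields list of [deformity_field()]s (or numeric vectors) on the
#'   basis' template.
#' @param basis a [compute_harmonics()] basis.
#' @param energy_fraction target captured-energy fraction (default 0.9).
#' @return integer cut-off `N_c`.
#' @export
choose_cutoff <- function(fields, basis, energy_fraction = 0.9) {
  stopifnot(energy_fraction > 0, energy_fraction <= 1)
  fracs <- vapply(fields, function(f) {
    x <- if (is.numeric(f)) f else f$values
    tot <- sum(basis$mass * x^2)
    if (tot == 0) return(rep(1, basis$K))
    beta <- mht_forward(x, basis)$coefficients
    cumsum(beta^2) / tot
  }, numeric(basis$K))
  avg <- rowMeans(fracs)
  idx <- which(avg >= energy_fraction - 1e-12)
  if (!length(idx)) basis$K else as.integer(idx[1])
}

# canonical structure order for concatenated features
feature_structures <- function(feature_set = c("combined", "hippocampal", "amygdalar")) {
  switch(match.arg(feature_set),
         hippocampal = c("hippocampus_L", "hippocampus_R"),
         amygdalar   = c("amygdala_L", "amygdala_R"),
         combined    = c("hippocampus_L", "hippocampus_R",
                         "amygdala_L", "amygdala_R"))
}

#' Assemble a per-subject spectral feature vector
#'
#' Concatenates truncated harmonic coefficients of the subject's structures
#' in the fixed order hippocampus_L, hippocampus_R, amygdala_L, amygdala_R
#' (restricted to the requested feature set), with deterministic names like
#' `hippL_k003`.
#'
#' @param fields named list of [deformity_field()]s keyed by structure tag.
#' @param feature_set `"hippocampal"`, `"amygdalar"` or `"combined"`.
#' @param bases named list of [compute_harmonics()] bases keyed by structure tag.
#' @param N_c cut-off per structure: scalar or named vector.
#' @return named numeric feature vector.
#' @export
assemble_feature <- function(fields, feature_set, bases, N_c) {
  structs <- feature_structures(feature_set)
  missing <- setdiff(structs, names(fields))
  if (length(missing))
    stop("missing deformity field(s) for structure(s): ",
         paste(missing, collapse = ", "))
  if (is.null(names(N_c))) N_c <- stats::setNames(rep(N_c, length.out = length(structs)), structs)
  out <- unlist(lapply(structs, function(s) {
    beta <- mht_forward(fields[[s]], bases[[s]], N_c[[s]])$coefficients
    stats::setNames(beta, sprintf("%s_k%03d", structure_prefix(s),
                                  seq_along(beta) - 1L))
  }))
  out
}

#' Build the subjects-by-coefficients feature matrix of a cohort
#'
#' @param cohort a cohort as returned by [simulate_cohort()], or any list
#'   with `fields[[structure]]` = subjects x vertices matrix and
#'   `subject_ids`.
#' @param bases named list of harmonic bases keyed by structure tag.
#' @param feature_set `"hippocampal"`, `"amygdalar"` or `"combined"`.
#' @param N_c cut-off per structure (scalar or named vector).
#' @return numeric matrix, subjects x coefficients, with subject ids as row
#'   names and `hippL_k000`-style column names.
#' @export
build_feature_matrix <- function(cohort, bases, feature_set = "combined", N_c = 70) {
  structs <- feature_structures(feature_set)
  missing <- setdiff(structs, names(cohort$fields))
  if (length(missing))
    stop("cohort lacks structure(s): ", paste(missing, collapse = ", "))
  if (is.null(names(N_c))) N_c <- stats::setNames(rep(N_c, length.out = length(structs)), structs)
  blocks <- lapply(structs, function(s) {
    basis <- bases[[s]]
    nc <- N_c[[s]]
    if (nc > basis$K) stop(sprintf("N_c = %d exceeds basis size K = %d (%s)", nc, basis$K, s))
    Phi <- basis$eigenvectors[, seq_len(nc), drop = FALSE]
    B <- cohort$fields[[s]] %*% (basis$mass * Phi)
    colnames(B) <- sprintf("%s_k%03d", structure_prefix(s), seq_len(nc) - 1L)
    B
  })
  X <- do.call(cbind, blocks)
  rownames(X) <- cohort$subject_ids
  X
}

#' Write / read a feature matrix as CSV
#' @param X feature matrix from [build_feature_matrix()].
#' @param path CSV path.
#' @return `path` invisibly (writer); matrix (reader).
#' @export
write_feature_csv <- function(X, path) {
  utils::write.csv(data.frame(subject_id = rownames(X), X, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df$subject_id
  X
}
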