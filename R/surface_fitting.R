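#' Construct a corresponded subject surface
#'
#' A subject surface that shares its connectivity (face list and vertex
#' ordering) with the structure's template, so that vertex i of every
#' subject refers to the same anatomical location by construction.
#'
#' @param subject_id character scalar.
#' @param vertices n x 3 matrix, n equal to the template vertex count.
#' @param template the structure's template [triangle_mesh()].
#' @param provenance `"fitted"` (produced by [laplacian_deform()]) or
#'   `"supplied"` (corresponded surface provided externally).
#' @return An object of class `corresponded_surface`.
#' @export
corresponded_surface <- function(subject_id, vertices, template,
                                 provenance = c("supplied", "fitted")) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) != n_vertices(template))
    stop(sprintf("vertex count %d does not match template's %d",
                 nrow(vertices), n_vertices(template)))
  structure(list(subject_id = subject_id,
                 structure_tag = template$structure_tag,
                 vertices = vertices,
                 faces = template$faces,     # shared connectivity
                 provenance = match.arg(provenance)),
            class = "corresponded_surface")
}

# occupancy array shifted by `by` voxels along `ax` (FALSE beyond the grid)
shift_occ <- function(occ, ax, by) {
  dm <- dim(occ)
  res <- array(FALSE, dm)
  src <- lapply(1:3, function(a) seq_len(dm[a]))
  dst <- src
  keep <- seq_len(dm[ax])
  keep <- keep[keep + by >= 1 & keep + by <= dm[ax]]
  dst[[ax]] <- keep
  src[[ax]] <- keep + by
  if (length(keep))
    res[dst[[1]], dst[[2]], dst[[3]]] <- occ[src[[1]], src[[2]], src[[3]]]
  res
}

# world centers of boundary faces between occupied and empty voxels
boundary_points <- function(grid) {
  occ <- grid$occupancy
  centers <- lapply(1:3, function(a) axis_centers(grid, a))
  pts <- list()
  for (ax in 1:3) {
    for (side in c(-1L, 1L)) {
      face <- which(occ & !shift_occ(occ, ax, side), arr.ind = TRUE)
      if (nrow(face)) {
        p <- cbind(centers[[1]][face[, 1]], centers[[2]][face[, 2]],
                   centers[[3]][face[, 3]])
        p[, ax] <- p[, ax] + side * grid$spacing[ax] / 2
        pts[[length(pts) + 1L]] <- p
      }
    }
  }
  do.call(rbind, pts)
}

# for each row of A find index of nearest row of B (brute force, chunked)
nearest_index <- function(A, B, chunk = 512L) {
  nb <- nrow(B)
  b2 <- rowSums(B^2)
  out <- integer(nrow(A))
  for (start in seq(1L, nrow(A), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(A))
    D <- outer(rowSums(A[idx, , drop = FALSE]^2), b2, "+") -
      2 * A[idx, , drop = FALSE] %*% t(B)
    out[idx] <- max.col(-D, ties.method = "first")
  }
  out
}

#' Deform a template mesh onto a binary segmentation
#'
#' Laplacian surface deformation: each iteration solves, per coordinate, the
#' least-squares system balancing preservation of the template's Laplacian
#' differential coordinates (cotangent stiffness applied to the template)
#' against soft closest-point constraints towards the target's boundary
#' (centers of occupied-to-empty voxel faces). The constraint weight is
#' ramped up over iterations so the surface first settles globally and then
#' locks onto the boundary. Connectivity is never changed, so the result is
#' in vertex correspondence with the template by construction.
#'
#' @param template a [triangle_mesh()] rigidly pre-positioned over the target.
#' @param target a [voxel_grid()] containing a single connected component.
#' @param iterations number of outer iterations.
#' @param stiffness_weight weight of the differential-coordinate term.
#' @param max_constraint_weight final per-vertex closest-point weight.
#' @param tol convergence threshold on mean vertex motion relative to voxel
#'   spacing; unmet after `iterations` produces a warning, returning the
#'   best (last) iterate.
#' @param subject_id id recorded on the fitted surface.
#' @return a [corresponded_surface()] with provenance `"fitted"`.
#' @export
laplacian_deform <- function(template, target, iterations = 12,
                             stiffness_weight = 1, max_constraint_weight = 4,
                             tol = 0.05, subject_id = "subject") {
  if (sum(target$occupancy) == 0) stop("target segmentation is empty")
  bp <- boundary_points(target)
  lap <- build_laplacian(template)
  S <- lap$stiffness
  V0 <- template$vertices
  delta <- as.matrix(S %*% V0)        # differential coordinates to preserve
  StS <- Matrix::crossprod(S)
  V <- V0
  mean_motion <- Inf
  h <- mean(target$spacing)
  for (it in seq_len(iterations)) {
    w <- max_constraint_weight * it / iterations
    C <- bp[nearest_index(V, bp), , drop = FALSE]
    A <- stiffness_weight^2 * StS + Matrix::Diagonal(n = nrow(V), x = w)
    rhs <- stiffness_weight^2 * as.matrix(Matrix::crossprod(S, delta)) + w * C
    Vnew <- as.matrix(Matrix::solve(A, rhs))
    mean_motion <- mean(sqrt(rowSums((Vnew - V)^2)))
    V <- Vnew
    if (it > 1 && mean_motion < tol * h) break
  }
  if (mean_motion >= tol * h)
    warning(sprintf("laplacian_deform: mean vertex motion %.3g mm after %d iterations (tol %.3g mm); returning best iterate",
                    mean_motion, iterations, tol * h))
  corresponded_surface(subject_id, V, template, provenance = "fitted")
}

#' Similarity Procrustes alignment of corresponded point sets
#'
#' Closed-form least-squares similarity transform (scale s, rotation R,
#' translation t) minimising sum ||s R x_i + t - y_i||^2 over corresponded
#' vertices, used as the size-normalisation step before deformity
#' computation.
#'
#' @param moving n x 3 matrix (or mesh/surface) to align.
#' @param fixed n x 3 matrix (or mesh/surface) to align to.
#' @return list with `scale`, `rotation` (3 x 3), `translation` (length 3)
#'   and `transformed` (the transformed moving vertices).
#' @export
similarity_align <- function(moving, fixed) {
  X <- surface_vertices(moving)
  Y <- surface_vertices(fixed)
  if (!all(dim(X) == dim(Y))) stop("point sets must be corresponded (equal dims)")
  n <- nrow(X)
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  varx <- sum(Xc^2) / n
  if (varx < 1e-12 || sum(Yc^2) / n < 1e-12)
    stop("degenerate (zero-variance) point set; cannot align")
  Sig <- crossprod(Yc, Xc) / n
  sv <- svd(Sig)
  d <- diag(3)
  d[3, 3] <- sign(det(sv$u) * det(sv$v))
  R <- sv$u %*% d %*% t(sv$v)
  s <- sum(diag(diag(sv$d) %*% d)) / varx
  t_ <- my - s * as.numeric(R %*% mx)
  list(scale = s, rotation = R, translation = t_,
       transformed = sweep(s * X %*% t(R), 2, t_, `+`))
}

surface_vertices <- function(x) {
  if (is.matrix(x)) x else x$vertices
}

#' Deformity field of a subject surface against its template
#'
#' Signed per-vertex displacement (mm) of the subject surface along the
#' template's outward unit normals: value_i = (v_i - u_i) . n_i, positive
#' outward (so atrophy is negative). With `normalize_size = TRUE` the
#' subject surface is first brought into the template frame by similarity
#' Procrustes on the corresponded vertices, removing global position,
#' rotation, and scale before projecting onto the normals.
#'
#' @param subject a [corresponded_surface()] (or bare vertex matrix).
#' @param template the structure's template [triangle_mesh()].
#' @param normalize_size apply [similarity_align()] first (default `TRUE`).
#' @return An object of class `deformity_field`: `subject_id`,
#'   `structure_tag`, `values` (length n, mm).
#' @export
compute_deformity <- function(subject, template, normalize_size = TRUE) {
  V <- surface_vertices(subject)
  if (nrow(V) != n_vertices(template))
    stop("subject/template vertex count mismatch")
  if (normalize_size) V <- similarity_align(V, template$vertices)$transformed
  nrm <- vertex_normals(template)
  vals <- rowSums((V - template$vertices) * nrm)
  if (!all(is.finite(vals))) stop("non-finite deformity values")
  deformity_field(if (is.matrix(subject)) "subject" else subject$subject_id,
                  template$structure_tag, vals)
}

#' Construct a deformity field
#' @param subject_id character scalar.
#' @param structure_tag see [structure_tags()].
#' @param values per-vertex signed displacement in mm (positive = outward).
#' @return An object of class `deformity_field`.
#' @export
deformity_field <- function(subject_id, structure_tag, values) {
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("deformity values must be finite")
  structure(list(subject_id = subject_id,
                 structure_tag = match.arg(structure_tag, structure_tags()),
                 values = values),
            class = "deformity_field")
}

#' Write / read deformity fields as a long-format CSV
#'
#' Columns: subject_id, structure_tag, vertex_index (0-based), value_mm.
#'
#' @param fields list of [deformity_field()]s.
#' @param path CSV path.
#' @return `path` invisibly (writer); list of fields (reader).
#' @export
write_deformity_csv <- function(fields, path) {
  rows <- lapply(fields, function(f)
    data.frame(subject_id = f$subject_id, structure_tag = f$structure_tag,
               vertex_index = seq_along(f$values) - 1L, value_mm = f$values))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_deformity_csv
#' @export
read_deformity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (key in unique(paste(df$subject_id, df$structure_tag))) {
    sub <- df[paste(df$subject_id, df$structure_tag) == key, ]
    sub <- sub[order(sub$vertex_index), ]
    out[[length(out) + 1L]] <- deformity_field(sub$subject_id[1],
                                               sub$structure_tag[1],
                                               sub$value_mm)
  }
  out
}
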