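#' Structure tags recognised by the pipeline
#'
#' Fixed identifiers for the four subcortical structures analysed by the
#' pipeline, in the canonical concatenation order used for combined feature
#' vectors, plus `"other"` for ad-hoc meshes.
#'
#' @return Character vector of valid `structure_tag` values.
#' @export
structure_tags <- function() {
  c("hippocampus_L", "hippocampus_R", "amygdala_L", "amygdala_R", "other")
}

# short column prefixes used in serialized feature names, e.g. hippL_k003
structure_prefix <- function(tag) {
  c(hippocampus_L = "hippL", hippocampus_R = "hippR",
    amygdala_L = "amygL", amygdala_R = "amygR", other = "other")[[tag]]
}

#' Construct a validated triangle mesh
#'
#' Builds a closed, consistently oriented triangle surface mesh in world
#' millimetres. Validation enforces the invariants the downstream operators
#' rely on: indices in range, no degenerate faces, every edge shared by
#' exactly two faces with opposite orientation (closed orientable
#' 2-manifold), and outward orientation (positive signed volume). A mesh
#' whose faces are consistently wound but inside-out is re-oriented with a
#' message rather than rejected.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @param structure_tag one of [structure_tags()].
#' @param validate set `FALSE` to skip invariant checks (internal use on
#'   meshes derived from an already-validated mesh).
#' @return An object of class `triangle_mesh` with elements `vertices`,
#'   `faces`, `structure_tag`.
#' @export
triangle_mesh <- function(vertices, faces, structure_tag = "other",
                          validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  structure_tag <- match.arg(structure_tag, structure_tags())
  mesh <- structure(
    list(vertices = vertices, faces = faces, structure_tag = structure_tag),
    class = "triangle_mesh")
  if (validate) {
    check_mesh(mesh)
    if (mesh_volume(mesh) < 0) {
      message("mesh is consistently wound but inside-out; re-orienting faces")
      mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
    }
  }
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh [%s]: %d vertices, %d faces\n",
              x$structure_tag, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

# directed half-edges encoded as a single integer-ish double key
half_edge_keys <- function(faces, nv) {
  i <- as.numeric(c(faces[, 1], faces[, 2], faces[, 3]))
  j <- as.numeric(c(faces[, 2], faces[, 3], faces[, 1]))
  list(from = i, to = j, key = i * (nv + 1) + j)
}

check_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)
  if (!all(is.finite(v))) stop("mesh vertices contain non-finite coordinates")
  if (any(f < 1L) || any(f > nv)) stop("face index out of range")
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    stop("degenerate face: a face repeats a vertex")
  he <- half_edge_keys(f, nv)
  if (anyDuplicated(he$key)) {
    d <- he$key[duplicated(he$key)][1]
    stop(sprintf("non-manifold or inconsistently oriented mesh: directed edge %d->%d occurs twice",
                 d %/% (nv + 1), d %% (nv + 1)))
  }
  rev_key <- he$to * (nv + 1) + he$from
  missing <- which(!(rev_key %in% he$key))
  if (length(missing)) {
    stop(sprintf("open (non-closed) mesh: edge %d->%d has no opposite half-edge",
                 he$from[missing[1]], he$to[missing[1]]))
  }
  ne <- length(he$key) / 2
  euler <- nv - ne + nrow(f)
  if (euler != 2)
    stop(sprintf("mesh is not genus-0: Euler characteristic V-E+F = %d (expected 2)", euler))
  invisible(TRUE)
}

# signed volume of the face fan about the origin; positive iff outward-oriented
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  det3 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
          a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
          a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(det3) / 6
}

face_cross <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

face_areas <- function(mesh) {
  cr <- face_cross(mesh)
  sqrt(rowSums(cr^2)) / 2
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a [triangle_mesh()].
#' @return Scalar area in mm^2.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Per-vertex outward unit normals
#'
#' Angle-weighted average of incident face normals, normalised to unit
#' length. Outwardness follows from the mesh's validated orientation
#' (positive signed volume).
#'
#' @param mesh a [triangle_mesh()].
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  cr <- face_cross(mesh)
  a2 <- sqrt(rowSums(cr^2))          # 2 * face area
  if (any(a2 <= 0)) stop("zero-area face in mesh; normals undefined")
  fn <- cr / a2                       # unit face normals
  nrm <- matrix(0, nrow(v), 3)
  for (corner in 1:3) {
    i0 <- f[, corner]
    i1 <- f[, corner %% 3L + 1L]
    i2 <- f[, (corner + 1L) %% 3L + 1L]
    u <- v[i1, , drop = FALSE] - v[i0, , drop = FALSE]
    w <- v[i2, , drop = FALSE] - v[i0, , drop = FALSE]
    cosang <- rowSums(u * w) / sqrt(rowSums(u^2) * rowSums(w^2))
    ang <- acos(pmin(1, pmax(-1, cosang)))
    for (d in 1:3) {
      nrm[, d] <- nrm[, d] + tabulate_add(i0, ang * fn[, d], nrow(v))
    }
  }
  len <- sqrt(rowSums(nrm^2))
  if (any(len <= 1e-300)) stop("vertex with degenerate incident-face fan")
  nrm / len
}

# sum `val` into bins `idx`, returning a length-n vector (0 for empty bins)
tabulate_add <- function(idx, val, n) {
  out <- numeric(n)
  s <- rowsum(val, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}
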