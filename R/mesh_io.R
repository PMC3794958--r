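#' Read a triangle mesh from an ASCII PLY or OFF file
#'
#' Minimal readers for the two ASCII formats the package writes. PLY files
#' may carry a per-vertex `quality` scalar (used for discriminative maps),
#' returned as the `quality` attribute.
#'
#' @param path file path ending in `.ply` or `.off`.
#' @param structure_tag tag to assign, see [structure_tags()].
#' @param validate passed to [triangle_mesh()].
#' @return a [triangle_mesh()]; per-vertex scalars (if present) in
#'   `attr(mesh, "quality")`.
#' @export
read_mesh <- function(path, structure_tag = "other", validate = TRUE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path, structure_tag, validate),
         off = read_off(path, structure_tag, validate),
         stop("unsupported mesh format '", ext, "' for ", path))
}

#' Write a triangle mesh to an ASCII PLY or OFF file
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path ending in `.ply` or `.off`.
#' @param quality optional per-vertex scalar written as the PLY `quality`
#'   property (PLY only).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, quality = NULL) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = write_ply(mesh, path, quality),
         off = write_off(mesh, path),
         stop("unsupported mesh format '", ext, "' for ", path))
  invisible(path)
}

read_ply <- function(path, structure_tag, validate) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || trimws(lines[1]) != "ply")
    stop("not a PLY file: ", path)
  hdr_end <- which(trimws(lines) == "end_header")[1]
  if (is.na(hdr_end)) stop("PLY header missing end_header: ", path)
  hdr <- trimws(lines[seq_len(hdr_end)])
  if (!any(grepl("^format ascii", hdr)))
    stop("only ASCII PLY is supported: ", path)
  nv <- as.integer(sub("^element vertex\\s+", "", grep("^element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("^element face\\s+", "", grep("^element face", hdr, value = TRUE)[1]))
  # vertex property names, in declaration order
  vprops <- character(0)
  in_vertex <- FALSE
  for (h in hdr) {
    if (grepl("^element vertex", h)) { in_vertex <- TRUE; next }
    if (grepl("^element ", h)) in_vertex <- FALSE
    if (in_vertex && grepl("^property ", h))
      vprops <- c(vprops, utils::tail(strsplit(h, "\\s+")[[1]], 1))
  }
  body <- lines[(hdr_end + 1):length(lines)]
  vtab <- matrix(scan(text = body[seq_len(nv)], quiet = TRUE),
                 nrow = nv, byrow = TRUE)
  colnames(vtab) <- vprops[seq_len(ncol(vtab))]
  verts <- vtab[, c("x", "y", "z"), drop = FALSE]
  dimnames(verts) <- NULL
  ftab <- matrix(scan(text = body[nv + seq_len(nf)], quiet = TRUE),
                 nrow = nf, byrow = TRUE)
  if (any(ftab[, 1] != 3)) stop("non-triangular face in ", path)
  mesh <- triangle_mesh(verts, ftab[, 2:4] + 1L, structure_tag, validate = validate)
  if ("quality" %in% colnames(vtab)) attr(mesh, "quality") <- vtab[, "quality"]
  mesh
}

write_ply <- function(mesh, path, quality = NULL) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  qhdr <- if (!is.null(quality)) "property float quality" else NULL
  if (!is.null(quality) && length(quality) != nv)
    stop("quality length must equal vertex count")
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z", qhdr,
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  vt <- mesh$vertices
  vlines <- if (is.null(quality)) {
    sprintf("%.8g %.8g %.8g", vt[, 1], vt[, 2], vt[, 3])
  } else {
    sprintf("%.8g %.8g %.8g %.8g", vt[, 1], vt[, 2], vt[, 3], quality)
  }
  f0 <- mesh$faces - 1L
  flines <- sprintf("3 %d %d %d", f0[, 1], f0[, 2], f0[, 3])
  writeLines(c(hdr, vlines, flines), path)
}

read_off <- function(path, structure_tag, validate) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (toupper(trimws(lines[1])) != "OFF") stop("not an OFF file: ", path)
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  verts <- matrix(scan(text = lines[2 + seq_len(nv)], quiet = TRUE),
                  nrow = nv, byrow = TRUE)[, 1:3, drop = FALSE]
  ftab <- matrix(scan(text = lines[2 + nv + seq_len(nf)], quiet = TRUE),
                 nrow = nf, byrow = TRUE)
  if (any(ftab[, 1] != 3)) stop("non-triangular face in ", path)
  triangle_mesh(verts, ftab[, 2:4] + 1L, structure_tag, validate = validate)
}

write_off <- function(mesh, path) {
  vt <- mesh$vertices; f0 <- mesh$faces - 1L
  writeLines(c("OFF",
               sprintf("%d %d 0", nrow(vt), nrow(f0)),
               sprintf("%.8g %.8g %.8g", vt[, 1], vt[, 2], vt[, 3]),
               sprintf("3 %d %d %d", f0[, 1], f0[, 2], f0[, 3])),
             path)
}
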