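test_that("mesh validation enforces closed oriented manifold invariants", {
  tet <- tetra_mesh()
  expect_s3_class(tet, "triangle_mesh")
  expect_gt(subshape:::mesh_volume(tet), 0)

  v <- tet$vertices; f <- tet$faces
  expect_error(triangle_mesh(v, rbind(f, c(1, 1, 2))), "degenerate")
  expect_error(triangle_mesh(v, f[-1, , drop = FALSE]), "open")
  expect_error(triangle_mesh(v, rbind(f, f[1, ])), "non-manifold|twice")
  expect_error(triangle_mesh(v, cbind(f[, 1], f[, 2], 9L)), "out of range")

  # inside-out but consistent winding is re-oriented, never left inward
  expect_message(flipped <- triangle_mesh(v, f[, c(1, 3, 2)]), "re-orienting")
  expect_gt(subshape:::mesh_volume(flipped), 0)
})

test_that("cotangent stiffness matches the closed form on a regular tetrahedron", {
  lap <- build_laplacian(tetra_mesh())
  S <- as.matrix(lap$stiffness)
  # every edge sees two equilateral corners: -(cot60 + cot60)/2 = -1/sqrt(3)
  off <- S[upper.tri(S)]
  expect_equal(off, rep(-1 / sqrt(3), 6), tolerance = 1e-12)
  expect_equal(max(abs(S - t(S))), 0)
  expect_equal(max(abs(rowSums(S))), 0, tolerance = 1e-12)
})

test_that("stiffness has zero row sums and mass sums to surface area on templates", {
  for (tag in c("hippocampus_L", "amygdala_R")) {
    mesh <- fix_template(tag, 2)
    lap <- build_laplacian(mesh)
    expect_lt(max(abs(Matrix::rowSums(lap$stiffness))), 1e-10)
    expect_lt(max(abs(lap$stiffness - Matrix::t(lap$stiffness))), 1e-12)
    expect_true(all(lap$mass > 0))
    expect_equal(sum(lap$mass), mesh_area(mesh), tolerance = 1e-10)
  }
  # applied to the constant vector the stiffness annihilates it
  lap <- build_laplacian(fix_template("hippocampus_L", 2))
  expect_lt(max(abs(lap$stiffness %*% rep(1, 162))), 1e-10)
})

test_that("icosphere total mass approximates the analytic sphere area", {
  sph <- fix_template("other", 3, semi_axes = c(1, 1, 1))
  lap <- build_laplacian(sph)
  expect_equal(sum(lap$mass), 4 * pi, tolerance = 0.01)
})

test_that("harmonic basis is mass-orthonormal with deterministic signs", {
  b <- fix_basis("hippocampus_L", 2, K = 25)
  G <- crossprod(b$eigenvectors, b$mass * b$eigenvectors)
  expect_lt(max(abs(G - diag(25))), 1e-8)
  expect_true(all(diff(b$eigenvalues) > -1e-10))
  expect_lt(abs(b$eigenvalues[1]), 1e-8 * b$eigenvalues[2])
  # constant first mode
  expect_lt(diff(range(b$eigenvectors[, 1])), 1e-8 * abs(b$eigenvectors[1, 1]))
  # sign rule: largest-|entry| component positive
  for (k in 1:25) {
    expect_gt(b$eigenvectors[which.max(abs(b$eigenvectors[, k])), k], 0)
  }
  expect_error(compute_harmonics(fix_template("hippocampus_L", 2), 0), "out of range")
  expect_error(compute_harmonics(fix_template("hippocampus_L", 2), 500), "out of range")
})

test_that("K = 1 returns only the constant nullspace mode", {
  b <- compute_harmonics(tetra_mesh(), 1)
  expect_lt(abs(b$eigenvalues[1]), 1e-10)
  expect_lt(diff(range(b$eigenvectors[, 1])), 1e-10)
})

test_that("vertex normals are unit, outward, and radial on a sphere", {
  sph <- fix_template("other", 2, semi_axes = c(1, 1, 1))
  nrm <- vertex_normals(sph)
  expect_lt(max(abs(sqrt(rowSums(nrm^2)) - 1)), 1e-12)
  radial <- sph$vertices / sqrt(rowSums(sph$vertices^2))
  ang <- acos(pmin(1, rowSums(nrm * radial))) * 180 / pi
  expect_lt(max(ang), 2)
  # a convex fixture built with inverted winding still yields outward normals
  inv <- suppressMessages(triangle_mesh(sph$vertices, sph$faces[, c(1, 3, 2)]))
  expect_gt(mean(rowSums(vertex_normals(inv) * radial)), 0.9)
})

test_that("voxelization reproduces analytic ellipsoid volume within 2%", {
  ell <- fix_template("other", 3, semi_axes = c(10, 6, 4))
  g <- voxelize(ell, 0.5)
  expect_equal(grid_volume(g), 4 / 3 * pi * 10 * 6 * 4, tolerance = 0.02)
  # corners of the padded grid stay empty
  dm <- dim(g$occupancy)
  expect_false(any(g$occupancy[c(1, dm[1]), , ]))
  expect_false(any(g$occupancy[, c(1, dm[2]), ]))
  # explicit grid that clips the mesh is rejected
  expect_error(voxelize(ell, 0.5, origin = c(0, 0, 0), shape = c(10L, 10L, 10L)),
               "exceeds grid")
  expect_error(voxelize(ell, 0.5, origin = c(0, 0, 0)), "together")
})

test_that("overlap_fraction counts reference coverage and symmetric Dice", {
  occ <- array(FALSE, c(12, 12, 12))
  occ[2:11, 2:11, 2:11] <- TRUE
  a <- voxel_grid(occ, rep(1, 3), rep(0, 3))
  expect_equal(overlap_fraction(a, a)$overlap, 1.0)
  expect_equal(overlap_fraction(a, a)$dice, 1.0)

  occ2 <- array(FALSE, c(12, 12, 12)); occ2[1, 1, 1] <- TRUE
  b <- voxel_grid(occ2, rep(1, 3), rep(0, 3))
  expect_equal(overlap_fraction(b, a)$overlap, 0.0)

  # 10-voxel cube against itself shifted by 5 voxels: half covered
  occ3 <- array(FALSE, c(20, 12, 12)); occ3[2:11, 2:11, 2:11] <- TRUE
  occ4 <- array(FALSE, c(20, 12, 12)); occ4[7:16, 2:11, 2:11] <- TRUE
  s1 <- voxel_grid(occ3, rep(1, 3), rep(0, 3))
  s2 <- voxel_grid(occ4, rep(1, 3), rep(0, 3))
  expect_equal(overlap_fraction(s2, s1)$overlap, 0.5)
  expect_equal(overlap_fraction(s2, s1)$dice, overlap_fraction(s1, s2)$dice)

  c_ <- voxel_grid(array(FALSE, c(2, 2, 2)), rep(1, 3), rep(0, 3))
  expect_error(overlap_fraction(a, c_), "mismatched")
  expect_error(overlap_fraction(a, voxel_grid(array(FALSE, c(12, 12, 12)),
                                              rep(1, 3), rep(0, 3))), "empty")
})

test_that("NIfTI segmentations round-trip occupancy and geometry", {
  g <- voxelize(fix_template("amygdala_L", 2), 1.0)
  path <- tempfile(fileext = ".nii.gz")
  write_segmentation(g, path)
  g2 <- read_segmentation(path)
  expect_identical(g2$occupancy, g$occupancy)
  expect_equal(g2$spacing, g$spacing, tolerance = 1e-5)
  expect_equal(g2$origin, g$origin, tolerance = 1e-4)
})

test_that("PLY and OFF files round-trip meshes and per-vertex scalars", {
  mesh <- fix_template("amygdala_R", 2)
  for (ext in c(".ply", ".off")) {
    path <- tempfile(fileext = ext)
    write_mesh(mesh, path)
    m2 <- read_mesh(path, "amygdala_R")
    expect_equal(m2$vertices, mesh$vertices, tolerance = 1e-6)
    expect_identical(m2$faces, mesh$faces)
  }
  # PLY quality channel
  q <- sin(seq_len(nrow(mesh$vertices)))
  path <- tempfile(fileext = ".ply")
  write_mesh(mesh, path, quality = q)
  m3 <- read_mesh(path, "amygdala_R")
  expect_equal(attr(m3, "quality"), q, tolerance = 1e-6)
  # header declares the quality property
  hdr <- readLines(path, n = 12)
  expect_true(any(grepl("property float quality", hdr)))
  expect_true(any(grepl("element vertex 162", hdr)))
})
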