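test_that("constant fields load only the zeroth harmonic", {
  b <- fix_basis("hippocampus_L", 2)
  beta <- mht_forward(rep(2.5, 162), b, 20)
  expect_equal(beta$coefficients[1], 2.5 * sqrt(sum(b$mass)), tolerance = 1e-8)
  expect_lt(max(abs(beta$coefficients[-1])), 1e-8 * abs(beta$coefficients[1]))
  # and beta = e_0 synthesises a spatially constant field
  flat <- mht_inverse(c(1, rep(0, 5)), b)
  expect_lt(diff(range(flat)), 1e-10 * abs(flat[1]))
})

test_that("projecting a basis function returns its unit coefficient", {
  b <- fix_basis("hippocampus_L", 2)
  beta <- mht_forward(b$eigenvectors[, 4], b, 10)
  expect_equal(beta$coefficients[4], 1, tolerance = 1e-8)
  expect_lt(max(abs(beta$coefficients[-4])), 1e-8)
})

test_that("full-basis transform is a lossless round trip satisfying Parseval", {
  tag <- "amygdala_L"
  tpl <- fix_template(tag, 2)
  b <- cached("basis_full_amyL", compute_harmonics(tpl, 162))
  set.seed(3)
  x <- rnorm(162)
  beta <- mht_forward(x, b)
  expect_lt(max(abs(mht_inverse(beta, b) - x)) / max(abs(x)), 1e-8)
  expect_equal(sum(beta$coefficients^2), sum(b$mass * x^2), tolerance = 1e-8)
  # linearity
  y <- rnorm(162)
  expect_equal(mht_forward(2 * x + y, b, 30)$coefficients,
               2 * mht_forward(x, b, 30)$coefficients +
                 mht_forward(y, b, 30)$coefficients,
               tolerance = 1e-10)
  expect_error(mht_forward(x, b, 200), "exceeds")
  expect_error(mht_forward(rnorm(10), b), "length")
})

test_that("truncation error is monotone in the cut-off and filtering is idempotent", {
  b <- cached("basis_full_amyL", compute_harmonics(fix_template("amygdala_L", 2), 162))
  set.seed(4)
  x <- rnorm(162)
  errs <- vapply(c(1, 5, 10, 20, 40, 80, 162), function(nc) {
    sum(b$mass * (mht_inverse(mht_forward(x, b, nc), b) - x)^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
  expect_lt(errs[length(errs)], 1e-12)

  smooth1 <- mht_inverse(mht_forward(x, b, 20), b)
  smooth2 <- mht_inverse(mht_forward(smooth1, b, 20), b)
  expect_equal(smooth2, smooth1, tolerance = 1e-10)
})

test_that("low-pass filtering reduces the graph roughness of white noise", {
  tpl <- fix_template("hippocampus_L", 2)
  b <- fix_basis("hippocampus_L", 2)
  S <- build_laplacian(tpl)$stiffness
  roughness <- function(x) sum(x * as.numeric(S %*% x)) / length(x)
  set.seed(6)
  x <- rnorm(162)
  xf <- mht_inverse(mht_forward(x, b, 20), b)
  expect_lt(roughness(xf), roughness(x))
})

test_that("feature vectors concatenate structures in fixed order", {
  b <- fix_geometry()$bases
  set.seed(7)
  fields <- lapply(stats::setNames(nm = setdiff(structure_tags(), "other")),
                   function(s) deformity_field("s1", s, rnorm(162)))
  fv <- assemble_feature(fields, "combined", b, N_c = 15)
  expect_length(fv, 60)
  expect_identical(names(fv)[1], "hippL_k000")
  expect_identical(names(fv)[16], "hippR_k000")
  expect_identical(names(fv)[31], "amygL_k000")
  expect_identical(names(fv)[60], "amygR_k014")
  # hippocampal set is the leading block of the combined vector
  fh <- assemble_feature(fields, "hippocampal", b, N_c = 15)
  expect_identical(unname(fh), unname(fv[1:30]))
  # identical fields give identical features
  fv2 <- assemble_feature(fields, "combined", b, N_c = 15)
  expect_identical(fv, fv2)
  expect_error(assemble_feature(fields[1:3], "combined", b, 15), "amygdala_R")
})

test_that("cohort feature matrices agree with per-subject assembly", {
  coh <- fix_cohort(seed = 21)
  geom <- fix_geometry()
  X <- build_feature_matrix(coh, geom$bases, "combined", N_c = 12)
  expect_identical(dim(X), c(68L, 48L))
  expect_identical(rownames(X), coh$subject_ids)
  i <- 7
  fields <- lapply(stats::setNames(nm = names(coh$fields)), function(s)
    deformity_field(coh$subject_ids[i], s, coh$fields[[s]][i, ]))
  fv <- assemble_feature(fields, "combined", geom$bases, 12)
  expect_equal(X[i, ], fv, tolerance = 1e-12)
  # CSV round trip
  path <- tempfile(fileext = ".csv")
  write_feature_csv(X, path)
  X2 <- read_feature_csv(path)
  expect_equal(X2, X, tolerance = 1e-12)
})

test_that("goodness-of-fit cut-off captures the target energy fraction", {
  b <- fix_basis("hippocampus_L", 2)
  # field living entirely in the first 8 modes is captured by N_c <= 8
  set.seed(8)
  x <- mht_inverse(rnorm(8), b)
  expect_lte(choose_cutoff(list(x), b, 0.9), 8)
  # white noise needs many modes: the cut grows with the target fraction
  bf <- cached("basis_full_amyL", compute_harmonics(fix_template("amygdala_L", 2), 162))
  z <- rnorm(162)
  expect_gt(choose_cutoff(list(z), bf, 0.9), choose_cutoff(list(z), bf, 0.3))
})
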