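#' Synthetic structure templates (scaled icospheres)
#'
#' Builds a genus-0 template mesh for a subcortical structure by subdividing
#' an icosahedron (vertex count 10 * 4^s + 2), projecting to the unit
#' sphere, and scaling anisotropically to structure-like proportions:
#' hippocampus-like 20 x 10 x 8 mm extents, amygdala-like 12 x 10 x 9 mm.
#' These are geometric stand-ins with the right size, topology and mesh
#' quality, not anatomical atlases.
#'
#' @param structure_tag see [structure_tags()].
#' @param subdivision_level icosphere subdivisions, >= 2 (default 3: 642
#'   vertices).
#' @param semi_axes optional length-3 override of the ellipsoid semi-axes (mm).
#' @return a [triangle_mesh()].
#' @export
make_template <- function(structure_tag, subdivision_level = 3, semi_axes = NULL) {
  if (subdivision_level < 2) stop("subdivision_level must be >= 2")
  if (is.null(semi_axes)) {
    semi_axes <- if (grepl("^hippocampus", structure_tag)) c(10, 5, 4) else c(6, 5, 4.5)
  }
  ico <- icosphere(subdivision_level)
  triangle_mesh(sweep(ico$vertices, 2, semi_axes, `*`), ico$faces, structure_tag)
}

icosphere <- function(level) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(level)) {
    nv <- nrow(v)
    edge_mid <- new.env(hash = TRUE)
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    verts <- list(v)
    next_id <- nv
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- edge_mid[[key]]
      if (is.null(id)) {
        next_id <<- next_id + 1L
        verts[[length(verts) + 1L]] <<- (v[i, ] + v[j, ]) / 2
        edge_mid[[key]] <- next_id
        id <- next_id
      }
      id
    }
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c_ <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newf[4 * t - 3, ] <- c(a, ab, ca)
      newf[4 * t - 2, ] <- c(b, bc, ab)
      newf[4 * t - 1, ] <- c(c_, ca, bc)
      newf[4 * t, ]     <- c(ab, bc, ca)
    }
    v <- do.call(rbind, c(list(v), verts[-1]))
    f <- newf
    v <- v / sqrt(rowSums(v^2))
  }
  v <- v / sqrt(rowSums(v^2))
  list(vertices = v, faces = f)
}

#' Specify a synthetic cohort
#'
#' Parameters of the generative model for per-subject deformity fields:
#' group sizes mirror the clinical cohort (45 PiB(-) / 23 PiB(+)); the
#' PiB(+) group carries a spatially smooth planted mean effect; every
#' subject adds a smooth random field (harmonic coefficients with variance
#' decaying with eigenvalue, i.e. a squared-exponential spectral profile
#' with correlation length `smooth_length` mm) plus white vertex noise.
#'
#' @param n_negative,n_positive group sizes (>= 2 each; defaults 45 / 23).
#' @param structures structure tags simulated (default all four).
#' @param effect_structures structures carrying the group effect (default:
#'   all simulated structures, i.e. bilateral effects).
#' @param effect_pattern `"harmonic"` (random low-order harmonic mixture) or
#'   `"patch"` (spectrally smoothed geodesic patch indicator).
#' @param effect_amplitude planted effect size in mm; with `"harmonic"` this
#'   is the mass-weighted RMS of the mean-difference field, with `"patch"`
#'   the mean outward displacement over the patch. Default 1.0 mm = twice
#'   the subject-level smooth noise SD.
#' @param smooth_sd subject-level smooth random-field SD in mm (default 0.5).
#' @param smooth_length correlation length of the smooth field in mm
#'   (default 5).
#' @param vertex_sd white per-vertex noise SD in mm (default 0.2).
#' @param patch_radius Euclidean radius of the `"patch"` effect seed region
#'   in mm (default 3.5, a focal subregion covering roughly a tenth of a
#'   structure's surface).
#' @param subdivision_level template resolution (default 3: 642 vertices).
#' @param seed integer seed; cohorts are pure functions of (spec, seed).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_negative = 45, n_positive = 23,
                        structures = setdiff(structure_tags(), "other"),
                        effect_structures = structures,
                        effect_pattern = c("harmonic", "patch"),
                        effect_amplitude = 1.0,
                        smooth_sd = 0.5, smooth_length = 5, vertex_sd = 0.2,
                        patch_radius = 3.5, subdivision_level = 3, seed = 1) {
  if (n_negative < 2 || n_positive < 2) stop("need >= 2 subjects per group")
  if (effect_amplitude < 0 || smooth_sd < 0 || vertex_sd < 0)
    stop("amplitude and noise SDs must be >= 0")
  structure(list(n_negative = n_negative, n_positive = n_positive,
                 structures = match.arg(structures, structure_tags(), several.ok = TRUE),
                 effect_structures = effect_structures,
                 effect_pattern = match.arg(effect_pattern),
                 effect_amplitude = effect_amplitude,
                 smooth_sd = smooth_sd, smooth_length = smooth_length,
                 vertex_sd = vertex_sd, patch_radius = patch_radius,
                 subdivision_level = subdivision_level, seed = seed),
            class = "cohort_spec")
}

#' Templates and harmonic bases for a cohort spec
#'
#' Convenience constructor of the per-structure templates and their
#' manifold-harmonic bases at the spec's resolution.
#'
#' @param spec a [cohort_spec()].
#' @param K number of eigenpairs per basis (default 80).
#' @return list with `templates` and `bases`, both named by structure tag.
#' @export
cohort_geometry <- function(spec, K = 80) {
  templates <- stats::setNames(
    lapply(spec$structures, make_template, subdivision_level = spec$subdivision_level),
    spec$structures)
  bases <- lapply(templates, compute_harmonics, K = K)
  list(templates = templates, bases = bases)
}

# group-mean effect pattern on one structure's template (unit amplitude)
effect_pattern_field <- function(spec, template, basis, rng) {
  if (spec$effect_pattern == "harmonic") {
    n_harm <- min(8L, basis$K - 1L)
    gamma <- rng$rnorm(n_harm) * exp(-basis$eigenvalues[1 + seq_len(n_harm)] *
                                       spec$smooth_length^2 / 4)
    pat <- as.numeric(basis$eigenvectors[, 1 + seq_len(n_harm), drop = FALSE] %*% gamma)
    rms <- sqrt(sum(basis$mass * pat^2) / sum(basis$mass))
    list(values = pat / rms, support = which(abs(pat / rms) >= stats::quantile(abs(pat / rms), 0.9)))
  } else {
    seed_vertex <- which.max(template$vertices[, 1])
    d <- sqrt(rowSums(sweep(template$vertices, 2,
                            template$vertices[seed_vertex, ])^2))
    patch <- as.numeric(d <= spec$patch_radius)
    n_smooth <- min(30L, basis$K)
    sm <- mht_inverse(mht_forward(patch, basis, n_smooth), basis)
    sm <- pmax(sm, 0)
    sm <- sm / mean(sm[patch > 0])    # unit mean displacement over the patch
    list(values = sm, support = which(patch > 0))
  }
}

#' Simulate a cohort of deformity fields
#'
#' Generates per-subject, per-structure deformity fields: group mean (zero
#' for PiB(-); the planted pattern scaled by `effect_amplitude` for PiB(+))
#' + smooth subject random field + white vertex noise. Bilateral structure
#' pairs share the planted pattern (the left/right templates are congruent).
#' Fully reproducible from the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @param geometry result of [cohort_geometry()] (built from `spec` if omitted).
#' @return An object of class `shape_cohort`: `fields` (named list of
#'   subjects x vertices matrices), `labels` (factor), `subject_ids`,
#'   `effects` (per-structure list with `values` in mm and `support` vertex
#'   indices), `spec`, `geometry`.
#' @export
simulate_cohort <- function(spec, geometry = NULL) {
  if (is.null(geometry)) geometry <- cohort_geometry(spec)
  rng <- rng_stream(spec$seed)
  n <- spec$n_negative + spec$n_positive
  labels <- factor(rep(pib_levels(), c(spec$n_negative, spec$n_positive)),
                   levels = pib_levels())
  subject_ids <- sprintf("s%03d", seq_len(n))
  # one pattern per structure "kind" so bilateral pairs match
  kind <- sub("_[LR]$", "", spec$effect_structures)
  patterns <- list()
  fields <- list()
  effects <- list()
  for (s in spec$structures) {
    basis <- geometry$bases[[s]]
    template <- geometry$templates[[s]]
    V <- nrow(basis$eigenvectors)
    eff <- numeric(V); support <- integer(0)
    if (s %in% spec$effect_structures && spec$effect_amplitude > 0) {
      k <- sub("_[LR]$", "", s)
      if (is.null(patterns[[k]]))
        patterns[[k]] <- effect_pattern_field(spec, template, basis, rng)
      eff <- spec$effect_amplitude * patterns[[k]]$values
      support <- patterns[[k]]$support
    }
    # smooth subject-level field: harmonic coefficients with decaying variance
    sig2 <- exp(-basis$eigenvalues * spec$smooth_length^2 / 2)
    sig2 <- sig2 / sum(sig2) * spec$smooth_sd^2 * sum(basis$mass)
    gamma <- matrix(rng$rnorm(n * basis$K), n, basis$K) *
      rep(sqrt(sig2), each = n)
    Xs <- gamma %*% t(basis$eigenvectors)
    Xs <- Xs + matrix(rng$rnorm(n * V, sd = spec$vertex_sd), n, V)
    Xs[labels == "PiB_positive", ] <-
      sweep(Xs[labels == "PiB_positive", , drop = FALSE], 2, eff, `+`)
    rownames(Xs) <- subject_ids
    fields[[s]] <- Xs
    effects[[s]] <- list(values = eff, support = support)
  }
  structure(list(fields = fields, labels = labels, subject_ids = subject_ids,
                 effects = effects, spec = spec, geometry = geometry),
            class = "shape_cohort")
}

#' @export
print.shape_cohort <- function(x, ...) {
  cat(sprintf("shape_cohort: %d PiB(-) + %d PiB(+) subjects, structures: %s\n",
              sum(x$labels == "PiB_negative"), sum(x$labels == "PiB_positive"),
              paste(names(x$fields), collapse = ", ")))
  invisible(x)
}

#' Voxelized segmentations of simulated subject surfaces
#'
#' Displaces each structure template along its outward normals by the
#' subject's deformity field and voxelizes the resulting surface on a grid
#' shared across subjects. Subjects whose displaced surface fails
#' validation or voxelization (e.g. self-intersection) are skipped with a
#' warning.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param structure structure tag to voxelize.
#' @param spacing voxel spacing in mm (default 0.5).
#' @param subjects subject ids (default: all).
#' @return named list of [voxel_grid()]s.
#' @export
simulate_segmentations <- function(cohort, structure, spacing = 0.5,
                                   subjects = cohort$subject_ids) {
  template <- cohort$geometry$templates[[structure]]
  if (is.null(template)) stop("cohort has no structure ", structure)
  nrm <- vertex_normals(template)
  fields <- cohort$fields[[structure]]
  margin <- max(abs(fields[subjects, , drop = FALSE])) + 2 * spacing
  lo <- apply(template$vertices, 2, min) - margin
  hi <- apply(template$vertices, 2, max) + margin
  shape <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  out <- list()
  for (sid in subjects) {
    verts <- template$vertices + fields[sid, ] * nrm
    grid <- tryCatch({
      mesh <- triangle_mesh(verts, template$faces, structure)
      withCallingHandlers(
        voxelize(mesh, spacing, origin = lo, shape = shape),
        warning = function(w) stop(conditionMessage(w)))
    }, error = function(e) {
      warning(sprintf("skipping subject %s (%s): %s", sid, structure,
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(grid)) out[[sid]] <- grid
  }
  out
}

#' Simulate regional PiB uptake tables
#'
#' Draws per-subject 28-VOI uptake tables whose global retention ratio is
#' above 1.5 for positives and below for negatives by construction, so that
#' recomputing labels through [global_pib_ratio()] + [assign_pib_label()]
#' reproduces the generation truth exactly.
#'
#' @param n_subjects number of subjects.
#' @param positive_fraction fraction of PiB(+) subjects in \[0, 1\].
#' @param seed integer seed.
#' @return list with `tables` (list of [uptake_table()]s), `labels`,
#'   `ratios` (the constructed global ratios).
#' @export
simulate_suvr_tables <- function(n_subjects, positive_fraction = 23 / 68, seed = 1) {
  if (positive_fraction < 0 || positive_fraction > 1)
    stop("positive_fraction must be in [0, 1]")
  rng <- rng_stream(seed)
  n_pos <- round(n_subjects * positive_fraction)
  labels <- rep(c("PiB_negative", "PiB_positive"),
                c(n_subjects - n_pos, n_pos))
  voi_names <- as.vector(outer(
    c("frontal_sup", "frontal_mid", "frontal_med", "frontal_orb", "rectus",
      "olfactory", "cingulum_post", "parietal_sup", "parietal_inf",
      "supramarginal", "angular", "precuneus", "temporal_lat", "occipital"),
    c("L", "R"), paste, sep = "_"))
  tables <- vector("list", n_subjects)
  ratios <- numeric(n_subjects)
  for (i in seq_len(n_subjects)) {
    target <- if (labels[i] == "PiB_positive") rng$runif(1, 1.6, 2.4)
              else rng$runif(1, 1.0, 1.4)
    vol <- rng$runif(28, 5, 25)
    suvr <- pmax(0.2, target + rng$rnorm(28, sd = 0.15))
    suvr <- suvr * target / (sum(vol * suvr) / sum(vol))  # pin the global ratio
    ref <- rng$runif(1, 0.8, 1.2)
    tables[[i]] <- uptake_table(
      data.frame(voi_name = voi_names, mean_suv = suvr * ref, volume_ml = vol),
      ref)
    ratios[i] <- target
  }
  list(tables = tables, labels = labels, ratios = ratios)
}
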