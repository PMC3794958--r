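---
title: "Subcortical shape deformity, manifold harmonics and incremental PCA-LDA classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subcortical shape deformity, manifold harmonics and incremental PCA-LDA classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subshape)
```

## The problem

Subcortical vascular dementia (SVaD) frequently co-occurs with
Alzheimer-type amyloid pathology ("mixed dementia"). The two phenotypes
call for different management, but amyloid PET is short-lived, expensive
tracer chemistry and CSF sampling is invasive. The hippocampus and
amygdala are affected early by amyloid pathology, so their shape on
routine structural MRI is a candidate non-invasive marker. `subshape`
implements an individual-subject classifier of amyloid status from the
surface shape of those four structures (left/right hippocampus and
amygdala), together with the machinery to validate it: surface fitting
with built-in vertex correspondence, spectral low-pass feature extraction,
a PCA+LDA discriminant with exact incremental updating, cross-validated
and permutation-tested evaluation, and back-projected discriminative
maps.

## The model, stage by stage

### Shape representation

Shape is encoded as a *deformity field*: for a subject surface in vertex
correspondence with its structure template, the signed displacement of
each vertex along the template's outward unit normal,
$x_i = (v_i - u_i)\cdot n_i$ (mm; atrophy is negative). Correspondence
comes for free from the fitting stage: `laplacian_deform()` deforms the
template onto the subject's binary segmentation without ever touching the
face list. Each outer iteration solves, per coordinate, the regularised
least-squares system

$$(\alpha^2 S^\top S + w_t I)\,v \;=\; \alpha^2 S^\top \delta + w_t c,$$

where $S$ is the template's cotangent stiffness matrix,
$\delta = S\,u$ the template's differential coordinates (the shape
memory), and $c$ the per-vertex nearest points on the segmentation
boundary (centres of occupied-to-empty voxel faces — no surface
extraction of the target is needed). The constraint weight $w_t$ ramps up
linearly over iterations so the mesh settles globally before locking onto
the boundary. Fits are validated by voxelizing the result back
(`voxelize()`, parity of ray crossings at voxel centres with a fixed
sub-voxel ray offset to break ties deterministically) and intersecting
with the input segmentation: on simulated segmentations at 0.5 mm spacing
the overlap exceeds 0.90 and planted fields are recovered with vertex-wise
correlation above 0.8 (see `tests/testthat/test-acceptance.R`, which
computes both).

Brain-size correction is similarity Procrustes (`similarity_align()`) on
the corresponded vertices, applied per structure before projecting onto
the normals. Per-structure (rather than whole-brain) normalisation is a
deliberate choice: intracranial volume does not exist for synthetic
cohorts, the closed-form Procrustes solution is deterministic and
testable, and the alternative — carrying a global scale through the
pipeline — changes nothing downstream of the spectral projection. The
order of operations (align first, then project onto template normals) is
likewise fixed and documented here because only that order makes the
field exactly zero for a subject that is a similarity transform of its
template.

### Manifold harmonic features

Per-vertex fields are high-dimensional (thousands of correlated values)
and noisy. Disease effects, by contrast, are spatially coherent: nearby
vertices deform together. The natural basis for "smooth on this surface"
is the spectrum of the surface's own Laplace–Beltrami operator,
discretised as cotangent stiffness $S$ with barycentric lumped mass $M$
(the standard manifold-harmonics construction; the mass weights make the
basis independent of triangle sizing). Solving $S\phi_k = \lambda_k M
\phi_k$ gives a mass-orthonormal basis ordered by spatial frequency;
`mht_forward()` projects a field to coefficients
$\beta_k = \sum_i m_i \phi_k(i) x_i$ and truncation at a cut-off $N_c$ is
the optimal low-pass filter. We use the mass-weighted inner product (the
standard choice; plain Euclidean projection would not be orthogonal in
the surface metric and would break Parseval). Eigenvector signs are fixed
by making the largest-magnitude entry positive (ties to the lowest vertex
index) so serialized features are reproducible across platforms and BLAS
libraries.

The default cut-off is $N_c = 70$ coefficients per structure.
`choose_cutoff()` implements the goodness-of-fit alternative: the
smallest $N_c$ whose reconstructions capture a target fraction (default
0.9) of field energy averaged over training subjects. Feature vectors
concatenate structures in the fixed order hippocampus L, hippocampus R,
amygdala L, amygdala R; the hippocampal, amygdalar and combined feature
sets are the three natural column subsets. Coefficients are deliberately
*not* standardised before PCA, and PCA is fit separately per feature set.

### PCA + LDA with exact incremental updating

With tens of subjects and hundreds of coefficients the pooled
within-class scatter is singular, so LDA is preceded by PCA keeping the
smallest number of components whose cumulative variance reaches 70%
(`fit_pca()`; the threshold is the `variance_fraction` argument
everywhere). The discriminant is Fisher's axis
$w \propto S_w^{-1}(\mu_+-\mu_-)$, unit-normalised, with the decision
threshold at the midpoint of the projected class means. The midpoint
(prior-free) threshold is chosen because the clinical posture is
screening: with unbalanced classes (45 negative / 23 positive) a
prior-weighted cut would sacrifice sensitivity for specificity; a
`threshold = "prior"` option provides the alternative. Scores tie-break
toward PiB(+) for the same reason.

Training never stores raw data: the state keeps per-class counts, feature
sums and raw cross-product matrices. Every update
(`update_incremental()`) adds a batch to these accumulators and re-derives
PCA (from the pooled scatter) and LDA (class means and within-class
scatter projected into the new subspace). Because the accumulators are
exact, a classifier that has absorbed any partition of the data in any
order is prediction-equivalent to batch training on the union — the
property the test suite asserts over random partitions, and the reason
the learning curve's final point coincides exactly with the batch
accuracy. An approximate eigenspace-merging scheme would be cheaper at
very high dimension but only *converge* to the batch solution; at the
few-hundred feature dimensions used here exactness costs little
($p \times p$ accumulators) and buys a testable contract.

### Evaluation

`run_cv()` performs stratified k-fold cross-validation (default 10-fold;
`k = n` is leave-one-out). Stratification preserves the 45/23 imbalance
in every fold, preventing training partitions from losing a class. All
headline metrics are computed from the pooled out-of-fold predictions
(not by averaging fold-wise metrics), which keeps them expressible as
integer confusion counts. ROC and AUC use pooled decision scores; AUC is
computed as the Mann–Whitney pair-win fraction with ties counting one
half, which the tests check against brute-force pair counting and against
pROC.

`learning_curve()` emulates steady data accrual: for each of `n_orders`
(default 500) random orderings of the training subjects, batches of
`batch_size` (default 10) are absorbed incrementally, scoring the full
test set after every batch; accuracies are averaged per training-set
size.

`permutation_test()` assesses significance of the CV accuracy: training
labels are permuted before training, held-out folds are always scored
against true labels, and the add-one estimator
$p = (1+\#\{\text{null} \ge \text{obs}\})/(1+B)$ is used (at
$B = 10{,}000$ a single exceedance gives $p = 0.0002$, which is why the
add-one rule is the consistent choice). Two implementation facts are
worth recording: the fold assignment is held fixed across permutations,
and since PCA is label-independent the per-fold PCA projections are
computed once with only the LDA refit per permutation — the statistic is
identical to a full rerun, at a small fraction of the cost. Calibration
is verified empirically: across 200 null cohorts with 199 permutations
each, the fraction of $p < 0.05$ falls in [0.02, 0.08].

### Discriminative maps

`backproject_axis()` maps the LDA axis back to vertex space: through the
PCA components into coefficient space, split into per-structure blocks,
then through the inverse harmonic transform onto each template. Each map
is normalised to unit Euclidean norm for display; the pre-normalisation
squared norm of each coefficient block, as a fraction of the axis' total,
is reported as that structure's *energy share* (the shares sum to one
exactly, because the harmonic synthesis is mass-orthonormal). We
normalise per structure — four maps for the combined feature set — rather
than per hemisphere, since the feature sets mix structures; the energy
shares preserve the cross-structure comparability that per-structure
normalisation would otherwise hide. No vertex-wise significance
thresholds are drawn: the map shows where the classifier looks, not which
group deforms where.

### Amyloid labels

`global_pib_ratio()` computes the volume-weighted average SUVR over the
(nominally 28) cortical VOIs against the cerebellar-cortex reference, and
`assign_pib_label()` applies the strict threshold: PiB(+) iff ratio
> 1.5, a ratio of exactly 1.5 being negative. VOI volumes (ml), not voxel
counts, are the weights; the ratio is invariant to rescaling all uptakes
by a common factor.

## The synthetic cohort generator

No clinical data of this kind are deposited anywhere, so the generator is
first-class, tested code rather than a fixture. `make_template()` builds
genus-0 templates by icosphere subdivision scaled to structure-like
extents (hippocampus 20×10×8 mm, amygdala 12×10×9 mm); these are
geometric stand-ins with the right size, topology and mesh quality, not
anatomical atlases. The default resolution is subdivision level 3 (642
vertices per structure; the level is configurable and the tests run at
level 2, 162 vertices, for speed — problem sizes chosen as the smallest
at which every property under test is non-trivial).

`simulate_cohort()` draws, per structure,

* a **group effect** added to the PiB(+) subjects: either a random
  mixture of low-order harmonics (spatially coherent, bilateral by
  default since left/right templates are congruent) scaled to a
  mass-weighted RMS of `effect_amplitude` mm, or a spectrally smoothed
  focal patch whose mean displacement over the patch equals the
  amplitude;
* a **smooth subject-level random field**: harmonic coefficients with a
  squared-exponential variance profile
  $\sigma_k^2 \propto e^{-\lambda_k \ell^2/2}$ (correlation length
  $\ell$ = 5 mm), normalised so the expected per-vertex SD is
  `smooth_sd`;
* **white vertex noise** with SD `vertex_sd`.

Defaults are 45 PiB(−) / 23 PiB(+) (the clinical imbalance, which is what
exercises the sensitivity/specificity asymmetry), `smooth_sd` = 0.5 mm and
`vertex_sd` = 0.2 mm (sub-millimetre biological variability plus
segmentation jitter, the scale reported for subcortical surface studies),
and `effect_amplitude` = 1.0 mm — twice the smooth noise SD, a strong but
not degenerate group difference. The focal-patch radius defaults to
3.5 mm so the planted region covers roughly a tenth of the structure
surface, matching the top-decile read-out used when testing region
recovery; a larger patch would make decile-based recall arithmetically
impossible regardless of map quality. `simulate_segmentations()` closes
the loop for the geometric front-end by voxelizing each subject's
displaced surface, and `simulate_suvr_tables()` generates 28-VOI uptake
tables whose recomputed labels match the generation truth exactly.

What the generator does **not** emulate: anatomical subfield geometry
(CA1, subiculum, amygdalar nuclei), asymmetric or spatially non-stationary
noise, segmentation bias fields, scanner site effects, and any coupling
between shape and covariates (age, lesion load). Passing tests therefore
demonstrate the correctness and statistical calibration of the machinery
under its own assumptions — not clinical accuracy on real cohorts, which
can only be established on real data.

## Numerical choices and degenerate inputs

* Cotangent weights of obtuse triangle pairs are kept as-is (negative
  weights are allowed). The default anisotropic templates carry ~15%
  non-Delaunay edges by construction without measurable effect on the
  low-order spectrum; `build_laplacian()` returns the fraction and warns
  only beyond 25%.
* The generalized eigenproblem is solved densely via the symmetric
  similarity transform $M^{-1/2} S M^{-1/2}$ (LAPACK); at template
  resolutions up to a few thousand vertices this is faster and more robust
  than iterative sparse solvers, and exact mass-orthonormality is restored
  by construction.
* Meshes must be closed orientable genus-0 2-manifolds; validation names
  the offending edge. Inside-out but consistently wound meshes are
  re-oriented with a message instead of rejected.
* Voxel membership is decided at voxel centres; ray origins carry a fixed
  sub-voxel offset (3.7e-4 / 4.1e-4 of a voxel) so rays through vertices
  or edges cannot produce ambiguous parities; columns that still produce
  an odd crossing count (numerically degenerate or self-intersecting
  surfaces) are left empty with a warning.
* PCA's cumulative-variance cut uses a 1e-9 tolerance so that exact
  fractions (e.g. ten equal variances at a 0.70 target) keep the intended
  component count under floating-point arithmetic.
* `fit_lda()` fails with advice (lower `variance_fraction`) when the
  pooled scatter is singular, e.g. perfectly separated classes with zero
  within-class variance.
* All stochastic procedures take explicit integer seeds and use an
  isolated RNG stream, so library calls never perturb the caller's
  `.Random.seed` and identical seeds give bit-identical outputs.

## Known limitations

* Templates are ellipsoidal stand-ins; anatomical subregion naming on the
  maps is out of scope.
* The surface-fitting front-end assumes rigid pre-positioning of the
  template over the target and a single connected segmentation component;
  it performs no rigid initialisation of its own.
* Only two-class problems are supported; no kernelised or regularised
  discriminants.
* The incremental scheme is exact accumulation, not streaming eigenspace
  merging; memory grows with the square of the feature dimension, which
  is irrelevant at $N_c \le$ a few hundred but would not scale to raw
  vertex-space features.
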