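---
title: "Methods: an SDF autodecoder morphospace for bill-like shapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an SDF autodecoder morphospace for bill-like shapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(beakmorph)
```

This vignette is the package's own account of its models, its synthetic
data, the numerical choices behind both, and what the test suite does
and does not establish.

## 1. The shape representation

A 3D surface is represented implicitly by its signed distance function
(SDF): the map from any point `x` to its distance from the nearest
surface point, negative inside and positive outside.  The surface is
the zero level set.  One decoder network `f_θ(z, x)` approximates the
SDFs of a whole collection of shapes at once, with an `d`-dimensional
latent code `z_i` identifying specimen `i`.  There is no encoder: the
codes are free parameters estimated jointly with `θ` (an *autodecoder*).
MAP estimation under a spherical Gaussian prior on the codes yields

\[
Q = \sum_{ij} \bigl|\mathrm{clamp}(s_{ij},\delta) -
\mathrm{clamp}(f_\theta(z_i, x_{ij}),\delta)\bigr| \;+\;
\lambda \sum_i \lVert z_i \rVert_2^2 ,
\]

where `clamp(x, δ) = min(δ, max(−δ, x))`.  Only the ratio of the noise
and prior variances is identifiable; it is exposed as the single
penalty weight `lambda`.  Clamping (default δ = 0.1, in unit-sphere
units) concentrates the fit near the zero isosurface, which alone
determines the reconstructed shape.

**Architecture.** Two chained 3-layer perceptrons.  Module 1 maps the
concatenated `(z, x)` (width d + 3) through ReLU layers of
`hidden_size` units; module 2 receives module 1's output concatenated
again with `(z, x)` (a skip connection) and emits one value through a
tanh output.  Defaults are `hidden_size = 512`, `d = 64`, matching the
full-scale model; the desk-scale examples use 64 and 8 (or 4).  Choices
the architecture description leaves open and how they were fixed:
ReLU/tanh activations follow the architecture's published ancestor; the
output layer is initialized with a small weight scale (sd
`0.01/sqrt(h)`) so initial predictions start inside the clamp band —
with a conventional initialization the tanh saturates outside ±δ and
the clamped loss has zero gradient everywhere, so nothing trains.

**Optimization.** Adam with separate learning rates for weights
(default 1e-4; the desk-scale runs use 5e-4) and codes (1e-3; desk
5e-3), minibatch SGD over pooled SDF rows.  Codes are initialized from
N(0, 0.01²) so the prior dominates early.  The per-shape penalty enters
once per minibatch containing rows of that shape, matching the
minibatch expectation of the objective.  All gradients are hand-derived
and verified against central finite differences in the test suite.
Training, sampling and embedding are exactly reproducible under a fixed
seed because every RNG draw is sequenced from `config$seed`.

## 2. Geometry

Meshes are plain vertex/face matrices with three named landmarks (tip,
base top, base bottom).  The preprocessing pipeline mirrors a
scan-cleaning workflow in four steps:

1. **clean** — merge duplicate vertices (quantized at 1e-9), drop
   degenerate and duplicate faces, remove connected components below 1%
   of faces (scanner-debris heuristic), and fail loudly on non-manifold
   edges.  A full self-intersection test is not performed; the validity
   check is edge-manifoldness plus consistent orientation.
2. **reorient** — a rigid map (rotation with determinant +1 plus
   translation, never scaling or reflection) sending base-center→tip to
   +x and the base bottom→top component to the x–z plane.
3. **trim and cap** — the minimal sphere enclosing five bill hull
   points (tip, upper/lower base landmarks, extreme left/right vertices
   within a base slab 5% of the length) is computed exactly by brute
   force over support subsets of up to four points; geometry outside is
   removed, faces crossing the sphere are cut at the sphere (each cut
   edge solved as a segment–sphere quadratic, shared between
   neighbouring faces so the seam is watertight), and each boundary
   loop is closed by a fan to the loop centroid projected onto the
   sphere.  Cutting at the sphere rather than dropping whole faces
   gives a clean cap seam; this is a declared interpretation, since
   "trimming with an enclosing sphere" does not itself specify the
   treatment of crossing faces.
4. **normalize** — center at the bounding-box midpoint and scale so the
   farthest vertex sits on the unit sphere; scale and center are
   returned so reconstructions can be mapped back to model units.

The signed distance to a mesh is computed exactly per face (interior
projection plus edge clamping) with the sign from the generalized
winding number, which stays robust for near-degenerate caps.  Inside
points have winding number near 1, outside near 0; the 0.5 threshold
decides the sign.

**Isosurface extraction** uses the marching-tetrahedra variant of
marching cubes: each cell of the (cell-centered) lattice is split into
six tetrahedra by the Kuhn subdivision, whose shared face diagonals
agree between neighbouring cells, so the extracted surface is
watertight by construction wherever the level set stays inside the
grid — the classic 256-case cube table has ambiguous configurations
that can leak holes, and nothing in the environment provides a vetted
implementation.  Triangle orientation is fixed per tetrahedron by
pointing normals away from the interior lattice point.  Lattice values
exactly equal to the isovalue are nudged by a relative 1e-12 so
interpolation parameters stay in (0, 1).  Default reconstruction
resolution is 128³ at full scale; the tests use 32–64³.

**Chamfer distance** draws area-uniform surface samples from each mesh
with the *same* seed and averages nearest-neighbour distances in both
directions, making the metric exactly symmetric in its arguments.

## 3. The synthetic populations

`make_beak_mesh` builds a watertight beak from six parameters: a
tapered body with elliptical cross-sections (radius profile
`(1 − t)^{0.65}` from base to tip), an ellipsoidal base cap occupying
8% of the length, a dorsal centerline bend `curvature · depth · t²`,
and a tip downturn `hook · depth · t⁵` with hook in [0, 1].  After
construction the mesh is rotated into canonical pose and rescaled
per-axis so the bounding extents equal (length, width, depth)
*exactly*; curvature and hook therefore change shape at fixed extents.
The cap is kept shallower than the rear-10% measurement slab (below) so
measured width and depth equal the nominal values.  Landmarks are
emitted analytically.  Ring counts scale with `resolution`; volume
converges to better than 1% between resolutions 64 and 128.

Three canned study populations define the package's study conditions:

* `elongation_series_params(n)` — length uniform on 2–6 model units,
  width and depth near 1 (sd 0.08), mild curvature (U(0, 0.15)) and
  hook (U(0, 0.3)).  This is the substrate for the overfit and
  morphospace experiments; elongation is the dominant axis of
  variation, as it is in comparative bill data.
* `niche_demo_spec()` — three classes of 15: a distinct class (long,
  narrow, curved; the nectarivore archetype) and two heavily
  overlapping generalist classes whose parameter distributions differ
  only slightly, emulating the published pattern that one niche is
  morphologically unmistakable while two others blur into each other.
  Class means/SDs are free choices; no quantitative per-niche variance
  data exist to estimate them from.
* `simulate_clade()` — pure-birth (Yule) trees via exponential waiting
  times, with traits evolved by Brownian motion along each edge.  Size
  traits evolve on the log scale and are exponentiated, the standard
  comparative-methods device for keeping sizes positive.  One RNG draw
  per edge keeps replays bit-identical under a fixed seed.

What the generator does *not* emulate: nares, ornaments, rhamphotheca
texture, scan noise, landmark placement error, or asymmetry.  Passing
tests therefore establish that the pipeline's machinery is correct and
that its claims hold when their assumptions hold — not that a model
trained on real scans would reach any particular accuracy.

## 4. Desk-scale experiments and their sizes

Problem sizes were chosen so the full suite trains three models on one
CPU in well under half an hour while leaving comfortable margins on
every property:

* **Overfit model** — 10 beaks, 1,500 SDF rows each (750 uniform + 750
  near-surface, jitter sd 0.01), latent dim 8, hidden 64, 250 epochs ×
  8 minibatches = 2,000 optimizer steps.  Final mean clamped error is
  about 0.002 (band 0.01), and reconstruction chamfer at 64³ is
  0.015–0.03 for all ten shapes (threshold 0.05).
* **Morphospace model** — 30 beaks, latent dim 4, 220 epochs.  The
  lower latent dimension is deliberate: with ten to thirty specimens an
  8-d code table leaves the no-intercept regression nearly saturated
  (n barely exceeds d), and the fitted direction picks up unconstrained
  off-manifold components along which the decoder's behaviour is
  arbitrary.  At d = 4 the direction is well determined and traversal
  behaves.  Traversal draws start from the empirical Gaussian of the
  trained codes (mean and per-dimension sd) — at desk scale the code
  distribution *is* the model's prior-scale information — and step
  ±1 code-sd·√d along the unit direction.  Monotonicity of measured
  elongation is assessed with a tolerance of 0.05, the scale of the
  voxel quantization of mesh extents at the 40³ reconstruction
  resolution used.
* **Niche pipeline** — 45 beaks (3 × 15), latent dim 8, 180 epochs,
  then a class-weighted random forest tuned by Monte-Carlo
  cross-validation.  Per-class sensitivities are pooled over five
  repeats of the stratified 20% holdout protocol: a single 9-specimen
  holdout would make per-class sensitivity a three-coin-flip estimate,
  while the pooled confusion matrix rests on 15 test members per class.

## 5. Second-stage conditional VAE

The CVAE is trained on the code table with one-hot label conditioning
concatenated to both encoder and decoder inputs (the conditioning
mechanism and the 2 × 128 hidden layers are declared defaults; nothing
in the source architecture pins them).  The reconstruction term is a
Gaussian log-density with a single trainable variance γ (optimized as
log γ), which balances reconstruction against the KL term; on
linear-Gaussian data with known observation noise the trained γ
recovers the noise variance within a factor of two.  Log-variances are
clamped to ±10 for numerical safety.  The stage-2 posterior means of
heavy-tailed stage-1 codes conform substantially better to a Gaussian
(lower mean |excess kurtosis|), the two-stage property that motivates
using the CVAE for generation: class-conditional samples are standard
normal draws decoded with the class label, and can be chained through
the SDF decoder to produce meshes.

## 6. Ecology and phylogenetics

**Weights and evaluation.** Each observation in class j carries weight
1/n_j, so classes contribute equally to training regardless of size.
Balanced accuracy is the macro average over classes of
(sensitivity + specificity)/2 in one-vs-rest form.  Hyperparameters are
selected on mean validation balanced accuracy across 20 Monte-Carlo
splits, each holding out a stratified 20% of the training data
(balanced accuracy as the selection metric is a declared default; the
protocol's source names only the metric set used for final
evaluation).  Random-forest and elastic-net solvers are delegated to
ranger and glmnet; the package owns weighting, splitting, selection and
evaluation.

**Phylogenetic signal.** Blomberg's K is implemented from its
definition: the ratio of the observed to the Brownian-expected value of
MSE₀/MSE, with the GLS phylogenetic mean and the tree covariance C of
shared root-to-ancestor path lengths.  The multivariate K sums squared
deviations across traits in both quadratic forms and reduces exactly to
the univariate K at p = 1.  Phylogenetic PCA eigen-decomposes the
GLS-estimated evolutionary covariance; on a star tree it reduces to
ordinary PCA.  PACA rotates the column-centered data onto the right
singular basis of `t(C_c) X_c` (both column-centered), so leading axes
maximize covariation with the tree structure; it is validated by
planted-structure recovery, not against any external implementation.
Zero-length terminal branches are bumped by 1e-8 with a warning so C
stays positive definite.  In the tests, phytools serves as an
independent oracle for K and phylogenetic PCA.

**Signal-profile simulations.** Two designs emulate the contrast
between a latent space that spreads phylogenetic signal uniformly and a
PCA that concentrates it.  (i) *Shared-factor latents*: one realized
Brownian factor spread across 16 axes by random unit loadings plus
small independent noise (sd 0.05, 96 tips).  Every axis then carries
the same realized phylogenetic pattern, so the per-axis K profile is
flat; PCA of the same data concentrates the factor in the leading
component, giving K that falls across early axes.  A flat profile
*cannot* be produced by independent BM per axis: K's sampling
variability across independent realizations is ~0.3–0.5 on any
realistic tree and shrinks only slowly with tips, so a 16-axis iid
profile always has a range near 1.  (ii) *Isotropic-latent BM data*
(independent BM per axis, 48 tips) for the alignment comparison, where
the phylogenetically aligned first axis carries at least as much signal
as the first principal component, in median over 20 replicates.

**Axis removal.** Dropping the first PACA axis and re-running the full
classification protocol distinguishes label structure that rides on
phylogeny (clade-derived labels: accuracy drops) from label structure
independent of it (random labels: accuracy unchanged within noise).

## 7. Known limitations

* The decoder is trained on fixed SDF samples by default; per-epoch
  resampling is available via the `resampler` hook but not exercised at
  desk scale.
* `clean_mesh` does not detect self-intersections; watertightness and
  manifoldness are the enforced invariants.
* Isosurfaces that cross the grid boundary are returned open; callers
  should keep shapes inside the sampling cube, as the preprocessing
  pipeline guarantees.
* The 2-d embedding wrappers (uwot, Rtsne) are deterministic only under
  their single-threaded settings, which the wrapper enforces.
* No-intercept direction regression can only reproduce a response with
  nonzero mean (such as elongation) through the mean direction of the
  code cloud.  With few specimens the shrinkage prior can leave that
  mean near zero for some training seeds, collapsing the uncentered R²
  and the discovered direction even when the decoder itself has trained
  well; with hundreds to thousands of specimens the aggregate code mean
  is estimated far more stably.  Check the reported R² before trusting
  a traversal.
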