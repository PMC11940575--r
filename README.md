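# beakmorph

Generative morphometrics of bill-like 3D shapes with a signed-distance
-function (SDF) autodecoder, in R.

## The problem

Bird bills are complex 3D surfaces whose shape carries ecological
(trophic niche) and evolutionary (phylogenetic) signal, but classical
morphometrics reduces them to a handful of calipers or landmarks.
`beakmorph` implements an alternative: represent each specimen's surface
implicitly by its signed distance function — negative inside the
surface, positive outside, zero on it — and learn a single decoder
network `f_θ(z, x) ≈ SDF_i(x)` together with one latent code `z_i` per
specimen.  The codes form a continuous morphospace in which shape can be
measured, traversed, generated, classified and tested for phylogenetic
signal.

The package is aimed at desk-scale methodological work: everything runs
on one CPU, and a parametric generator of watertight beak-like meshes
(with known dimensions, class structure, and Brownian-motion trait
evolution on simulated phylogenies) stands in for scan data so every
claim is testable against known truth.

## The model

Training data are Monte-Carlo samples of each shape's SDF: points
`x_ij` with signed distances `s_ij`, drawn half uniformly in the unit
sphere and half near the surface.  Codes and weights are jointly
estimated by maximum a posteriori under a spherical Gaussian prior on
the codes, giving the penalized objective

    Q = Σ_ij | clamp(s_ij, δ) − clamp(f_θ(z_i, x_ij), δ) |  +  λ Σ_i ‖z_i‖²

with δ = 0.1: clamping both observed and predicted distances
concentrates accuracy near the zero isosurface, which alone determines
the shape.  The decoder is two chained 3-layer perceptron modules with a
skip connection re-injecting `(z, x)` into the second module (512 hidden
units and 64 latent dimensions at full scale; smaller in the desk-scale
examples).  Any code is turned back into a mesh by evaluating the
decoder on a dense grid and extracting the zero level set.

Downstream, the package provides: interpretable latent directions by
no-intercept regression of measured shape indices (elongation,
broadness) on the codes; a second-stage conditional VAE with a trainable
reconstruction variance that gaussianizes the code distribution and
generates class-conditional shapes; class-weighted (w = 1/n_class)
trophic-niche classification with Monte-Carlo cross-validation; and
phylogenetic-signal statistics (Blomberg's K, multivariate K,
phylogenetic PCA, phylogenetically aligned components).

## A worked example

```r
library(beakmorph)

# ten synthetic beaks spanning elongation 2-6, preprocessed and sampled
params  <- elongation_series_params(10, seed = 10)
samples <- prepare_sdf_samples(params, mesh_resolution = 32,
                               n_uniform = 750, seed = 100)

cfg <- train_config(latent_dim = 8, hidden_size = 64, epochs = 250,
                    batch_size = 2048, lr_theta = 5e-4, lr_z = 5e-3,
                    lambda = 1e-4, seed = 12)
fit <- train_autodecoder(samples, cfg)
fit
#> <sdf_autodecoder> 10 shapes, latent_dim 8, 250 epochs, final mean clamped error 0.00151

# reconstruct a specimen from its code and compare to the input
Z   <- codes_matrix(fit$codes)
rec <- reconstruct_mesh(fit$params, Z[1, ], resolution = 64)
target <- preprocess_mesh(make_beak_mesh(params[1, ], resolution = 32))$mesh
chamfer_distance(target, rec, 2000, seed = 1)
#> [1] 0.01804

# find the latent elongation direction
elong <- params$length / ((params$width + params$depth) / 2)
dir <- discover_vector(fit$codes, elong, "elongation")
dir
#> <latent_direction> elongation: d = 8, uncentered R^2 = 1
```

The final training error (mean per-row clamped absolute error, about
0.0015 here) says the decoder reproduces each training shape's signed
distances to well within the clamp band; the chamfer distance (mean
nearest-neighbour surface distance, unit-sphere units) of about 0.018
says the reconstructed surface sits about 2% of the shape radius from
the input surface; the regression R² near 1 says elongation is encoded
linearly in the latent space.

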