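# Desk-scale trained models are expensive; build each once per test run.
.model_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (is.null(.model_cache[[name]])) assign(name, build(), .model_cache)
  get(name, .model_cache)
}

# 10-shape overfit model: latent dim 8, 2000 optimizer steps
# (250 epochs x 8 minibatches of 2048 over 15,000 rows).
overfit_model <- function() cached("overfit", function() {
  params <- elongation_series_params(10, seed = 10)
  samples <- prepare_sdf_samples(params, mesh_resolution = 32,
                                 n_uniform = 750, seed = 100)
  cfg <- train_config(latent_dim = 8, hidden_size = 64, epochs = 250,
                      batch_size = 2048, lr_theta = 5e-4, lr_z = 5e-3,
                      lambda = 1e-4, seed = 12)
  list(fit = train_autodecoder(samples, cfg), params = params,
       samples = samples, config = cfg)
})

# 30-shape morphospace model: denser coverage of the elongation gradient
# in a compact 4-d latent space, for direction-traversal experiments.
traversal_model <- function() cached("traversal", function() {
  params <- elongation_series_params(30, seed = 10)
  samples <- prepare_sdf_samples(params, mesh_resolution = 32,
                                 n_uniform = 750, seed = 100)
  cfg <- train_config(latent_dim = 4, hidden_size = 64, epochs = 220,
                      batch_size = 3000, lr_theta = 5e-4, lr_z = 5e-3,
                      lambda = 1e-4, seed = 12)
  fit <- train_autodecoder(samples, cfg)
  elong <- params$length / ((params$width + params$depth) / 2)
  dir <- suppressWarnings(discover_vector(fit$codes, elong, "elongation"))
  list(fit = fit, params = params, direction = dir)
})

# full pipeline on the three-niche population (one distinct class, two
# overlapping): meshes -> SDF -> autodecoder -> codes.
niche_pipeline <- function() cached("niche", function() {
  params <- sample_class_params(niche_demo_spec(15), seed = 31)
  samples <- prepare_sdf_samples(params, mesh_resolution = 26,
                                 n_uniform = 500, seed = 300)
  cfg <- train_config(latent_dim = 8, hidden_size = 64, epochs = 180,
                      batch_size = 4096, lr_theta = 5e-4, lr_z = 5e-3,
                      lambda = 1e-4, seed = 32)
  fit <- train_autodecoder(samples, cfg)
  list(fit = fit, params = params)
})
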