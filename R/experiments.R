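#' Canned synthetic study populations
#'
#' `elongation_series_params()` draws a population of beak parameters whose
#' main axis of variation is elongation (length uniform on 2-6 model
#' units, width and depth near 1, mild curvature and hook), the substrate
#' for desk-scale latent-space studies.  `niche_demo_spec()` is a
#' three-class specification with one morphologically distinct class
#' (long, narrow, curved bills, the nectarivore archetype) and two heavily
#' overlapping generalist classes, the substrate for the niche-asymmetry
#' classification study.
#'
#' @param n number of specimens.
#' @param seed integer seed.
#' @return `elongation_series_params`: tibble of shape parameters;
#'   `niche_demo_spec`: per-class specification for
#'   [sample_class_params()].
#' @export
elongation_series_params <- function(n = 30, seed = 10L) {
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(seed)
  tibble::tibble(
    species_id = sprintf("sp%02d", seq_len(n)),
    length = stats::runif(n, 2, 6),
    width = stats::rnorm(n, 1, 0.08),
    depth = stats::rnorm(n, 1, 0.08),
    curvature = stats::runif(n, 0, 0.15),
    hook = stats::runif(n, 0, 0.3),
    niche = "series")
}

#' @rdname elongation_series_params
#' @param n_per_class specimens per class.
#' @export
niche_demo_spec <- function(n_per_class = 15L) {
  tibble::tibble(
    niche = c("nectarivore", "invertivore", "omnivore"),
    n = n_per_class,
    length_mean = c(5.2, 2.8, 3.0), length_sd = c(0.4, 0.35, 0.35),
    width_mean = c(0.7, 1.15, 1.1), width_sd = c(0.06, 0.12, 0.12),
    depth_mean = c(0.7, 1.05, 1.0), depth_sd = c(0.06, 0.12, 0.12),
    curvature_mean = c(0.25, 0.05, 0.05), curvature_sd = c(0.05, 0.04, 0.04),
    hook_mean = c(0.1, 0.25, 0.25), hook_sd = c(0.05, 0.1, 0.1))
}

#' Mesh-to-SDF-sample preparation for a parameter table
#'
#' Generates each beak mesh, runs the full preprocessing pipeline, and
#' draws its SDF training sample; the standard front end of every
#' desk-scale training run.
#'
#' @param params tibble of shape parameters (one row per specimen).
#' @param mesh_resolution [make_beak_mesh()] resolution.
#' @param n_uniform uniform (= near-surface) SDF points per shape.
#' @param noise_sd near-surface jitter sd.
#' @param seed base seed; shape i uses `seed + i`.
#' @return list of `sdf_sample` objects.
#' @export
prepare_sdf_samples <- function(params, mesh_resolution = 32L,
                                n_uniform = 750L, noise_sd = 0.01,
                                seed = 100L) {
  lapply(seq_len(nrow(params)), function(i) {
    m <- make_beak_mesh(params[i, ], resolution = mesh_resolution)
    pp <- preprocess_mesh(m)
    sample_sdf(pp$mesh, n_uniform = n_uniform, noise_sd = noise_sd,
               seed = seed + i, shape_id = params$species_id[i])
  })
}

#' Latent-traversal monotonicity experiment
#'
#' Draws random codes from the model's empirical latent distribution
#' (Gaussian with the trained codes' mean and per-dimension sd), moves
#' each along a discovered direction, decodes every step, and measures
#' elongation on the reconstructed meshes.  A draw counts as monotone
#' when measured elongation never decreases by more than `tol` between
#' consecutive steps (`tol` absorbs the voxel-scale quantization of mesh
#' extents at the reconstruction resolution).
#'
#' @param fit a trained `sdf_autodecoder`.
#' @param direction a `latent_direction` (e.g. the elongation direction).
#' @param n_draws number of random starting codes.
#' @param steps_sd signed step sizes in units of the overall code sd times
#'   `sqrt(latent_dim)` (the typical code norm scale).
#' @param resolution reconstruction grid resolution.
#' @param seed integer seed for the draws.
#' @param tol monotonicity tolerance on the elongation index.
#' @return list with `results` (tibble: draw, step, elongation),
#'   `monotone` (logical per draw), `n_monotone`.
#' @export
traversal_monotonicity <- function(fit, direction, n_draws = 10L,
                                   steps_sd = c(-1, -0.5, 0, 0.5, 1),
                                   resolution = 40L, seed = 21L,
                                   tol = 0.05) {
  Z <- codes_matrix(fit$codes)
  d <- ncol(Z)
  mu <- colMeans(Z); sds <- apply(Z, 2, stats::sd)
  gs <- stats::sd(as.vector(Z))
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(seed)
  draws <- sweep(sweep(matrix(stats::rnorm(n_draws * d), n_draws, d),
                       2, sds, "*"), 2, mu, "+")
  steps <- steps_sd * gs * sqrt(d)
  res <- list(); monotone <- logical(n_draws)
  for (i in seq_len(n_draws)) {
    path <- apply_vector(draws[i, ], direction, steps)
    es <- vapply(seq_len(nrow(path)), function(j) {
      m <- tryCatch(reconstruct_mesh(fit$params, path[j, ],
                                     resolution = resolution),
                    error = function(e) NULL)
      if (is.null(m)) return(NA_real_)
      measure_beak(m, assume_canonical = TRUE)$elongation
    }, numeric(1))
    monotone[i] <- !anyNA(es) && all(diff(es) >= -tol)
    res[[i]] <- tibble::tibble(draw = i, step = steps, elongation = es)
  }
  list(results = dplyr::bind_rows(res), monotone = monotone,
       n_monotone = sum(monotone))
}

#' Repeated stratified-holdout evaluation
#'
#' Repeats the full hold-out protocol (stratified 20% test split,
#' MC-CV hyperparameter tuning on the training part, evaluation on the
#' held-out part) and pools the confusion matrices, giving per-class
#' sensitivities with more test support than a single small holdout.
#'
#' @param features predictor table (rows = specimens).
#' @param labels class labels.
#' @param n_repeats number of independent holdout repetitions.
#' @param model,grid,n_mc_splits passed to [tune_and_fit()].
#' @param test_prop held-out fraction.
#' @param seed base seed; repeat r uses `seed + r`.
#' @return an `eval_report` computed from the pooled confusion matrix.
#' @export
repeated_holdout_eval <- function(features, labels, n_repeats = 5L,
                                  model = "random_forest", grid = NULL,
                                  n_mc_splits = 10L, test_prop = 0.2,
                                  seed = 1L) {
  features <- as.data.frame(features)
  labels <- droplevels(as.factor(labels))
  truth_all <- factor(character(), levels = levels(labels))
  pred_all <- factor(character(), levels = levels(labels))
  for (r in seq_len(n_repeats)) {
    sp <- stratified_split(labels, test_prop = test_prop, seed = seed + r)
    clf <- tune_and_fit(features[sp$train, , drop = FALSE], labels[sp$train],
                        model = model, grid = grid,
                        n_mc_splits = n_mc_splits, seed = seed + r)
    pred <- predict_labels(clf$fit, features[sp$test, , drop = FALSE], model)
    truth_all <- c(truth_all, labels[sp$test])
    pred_all <- c(pred_all, factor(pred, levels = levels(labels)))
  }
  evaluate_predictions(truth_all, pred_all)
}
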