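test_that("decoder forward pass has the declared shape and is reproducible", {
  p1 <- build_decoder(4, 16, seed = 3)
  p2 <- build_decoder(4, 16, seed = 3)
  expect_identical(p1$W1, p2$W1)
  expect_identical(p1$W6, p2$W6)
  set.seed(1)
  out <- decode_sdf(p1, rnorm(4), matrix(rnorm(21), 7, 3))
  expect_length(out, 7)
  expect_true(all(abs(out) < 1))              # tanh output
  # skip connection dimensions: module 2 consumes hidden + latent + 3
  expect_identical(dim(p1$W4), c(16L + 4L + 3L, 16L))
  expect_error(build_decoder(0, 16), "invalid")
})

test_that("autodiff gradients match central differences", {
  params <- build_decoder(4, 8, seed = 3)
  set.seed(2)
  n <- 9
  Z <- matrix(rnorm(n * 4), n, 4); X <- matrix(rnorm(n * 3), n, 3)
  s <- rnorm(n, 0, 0.05)
  delta <- 0.1
  loss <- function(params, Z) {
    sum(abs(clamp(s, delta) - clamp(beakmorph:::decoder_forward(params, Z, X),
                                    delta)))
  }
  cache <- beakmorph:::decoder_forward(params, Z, X, cache = TRUE)
  resid <- clamp(s, delta) - clamp(cache$out, delta)
  dout <- -sign(resid) * (abs(cache$out) < delta)
  bk <- beakmorph:::decoder_backward(params, cache, dout)
  h <- 1e-6
  Zp <- Z; Zp[3, 2] <- Zp[3, 2] + h
  Zm <- Z; Zm[3, 2] <- Zm[3, 2] - h
  fd <- (loss(params, Zp) - loss(params, Zm)) / (2 * h)
  expect_equal(bk$dZ[3, 2], fd, tolerance = 1e-4)
  for (w in c("W1", "W4", "b2")) {
    pp <- params; pp[[w]][5] <- pp[[w]][5] + h
    pm <- params; pm[[w]][5] <- pm[[w]][5] - h
    fd <- (loss(pp, Z) - loss(pm, Z)) / (2 * h)
    expect_equal(bk$grads[[w]][5], fd, tolerance = 1e-4)
  }
})

test_that("clamp truncates to the band", {
  expect_identical(clamp(0.5, 0.1), 0.1)
  expect_identical(clamp(-0.3, 0.1), -0.1)
  expect_identical(clamp(0.05, 0.1), 0.05)
  expect_error(clamp(1, 0), "positive")
})

test_that("the MAP loss matches its closed forms and decomposes in lambda", {
  params <- build_decoder(3, 8, seed = 1)
  codes <- codes_tibble(matrix(rnorm(6), 2, 3,
                               dimnames = list(c("a", "b"), NULL)))
  batch <- tibble::tibble(x = c(0.1, -0.2), y = c(0, 0.3), z = c(0.2, 0),
                          distance = c(0.5, 0.5), shape_id = c("a", "b"))
  cfg0 <- train_config(latent_dim = 3, delta = 0.1, lambda = 0)

  # observation and prediction clamp to opposite band edges: |0.1 - (-0.1)|
  stub <- params
  for (w in c("W1","b1","W2","b2","W3","b3","W4","b4","W5","b5","W6"))
    stub[[w]] <- stub[[w]] * 0
  stub$b6 <- atanh(-0.5)
  expect_equal(map_loss(batch, codes, stub, cfg0), 0.2 * 2)
  one_row <- batch[1, ]
  expect_equal(map_loss(one_row, codes, stub, cfg0), 0.2)

  # predictions equal observations -> zero loss
  stub$b6 <- atanh(0.5)  # prediction 0.5 clamps to 0.1 = clamped obs
  expect_equal(map_loss(batch, codes, stub, cfg0), 0)

  # exact lambda decomposition: loss(lambda) = loss(0) + lambda * sum ||z||^2
  cfg1 <- train_config(latent_dim = 3, delta = 0.1, lambda = 0.37)
  l0 <- map_loss(batch, codes, params, cfg0)
  l1 <- map_loss(batch, codes, params, cfg1)
  expect_equal(l1 - l0, 0.37 * sum(codes_matrix(codes)^2), tolerance = 1e-9)

  # all-zero codes contribute no penalty
  z0 <- codes_tibble(matrix(0, 2, 3, dimnames = list(c("a", "b"), NULL)))
  expect_equal(map_loss(batch, z0, params, cfg1),
               map_loss(batch, z0, params, cfg0))
})

tiny_samples <- function(n_shapes = 3, n_rows = 150, seed = 50) {
  set.seed(seed)
  lapply(seq_len(n_shapes), function(i) {
    P <- matrix(runif(3 * n_rows, -1, 1), ncol = 3)
    structure(list(shape_id = paste0("s", i), points = P,
                   distances = analytic_sdf("sphere", P, r = 0.25 + 0.1 * i),
                   near_surface = rep(FALSE, n_rows), seed = i),
              class = "sdf_sample")
  })
}

test_that("training is deterministic under a fixed seed", {
  cfg <- train_config(latent_dim = 3, hidden_size = 16, epochs = 5,
                      batch_size = 128, seed = 7)
  f1 <- train_autodecoder(tiny_samples(), cfg)
  f2 <- train_autodecoder(tiny_samples(), cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$codes, f2$codes)
  expect_error(train_autodecoder(tiny_samples(1), cfg), ">= 2 shapes")
})

test_that("the spherical prior shrinks codes monotonically in lambda", {
  norms <- vapply(c(1e-4, 0.3, 3), function(lam) {
    cfg <- train_config(latent_dim = 4, hidden_size = 32, epochs = 40,
                        batch_size = 600, lr_theta = 1e-3, lr_z = 1e-2,
                        lambda = lam, seed = 5)
    fit <- train_autodecoder(tiny_samples(4, 300), cfg)
    mean(sqrt(rowSums(codes_matrix(fit$codes)^2)))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("desk-scale training overfits its shapes and smooths over epochs", {
  mod <- overfit_model()
  hist <- mod$fit$history
  expect_lt(tail(hist$mean_clamped_error, 1), 0.01)
  expect_true(all(is.finite(codes_matrix(mod$fit$codes))))
  # non-increasing after 10-epoch smoothing (local bumps allowed)
  sm <- stats::filter(hist$mean_clamped_error, rep(1 / 10, 10), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) < 5e-4))
  expect_lt(tail(sm, 1), head(sm, 1))
})

test_that("a fresh sample of a training shape re-embeds onto its code", {
  mod <- overfit_model()
  m <- make_beak_mesh(mod$params[3, ], resolution = 32)
  s_new <- sample_sdf(preprocess_mesh(m)$mesh, n_uniform = 750,
                      noise_sd = 0.01, seed = 999, shape_id = "fresh")
  emb <- embed_new_shape(mod$fit$params, s_new, mod$config,
                         freeze_decoder = TRUE, iters = 400)
  z_train <- codes_matrix(mod$fit$codes)[3, ]
  cosine <- sum(emb$code * z_train) /
    sqrt(sum(emb$code^2) * sum(z_train^2))
  expect_gt(cosine, 0.95)
})

test_that("a held-out shape from the same family embeds with bounded error", {
  mod <- overfit_model()
  set.seed(77)
  pnew <- list(length = runif(1, 2.2, 5.5), width = rnorm(1, 1, 0.08),
               depth = rnorm(1, 1, 0.08), curvature = 0.1, hook = 0.2)
  s_new <- sample_sdf(preprocess_mesh(
    make_beak_mesh(pnew, resolution = 32))$mesh,
    n_uniform = 750, seed = 1000, shape_id = "held")
  emb <- embed_new_shape(mod$fit$params, s_new, mod$config, iters = 400)
  expect_lt(emb$final_error,
            3 * tail(mod$fit$history$mean_clamped_error, 1))
})

test_that("zero-iteration embedding returns the random initialization", {
  mod <- overfit_model()
  s <- mod$samples[[1]]
  emb0 <- embed_new_shape(mod$fit$params, s, mod$config, iters = 0)
  set.seed(mod$config$seed)
  expect_equal(emb0$code, rnorm(8, 0, 0.01))
})

test_that("latent interpolation between trained shapes decodes to valid meshes", {
  mod <- overfit_model()
  Z <- codes_matrix(mod$fit$codes)
  path <- latent_path(Z[c(1, 6), ], n_frames = 5)
  for (j in seq_len(5)) {
    m <- reconstruct_mesh(mod$fit$params, path[j, ], resolution = 32)
    expect_gt(nrow(m$faces), 0)
    expect_gt(mesh_volume(m), 0)
  }
})

test_that("checkpoints round-trip weights, codes and config", {
  cfg <- train_config(latent_dim = 3, hidden_size = 16, epochs = 3,
                      batch_size = 128, seed = 7)
  fit <- train_autodecoder(tiny_samples(), cfg)
  stem <- withr::local_tempfile()
  save_checkpoint(fit, stem)
  back <- load_checkpoint(stem)
  expect_identical(back$params$W1, fit$params$W1)
  expect_identical(back$codes, fit$codes)
  expect_identical(back$config$latent_dim, cfg$latent_dim)
})
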