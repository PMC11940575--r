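#' Clamp to a symmetric band
#'
#' `clamp(x, delta) = min(delta, max(-delta, x))`.  Truncating both
#' observed and predicted signed distances to `[-delta, delta]`
#' concentrates reconstruction accuracy near the zero isosurface.
#'
#' @param x numeric.
#' @param delta positive band half-width.
#' @return numeric of the same shape, in `[-delta, delta]`.
#' @export
clamp <- function(x, delta) {
  if (delta <= 0) stop("`delta` must be positive")
  pmin(delta, pmax(-delta, x))
}

#' Training configuration for the SDF autodecoder
#'
#' @param latent_dim latent code dimension (the published model uses 64).
#' @param hidden_size hidden-layer width (the published model uses 512).
#' @param delta clamp half-width of the reconstruction loss (default 0.1).
#' @param lambda weight of the spherical-prior L2 penalty on codes (the
#'   sigma^2/phi^2 ratio of the MAP objective; only the ratio is
#'   identifiable).
#' @param epochs training epochs.
#' @param batch_size minibatch rows.
#' @param lr_theta,lr_z Adam learning rates for decoder weights and codes.
#' @param seed integer seed for initialization and batching.
#' @param checkpoint_path optional path stem; a checkpoint is written at
#'   the end of training and every `checkpoint_every` epochs.
#' @param checkpoint_every checkpoint interval in epochs.
#' @return a `train_config` list.
#' @export
train_config <- function(latent_dim = 64L, hidden_size = 512L, delta = 0.1,
                         lambda = 1e-4, epochs = 100L, batch_size = 2048L,
                         lr_theta = 1e-4, lr_z = 1e-3, seed = 1L,
                         checkpoint_path = NULL, checkpoint_every = Inf) {
  if (delta <= 0) stop("`delta` must be positive")
  if (lambda < 0) stop("`lambda` must be >= 0")
  structure(list(latent_dim = as.integer(latent_dim),
                 hidden_size = as.integer(hidden_size), delta = delta,
                 lambda = lambda, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr_theta = lr_theta,
                 lr_z = lr_z, seed = as.integer(seed),
                 checkpoint_path = checkpoint_path,
                 checkpoint_every = checkpoint_every),
            class = "train_config")
}

#' Build the SDF decoder network
#'
#' Two chained 3-layer perceptron modules.  The first maps the
#' concatenated `(z, x)` input (width `latent_dim + 3`) through hidden
#' layers of `hidden_size` units; the second receives the first module's
#' output concatenated again with `(z, x)` (a skip connection) and emits a
#' single signed-distance prediction.  Hidden activations are ReLU, the
#' output is tanh.
#'
#' @param latent_dim latent dimension (>= 1).
#' @param hidden_size hidden width (>= 1).
#' @param seed integer seed for weight initialization.
#' @return an `sdf_decoder`: list of weight matrices/bias vectors plus
#'   dimensions.
#' @export
build_decoder <- function(latent_dim, hidden_size = 512L, seed = 1L) {
  if (latent_dim < 1 || hidden_size < 1) stop("invalid sizes")
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(seed)
  d <- as.integer(latent_dim); h <- as.integer(hidden_size)
  in1 <- d + 3L; in2 <- h + d + 3L
  he <- function(fi, fo) matrix(stats::rnorm(fi * fo, 0, sqrt(2 / fi)), fi, fo)
  structure(list(
    W1 = he(in1, h), b1 = numeric(h),
    W2 = he(h, h),  b2 = numeric(h),
    W3 = he(h, h),  b3 = numeric(h),
    W4 = he(in2, h), b4 = numeric(h),
    W5 = he(h, h),  b5 = numeric(h),
    # small output-layer init keeps initial predictions inside the clamp
    # band, where the loss has gradient
    W6 = matrix(stats::rnorm(h, 0, 0.01 / sqrt(h)), h, 1), b6 = 0,
    latent_dim = d, hidden_size = h), class = "sdf_decoder")
}

#' @export
print.sdf_decoder <- function(x, ...) {
  np <- sum(vapply(x[c("W1","b1","W2","b2","W3","b3","W4","b4","W5","b5","W6","b6")],
                   length, 1L))
  cat("<sdf_decoder> latent_dim ", x$latent_dim, ", hidden ", x$hidden_size,
      ", ", np, " parameters\n", sep = "")
  invisible(x)
}

# forward pass; returns prediction vector, optionally with caches for backprop
decoder_forward <- function(params, Z, X, cache = FALSE) {
  in1 <- cbind(Z, X)
  a1 <- in1 %*% params$W1; a1 <- sweep(a1, 2, params$b1, "+"); h1 <- pmax(a1, 0)
  a2 <- h1 %*% params$W2; a2 <- sweep(a2, 2, params$b2, "+"); h2 <- pmax(a2, 0)
  a3 <- h2 %*% params$W3; a3 <- sweep(a3, 2, params$b3, "+"); h3 <- pmax(a3, 0)
  in2 <- cbind(h3, in1)
  a4 <- in2 %*% params$W4; a4 <- sweep(a4, 2, params$b4, "+"); h4 <- pmax(a4, 0)
  a5 <- h4 %*% params$W5; a5 <- sweep(a5, 2, params$b5, "+"); h5 <- pmax(a5, 0)
  out <- tanh(as.vector(h5 %*% params$W6) + params$b6)
  if (!cache) return(out)
  list(out = out, in1 = in1, h1 = h1, h2 = h2, h3 = h3, in2 = in2,
       h4 = h4, h5 = h5)
}

#' Evaluate the decoder
#'
#' @param params an `sdf_decoder`.
#' @param z a single latent vector or an n x latent_dim matrix (recycled
#'   against `x` rows when a single vector).
#' @param x n x 3 matrix of query coordinates.
#' @return numeric vector of n predicted signed distances.
#' @export
decode_sdf <- function(params, z, x) {
  x <- rbind(x, deparse.level = 0)
  if (is.null(dim(z)) || nrow(rbind(z, deparse.level = 0)) == 1L)
    z <- matrix(as.numeric(z), nrow(x), params$latent_dim, byrow = TRUE)
  decoder_forward(params, z, x)
}

# backprop from dL/dout; returns parameter grads and dL/dZ
decoder_backward <- function(params, cache, dout) {
  dpre6 <- matrix(dout * (1 - cache$out^2), ncol = 1)
  gW6 <- crossprod(cache$h5, dpre6); gb6 <- sum(dpre6)
  dh5 <- dpre6 %*% t(params$W6)                 # n x h
  dpre5 <- dh5 * (cache$h5 > 0)
  gW5 <- crossprod(cache$h4, dpre5); gb5 <- colSums(dpre5)
  dh4 <- dpre5 %*% t(params$W5)
  dpre4 <- dh4 * (cache$h4 > 0)
  gW4 <- crossprod(cache$in2, dpre4); gb4 <- colSums(dpre4)
  din2 <- dpre4 %*% t(params$W4)
  h <- params$hidden_size; d <- params$latent_dim
  dh3 <- din2[, seq_len(h), drop = FALSE]
  din1_skip <- din2[, h + seq_len(d + 3L), drop = FALSE]
  dpre3 <- dh3 * (cache$h3 > 0)
  gW3 <- crossprod(cache$h2, dpre3); gb3 <- colSums(dpre3)
  dh2 <- dpre3 %*% t(params$W3)
  dpre2 <- dh2 * (cache$h2 > 0)
  gW2 <- crossprod(cache$h1, dpre2); gb2 <- colSums(dpre2)
  dh1 <- dpre2 %*% t(params$W2)
  dpre1 <- dh1 * (cache$h1 > 0)
  gW1 <- crossprod(cache$in1, dpre1); gb1 <- colSums(dpre1)
  din1 <- dpre1 %*% t(params$W1) + din1_skip
  list(grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3,
                    b3 = gb3, W4 = gW4, b4 = gb4, W5 = gW5, b5 = gb5,
                    W6 = gW6, b6 = gb6),
       dZ = din1[, seq_len(d), drop = FALSE])
}

#' Latent code tables
#'
#' Latent codes are carried as a tibble with a `shape_id` column and
#' `z_1 .. z_d` numeric columns; these helpers convert to and from the
#' matrix form used in linear algebra.
#'
#' @param codes a latent-code tibble.
#' @return `codes_matrix`: numeric matrix with `shape_id` rownames.
#' @export
codes_matrix <- function(codes) {
  zc <- grep("^z_", names(codes), value = TRUE)
  m <- as.matrix(codes[zc])
  rownames(m) <- codes$shape_id
  m
}

#' @rdname codes_matrix
#' @param Z numeric matrix (rows = shapes), rownames used as `shape_id`.
#' @export
codes_tibble <- function(Z) {
  ids <- rownames(Z)
  if (is.null(ids)) ids <- sprintf("shape_%03d", seq_len(nrow(Z)))
  colnames(Z) <- paste0("z_", seq_len(ncol(Z)))
  dplyr::bind_cols(tibble::tibble(shape_id = ids), tibble::as_tibble(Z))
}

#' Clamped-L1 MAP objective
#'
#' `sum(|clamp(s, delta) - clamp(f_theta(z, x), delta)|) +
#' lambda * sum_i ||z_i||^2`, the penalty counted once per shape present
#' in the batch.
#'
#' @param batch data frame with columns `x`, `y`, `z`, `distance`,
#'   `shape_id` (as produced by [as_tibble.sdf_sample()]).
#' @param codes latent-code tibble covering every `shape_id` in `batch`.
#' @param params an `sdf_decoder`.
#' @param config a [train_config()].
#' @return scalar loss.
#' @export
map_loss <- function(batch, codes, params, config) {
  Zm <- codes_matrix(codes)
  idx <- match(batch$shape_id, rownames(Zm))
  if (anyNA(idx)) stop("batch contains shape_ids missing from `codes`")
  pred <- decoder_forward(params, Zm[idx, , drop = FALSE],
                          cbind(batch$x, batch$y, batch$z))
  if (any(!is.finite(pred))) stop("training diverged: NaN in forward pass")
  recon <- sum(abs(clamp(batch$distance, config$delta) -
                     clamp(pred, config$delta)))
  pen <- config$lambda * sum(Zm[unique(idx), , drop = FALSE]^2)
  recon + pen
}

adam_init <- function(x) list(m = x * 0, v = x * 0, t = 0)
adam_step <- function(state, g, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$step <- lr * mhat / (sqrt(vhat) + eps)
  state
}

#' Train the SDF autodecoder
#'
#' Jointly optimizes the decoder weights and one latent code per shape by
#' minimizing the clamped-L1 reconstruction loss plus the spherical-prior
#' L2 penalty, with Adam and separate learning rates for weights and
#' codes.  Codes are initialized from N(0, 0.01^2) so the prior dominates
#' early training.
#'
#' @param samples list of `sdf_sample` objects (>= 2 shapes, each with
#'   >= 100 rows).
#' @param config a [train_config()].
#' @param resampler optional `function(epoch)` returning a fresh list of
#'   `sdf_sample`s, emulating re-drawing the Monte-Carlo SDF sample each
#'   epoch; default trains on the fixed input sample.
#' @return an `sdf_autodecoder`: list with `params` (`sdf_decoder`),
#'   `codes` (latent-code tibble), `history` (tibble with per-epoch mean
#'   per-row clamped error and total loss), `config`.
#' @export
train_autodecoder <- function(samples, config = train_config(),
                              resampler = NULL) {
  ids <- vapply(samples, function(s) s$shape_id, "")
  if (length(samples) < 2) stop("need >= 2 shapes")
  if (any(vapply(samples, function(s) nrow(s$points), 1) < 100))
    stop("each shape needs >= 100 SDF rows")
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(config$seed)

  params <- build_decoder(config$latent_dim, config$hidden_size,
                          seed = config$seed)
  n_shape <- length(samples)
  Z <- matrix(stats::rnorm(n_shape * config$latent_dim, 0, 0.01),
              n_shape, config$latent_dim, dimnames = list(ids, NULL))

  stack <- function(ss) {
    list(P = do.call(rbind, lapply(ss, `[[`, "points")),
         s = unlist(lapply(ss, `[[`, "distances")),
         shape = rep(seq_along(ss), vapply(ss, function(x) nrow(x$points), 1L)))
  }
  dat <- stack(samples)

  opt_p <- lapply(params[c("W1","b1","W2","b2","W3","b3","W4","b4","W5","b5","W6","b6")],
                  adam_init)
  opt_z <- adam_init(Z)
  delta <- config$delta
  history <- vector("list", config$epochs)
  wnames <- names(opt_p)

  for (epoch in seq_len(config$epochs)) {
    if (!is.null(resampler) && epoch > 1) dat <- stack(resampler(epoch))
    n <- length(dat$s)
    perm <- sample.int(n)
    starts <- seq(1, n, by = config$batch_size)
    ep_err <- 0
    for (b0 in starts) {
      rows <- perm[b0:min(b0 + config$batch_size - 1, n)]
      Zi <- dat$shape[rows]
      Zb <- Z[Zi, , drop = FALSE]
      cache <- decoder_forward(params, Zb, dat$P[rows, , drop = FALSE],
                               cache = TRUE)
      if (any(!is.finite(cache$out)))
        stop("training diverged: non-finite predictions")
      cs <- clamp(dat$s[rows], delta)
      cp <- clamp(cache$out, delta)
      resid <- cs - cp
      ep_err <- ep_err + sum(abs(resid))
      nb <- length(rows)
      dout <- -sign(resid) * (abs(cache$out) < delta) / nb
      bk <- decoder_backward(params, cache, dout)
      for (w in wnames) {
        opt_p[[w]] <- adam_step(opt_p[[w]], bk$grads[[w]], config$lr_theta)
        params[[w]] <- params[[w]] - opt_p[[w]]$step
      }
      # per-shape code gradients: data term summed over rows (mean-scaled)
      # + prior once per shape present
      gZ <- rowsum(bk$dZ, Zi)
      present <- as.integer(rownames(gZ))
      gfull <- Z * 0
      gfull[present, ] <- gZ + 2 * config$lambda * Z[present, , drop = FALSE]
      opt_z <- adam_step(opt_z, gfull, config$lr_z)
      Z[present, ] <- Z[present, ] - opt_z$step[present, , drop = FALSE]
    }
    history[[epoch]] <- tibble::tibble(
      epoch = epoch,
      mean_clamped_error = ep_err / n,
      penalty = config$lambda * sum(Z^2))
    if (is.finite(config$checkpoint_every) &&
        !is.null(config$checkpoint_path) &&
        epoch %% config$checkpoint_every == 0)
      save_checkpoint(list(params = params, codes = codes_tibble(Z),
                           config = config),
                      paste0(config$checkpoint_path, "_", epoch))
  }
  model <- structure(list(params = params, codes = codes_tibble(Z),
                          history = dplyr::bind_rows(history),
                          config = config),
                     class = "sdf_autodecoder")
  if (!is.null(config$checkpoint_path))
    save_checkpoint(model, config$checkpoint_path)
  model
}

#' @export
print.sdf_autodecoder <- function(x, ...) {
  cat("<sdf_autodecoder> ", nrow(x$codes), " shapes, latent_dim ",
      x$config$latent_dim, ", ", max(x$history$epoch), " epochs, final mean ",
      "clamped error ", signif(utils::tail(x$history$mean_clamped_error, 1), 3),
      "\n", sep = "")
  invisible(x)
}

#' Embed a new shape into a trained latent space
#'
#' Starting from a random latent vector, gradient-optimizes the clamped-L1
#' MAP objective for one shape's SDF sample.  With `freeze_decoder = TRUE`
#' (the default) only the code moves; with `FALSE` the decoder weights are
#' fine-tuned as well.
#'
#' @param params a trained `sdf_decoder`.
#' @param sample an `sdf_sample` for the new shape.
#' @param config a [train_config()] (learning rates, delta, lambda, seed).
#' @param freeze_decoder keep decoder weights fixed.
#' @param iters optimization steps (full-sample batches); 0 returns the
#'   random initialization unchanged.
#' @return list with `code` (latent vector), `final_error` (mean per-row
#'   clamped error), and `params` (updated when `freeze_decoder = FALSE`).
#' @export
embed_new_shape <- function(params, sample, config = train_config(),
                            freeze_decoder = TRUE, iters = 300L) {
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(config$seed)
  d <- params$latent_dim
  z <- stats::rnorm(d, 0, 0.01)
  P <- sample$points; s <- sample$distances; n <- nrow(P)
  delta <- config$delta
  opt_z <- adam_init(z)
  wnames <- c("W1","b1","W2","b2","W3","b3","W4","b4","W5","b5","W6","b6")
  if (!freeze_decoder) opt_p <- lapply(params[wnames], adam_init)
  err <- NA_real_
  for (it in seq_len(iters)) {
    Zb <- matrix(z, n, d, byrow = TRUE)
    cache <- decoder_forward(params, Zb, P, cache = TRUE)
    resid <- clamp(s, delta) - clamp(cache$out, delta)
    err <- mean(abs(resid))
    dout <- -sign(resid) * (abs(cache$out) < delta) / n
    bk <- decoder_backward(params, cache, dout)
    gz <- colSums(bk$dZ) + 2 * config$lambda * z
    opt_z <- adam_step(opt_z, gz, config$lr_z)
    z <- z - opt_z$step
    if (!freeze_decoder) {
      for (w in wnames) {
        opt_p[[w]] <- adam_step(opt_p[[w]], bk$grads[[w]], config$lr_theta)
        params[[w]] <- params[[w]] - opt_p[[w]]$step
      }
    }
  }
  if (iters == 0) {
    pred <- decode_sdf(params, z, P)
    err <- mean(abs(clamp(s, delta) - clamp(pred, delta)))
  }
  out <- list(code = z, final_error = err)
  if (!freeze_decoder) out$params <- params
  out
}

#' Checkpoint IO
#'
#' A checkpoint is a container of named numeric arrays (decoder weights
#' and codes, R serialization) with a JSON sidecar recording the training
#' configuration.
#'
#' @param model an `sdf_autodecoder` (or list with `params`, `codes`,
#'   `config`).
#' @param path file stem; writes `<path>.rds` and `<path>.json`.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model[c("params", "codes", "history")], paste0(path, ".rds"))
  cfg <- model$config
  jsonlite::write_json(cfg[!vapply(cfg, is.null, TRUE)],
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(paste0(path, ".rds"))
  cfg <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  obj$config <- do.call(train_config, cfg[names(cfg) %in% names(formals(train_config))])
  class(obj) <- "sdf_autodecoder"
  obj
}
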