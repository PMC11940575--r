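#' Configuration for the second-stage conditional VAE
#'
#' @param cvae_latent_dim stage-2 latent dimension (default 15).
#' @param hidden_size encoder/decoder hidden width (2 layers each).
#' @param epochs training epochs.
#' @param batch_size minibatch rows.
#' @param lr Adam learning rate.
#' @param seed integer seed.
#' @return a `cvae_config` list.
#' @export
cvae_config <- function(cvae_latent_dim = 15L, hidden_size = 128L,
                        epochs = 300L, batch_size = 128L, lr = 1e-3,
                        seed = 1L) {
  structure(list(cvae_latent_dim = as.integer(cvae_latent_dim),
                 hidden_size = as.integer(hidden_size),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 seed = as.integer(seed)), class = "cvae_config")
}

#' Closed-form Gaussian KL divergence to the standard normal
#'
#' `KL(N(mu, diag(sigma^2)) || N(0, I)) =
#' 0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2)` per row.
#'
#' @param mu n x q matrix (or vector) of posterior means.
#' @param logvar matching matrix of posterior log-variances.
#' @return numeric vector of per-row KL divergences (non-negative).
#' @export
kl_gaussian <- function(mu, logvar) {
  mu <- rbind(mu, deparse.level = 0)
  logvar <- rbind(logvar, deparse.level = 0)
  0.5 * rowSums(mu^2 + exp(logvar) - 1 - logvar)
}

build_cvae <- function(input_dim, n_cond, config) {
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(config$seed)
  h <- config$hidden_size; q <- config$cvae_latent_dim
  he <- function(fi, fo) matrix(stats::rnorm(fi * fo, 0, sqrt(2 / fi)), fi, fo)
  xav <- function(fi, fo) matrix(stats::rnorm(fi * fo, 0, sqrt(1 / fi)), fi, fo)
  structure(list(
    We1 = he(input_dim + n_cond, h), be1 = numeric(h),
    We2 = he(h, h), be2 = numeric(h),
    Wm = xav(h, q), bm = numeric(q),
    Wv = xav(h, q), bv = numeric(q) - 1,        # start with small variances
    Wd1 = he(q + n_cond, h), bd1 = numeric(h),
    Wd2 = he(h, h), bd2 = numeric(h),
    Wo = xav(h, input_dim), bo = numeric(input_dim),
    log_gamma = 0,
    input_dim = as.integer(input_dim), n_cond = as.integer(n_cond),
    cvae_latent_dim = q, hidden_size = h), class = "cvae_params")
}

#' @export
print.cvae_params <- function(x, ...) {
  cat("<cvae_params> ", x$input_dim, " -> ", x$cvae_latent_dim,
      " latent, ", x$n_cond, " condition levels, gamma = ",
      signif(exp(x$log_gamma), 3), "\n", sep = "")
  invisible(x)
}

one_hot <- function(labels, levels) {
  labels <- factor(labels, levels = levels)
  if (anyNA(labels)) stop("unknown condition label")
  O <- matrix(0, length(labels), length(levels))
  O[cbind(seq_along(labels), as.integer(labels))] <- 1
  O
}

cvae_forward <- function(params, X, O, eps) {
  ein <- cbind(X, O)
  a1 <- sweep(ein %*% params$We1, 2, params$be1, "+"); h1 <- pmax(a1, 0)
  a2 <- sweep(h1 %*% params$We2, 2, params$be2, "+"); h2 <- pmax(a2, 0)
  mu <- sweep(h2 %*% params$Wm, 2, params$bm, "+")
  lv <- sweep(h2 %*% params$Wv, 2, params$bv, "+")
  lv <- pmin(pmax(lv, -10), 10)
  sig <- exp(0.5 * lv)
  z <- mu + sig * eps
  din <- cbind(z, O)
  a3 <- sweep(din %*% params$Wd1, 2, params$bd1, "+"); g1 <- pmax(a3, 0)
  a4 <- sweep(g1 %*% params$Wd2, 2, params$bd2, "+"); g2 <- pmax(a4, 0)
  xhat <- sweep(g2 %*% params$Wo, 2, params$bo, "+")
  list(ein = ein, h1 = h1, h2 = h2, mu = mu, lv = lv, sig = sig, z = z,
       din = din, g1 = g1, g2 = g2, xhat = xhat)
}

#' Conditional-VAE evidence lower bound
#'
#' Splits the negative ELBO into its reconstruction and KL parts.  The
#' reconstruction term is the Gaussian log-density of the input under the
#' decoder output with trainable variance `gamma`
#' (`-0.5 * (||x - xhat||^2 / gamma + d * log(2 pi gamma))` per row); the
#' KL term is the closed-form divergence of [kl_gaussian()].  The total is
#' `-(reconstruction - KL)`, averaged over rows.
#'
#' @param x n x input_dim matrix of stage-1 codes.
#' @param condition labels within the declared set.
#' @param params a trained (or fresh) `cvae_params` carrying a `levels`
#'   attribute, as returned by [train_cvae()].
#' @param eps optional n x q reparameterization noise; 0 gives the
#'   deterministic evaluation at the posterior mean.
#' @return list with `total`, `reconstruction_term` (mean per-row log
#'   density), `kl_term` (mean per-row KL).
#' @export
elbo_loss <- function(x, condition, params, eps = NULL) {
  x <- rbind(x, deparse.level = 0)
  lv_set <- attr(params, "levels")
  O <- one_hot(condition, lv_set)
  q <- params$cvae_latent_dim
  if (is.null(eps)) eps <- matrix(stats::rnorm(nrow(x) * q), nrow(x), q)
  else if (length(eps) == 1) eps <- matrix(eps, nrow(x), q)
  fw <- cvae_forward(params, x, O, eps)
  gamma <- exp(params$log_gamma)
  d <- params$input_dim
  rec <- -0.5 * (rowSums((x - fw$xhat)^2) / gamma + d * log(2 * pi * gamma))
  kl <- kl_gaussian(fw$mu, fw$lv)
  list(total = mean(-(rec - kl)), reconstruction_term = mean(rec),
       kl_term = mean(kl))
}

cvae_wnames <- c("We1","be1","We2","be2","Wm","bm","Wv","bv",
                 "Wd1","bd1","Wd2","bd2","Wo","bo","log_gamma")

# gradients of the mean negative ELBO; exact reparameterized backprop
cvae_backward <- function(params, X, O, eps, fw) {
  n <- nrow(X); d <- params$input_dim; q <- params$cvae_latent_dim
  gamma <- exp(params$log_gamma)
  dxhat <- (fw$xhat - X) / gamma / n
  ss <- sum((X - fw$xhat)^2)
  g_lg <- -0.5 * ss / gamma / n + d / 2
  gWo <- crossprod(fw$g2, dxhat); gbo <- colSums(dxhat)
  dg2 <- dxhat %*% t(params$Wo) * (fw$g2 > 0)
  gWd2 <- crossprod(fw$g1, dg2); gbd2 <- colSums(dg2)
  dg1 <- dg2 %*% t(params$Wd2) * (fw$g1 > 0)
  gWd1 <- crossprod(fw$din, dg1); gbd1 <- colSums(dg1)
  ddin <- dg1 %*% t(params$Wd1)
  dz <- ddin[, seq_len(q), drop = FALSE]
  dmu <- dz + fw$mu / n                          # + KL term
  dlv <- dz * eps * 0.5 * fw$sig + 0.5 * (exp(fw$lv) - 1) / n
  gWm <- crossprod(fw$h2, dmu); gbm <- colSums(dmu)
  gWv <- crossprod(fw$h2, dlv); gbv <- colSums(dlv)
  dh2 <- (dmu %*% t(params$Wm) + dlv %*% t(params$Wv)) * (fw$h2 > 0)
  gWe2 <- crossprod(fw$h1, dh2); gbe2 <- colSums(dh2)
  dh1 <- dh2 %*% t(params$We2) * (fw$h1 > 0)
  gWe1 <- crossprod(fw$ein, dh1); gbe1 <- colSums(dh1)
  list(We1 = gWe1, be1 = gbe1, We2 = gWe2, be2 = gbe2, Wm = gWm, bm = gbm,
       Wv = gWv, bv = gbv, Wd1 = gWd1, bd1 = gbd1, Wd2 = gWd2, bd2 = gbd2,
       Wo = gWo, bo = gbo, log_gamma = g_lg)
}

#' Train the second-stage conditional VAE
#'
#' Fits a conditional VAE on stage-1 latent codes with one-hot label
#' conditioning of both encoder and decoder, maximizing the ELBO with a
#' single trainable reconstruction-variance parameter gamma that balances
#' reconstruction against the KL regularizer.
#'
#' @param codes latent-code tibble or numeric matrix (rows = shapes).
#' @param labels condition labels, one per row (>= 2 distinct).
#' @param config a [cvae_config()].
#' @return a `cvae_params` with attributes `levels` (condition labels) and
#'   `history` (per-epoch negative-ELBO tibble).
#' @export
train_cvae <- function(codes, labels, config = cvae_config()) {
  X <- if (is.data.frame(codes)) codes_matrix(codes) else as.matrix(codes)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop("need >= 2 condition labels")
  if (nrow(X) != length(labels)) stop("codes/labels length mismatch")
  lv_set <- levels(labels)
  O_all <- one_hot(labels, lv_set)
  params <- build_cvae(ncol(X), length(lv_set), config)
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(config$seed + 1L)
  opt <- lapply(params[cvae_wnames], adam_init)
  n <- nrow(X); q <- config$cvae_latent_dim
  history <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    tot <- 0
    for (b0 in seq(1, n, by = config$batch_size)) {
      rows <- perm[b0:min(b0 + config$batch_size - 1, n)]
      Xb <- X[rows, , drop = FALSE]; Ob <- O_all[rows, , drop = FALSE]
      eps <- matrix(stats::rnorm(length(rows) * q), length(rows), q)
      fw <- cvae_forward(params, Xb, Ob, eps)
      if (any(!is.finite(fw$xhat)))
        stop("CVAE training diverged: non-finite decoder output at epoch ",
             epoch)
      gamma <- exp(params$log_gamma)
      nb <- length(rows)
      loss <- mean(0.5 * (rowSums((Xb - fw$xhat)^2) / gamma +
                            ncol(X) * log(2 * pi * gamma)) +
                     kl_gaussian(fw$mu, fw$lv))
      tot <- tot + loss * nb
      gr <- cvae_backward(params, Xb, Ob, eps, fw)
      for (w in cvae_wnames) {
        opt[[w]] <- adam_step(opt[[w]], gr[[w]], config$lr)
        params[[w]] <- params[[w]] - opt[[w]]$step
      }
    }
    history[epoch] <- tot / n
  }
  attr(params, "levels") <- lv_set
  attr(params, "history") <- tibble::tibble(epoch = seq_len(config$epochs),
                                            neg_elbo = history)
  attr(params, "config") <- config
  params
}

#' Encode data to stage-2 posterior means
#'
#' @param params trained `cvae_params`.
#' @param codes stage-1 codes (tibble or matrix).
#' @param labels condition labels.
#' @return n x q matrix of posterior mean latents.
#' @export
encode_cvae <- function(params, codes, labels) {
  X <- if (is.data.frame(codes)) codes_matrix(codes) else as.matrix(codes)
  O <- one_hot(labels, attr(params, "levels"))
  fw <- cvae_forward(params, X, O, matrix(0, nrow(X), params$cvae_latent_dim))
  fw$mu
}

#' Generate stage-1 codes from the conditional prior
#'
#' Draws `z ~ N(0, I)` in the stage-2 latent space and decodes with the
#' conditioning label; chaining the result through the SDF decoder and
#' [extract_mesh()] yields generated meshes for that class.
#'
#' @param params trained `cvae_params`.
#' @param label single condition label.
#' @param n number of draws (0 gives an empty matrix).
#' @param seed integer seed.
#' @return n x input_dim matrix of generated stage-1 codes.
#' @export
sample_conditional <- function(params, label, n, seed = 1L) {
  lv_set <- attr(params, "levels")
  if (!label %in% lv_set) stop("unknown condition label: ", label)
  q <- params$cvae_latent_dim
  if (n == 0) return(matrix(numeric(0), 0, params$input_dim))
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(seed)
  z <- matrix(stats::rnorm(n * q), n, q)
  O <- one_hot(rep(label, n), lv_set)
  din <- cbind(z, O)
  g1 <- pmax(sweep(din %*% params$Wd1, 2, params$bd1, "+"), 0)
  g2 <- pmax(sweep(g1 %*% params$Wd2, 2, params$bd2, "+"), 0)
  sweep(g2 %*% params$Wo, 2, params$bo, "+")
}

#' Per-dimension normality diagnostics
#'
#' Excess kurtosis and maximal absolute deviation of the standardized
#' sample quantiles from the standard-normal quantiles, per column
#' (columns standardized first).  Used to compare the tail behavior of
#' stage-1 codes against stage-2 latents.
#'
#' @param X n x d numeric matrix (n >= 20).
#' @return tibble with columns `dimension`, `excess_kurtosis`,
#'   `qq_max_deviation`, `degenerate`.
#' @export
normality_diagnostics <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 20) stop("need >= 20 rows")
  probs <- stats::qnorm(stats::ppoints(nrow(X)))
  purrr::map_dfr(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    if (stats::sd(x) == 0)
      return(tibble::tibble(dimension = j, excess_kurtosis = NA_real_,
                            qq_max_deviation = NA_real_, degenerate = TRUE))
    z <- (x - mean(x)) / stats::sd(x)
    tibble::tibble(dimension = j,
                   excess_kurtosis = mean(z^4) / (mean(z^2))^2 - 3,
                   qq_max_deviation = max(abs(sort(z) - probs)),
                   degenerate = FALSE)
  })
}
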