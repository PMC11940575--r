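#' Measure bill shape indices on a canonically posed mesh
#'
#' Length is the extent along x (the tip axis); width and depth are the y
#' and z extents within the base slab (the rear 10% of the x extent, an
#' in-silico analogue of caliper measurements at the bill base).
#' Elongation is length over the mean of width and depth; broadness is
#' width over depth.  Both indices are unitless and scale-invariant.
#'
#' @param mesh a `beak_mesh` in canonical pose (tip towards +x).  Without
#'   landmarks the pose cannot be verified; pass `assume_canonical = TRUE`
#'   for meshes decoded from latent codes, which inherit the training
#'   frame.
#' @param assume_canonical skip the landmark check.
#' @return one-row tibble with `length`, `width`, `depth`, `elongation`,
#'   `broadness`.
#' @export
measure_beak <- function(mesh, assume_canonical = FALSE) {
  if (!assume_canonical) {
    if (is.null(mesh$landmarks))
      stop("non-canonical pose: landmarks absent ",
           "(use assume_canonical = TRUE for decoded meshes)")
    lf <- landmark_frame(mesh$landmarks)
    if (max(abs(lf$rotation - diag(3))) > 1e-6 ||
        max(abs(lf$translation)) > 1e-6 * max(abs(mesh$vertices)))
      stop("non-canonical pose: reorient the mesh first")
  }
  v <- mesh$vertices
  len <- diff(range(v[, 1]))
  slab <- v[, 1] <= min(v[, 1]) + 0.1 * len
  wid <- diff(range(v[slab, 2]))
  dep <- diff(range(v[slab, 3]))
  tibble::tibble(length = len, width = wid, depth = dep,
                 elongation = len / mean(c(wid, dep)),
                 broadness = wid / dep)
}

#' Discover an interpretable latent direction
#'
#' Regresses a per-shape response (e.g. measured elongation) on the latent
#' codes with no intercept; the coefficient vector points along the
#' direction of maximum increase of the response in latent space.  The
#' reported R^2 is uncentered, consistent with the no-intercept fit.
#'
#' @param codes latent-code tibble (`shape_id`, `z_1..z_d`).
#' @param response numeric vector, one value per row of `codes`.
#' @param response_name label stored with the direction.
#' @return a `latent_direction`: list with `vector`, `response_name`,
#'   `r_squared`.
#' @export
discover_vector <- function(codes, response, response_name = "response") {
  Zm <- codes_matrix(codes)
  d <- ncol(Zm); n <- nrow(Zm)
  if (!all(is.finite(response))) stop("response must be finite")
  if (length(response) != n) stop("response length must match codes rows")
  qrz <- qr(Zm)
  if (qrz$rank < d) {
    bad <- setdiff(seq_len(d), qrz$pivot[seq_len(qrz$rank)])
    stop("rank-deficient code matrix; collinear dimensions: ",
         paste(colnames(Zm)[bad], collapse = ", "))
  }
  if (n < d + 5)
    warning("fewer than latent_dim + 5 shapes; direction estimate is noisy")
  beta <- qr.coef(qrz, response)
  rss <- sum((response - Zm %*% beta)^2)
  structure(list(vector = as.numeric(beta), response_name = response_name,
                 r_squared = 1 - rss / sum(response^2)),
            class = "latent_direction")
}

#' @export
print.latent_direction <- function(x, ...) {
  cat("<latent_direction> ", x$response_name, ": d = ", length(x$vector),
      ", uncentered R^2 = ", signif(x$r_squared, 3), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.latent_direction <- function(x, ...) {
  tibble::tibble(term = paste0("z_", seq_along(x$vector)),
                 estimate = x$vector)
}

#' @exportS3Method generics::glance
glance.latent_direction <- function(x, ...) {
  tibble::tibble(response = x$response_name, r.squared = x$r_squared,
                 latent_dim = length(x$vector))
}

#' Traverse latent space along a direction
#'
#' Moves a code along the unit-normalized direction: `code +
#' step * unit(direction)` for each step (steps are in prior-SD units).
#'
#' @param code latent vector.
#' @param direction a `latent_direction` (or bare numeric vector).
#' @param steps numeric vector of signed step sizes.
#' @return matrix with one traversed code per row.
#' @export
apply_vector <- function(code, direction, steps) {
  v <- if (inherits(direction, "latent_direction")) direction$vector else direction
  if (length(v) != length(code)) stop("dimension mismatch")
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("zero direction")
  u <- v / nv
  out <- t(vapply(steps, function(s) code + s * u, numeric(length(code))))
  rownames(out) <- paste0("step_", steps)
  out
}

#' Draw codes from the latent prior
#'
#' I.i.d. spherical Gaussian draws matching the autodecoder's latent
#' prior (unit variance by default).
#'
#' @param n number of draws (>= 0).
#' @param latent_dim dimension.
#' @param seed integer seed.
#' @param sd prior scale.
#' @return n x latent_dim matrix.
#' @export
sample_prior_codes <- function(n, latent_dim = 64L, seed = 1L, sd = 1) {
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(seed)
  matrix(stats::rnorm(n * latent_dim, 0, sd), nrow = n, ncol = latent_dim)
}

#' Cubic-spline path through latent waypoints
#'
#' Natural cubic spline through the waypoints (one spline per latent
#' dimension, parameterized by waypoint index), evaluated at `n_frames`
#' evenly spaced parameter values; passes through every waypoint exactly.
#'
#' @param waypoints matrix of ordered waypoint codes (>= 2 rows).
#' @param n_frames number of output codes.
#' @return n_frames x latent_dim matrix.
#' @export
latent_path <- function(waypoints, n_frames = 100L) {
  waypoints <- as.matrix(waypoints)
  k <- nrow(waypoints)
  if (k < 2) stop("need >= 2 waypoints")
  if (any(rowSums(abs(diff(waypoints))) == 0))
    stop("degenerate segment: duplicate consecutive waypoints")
  tt <- seq_len(k)
  xout <- seq(1, k, length.out = n_frames)
  apply(waypoints, 2, function(y) {
    if (k == 2) stats::approx(tt, y, xout = xout)$y
    else stats::spline(tt, y, xout = xout, method = "natural")$y
  })
}

#' Two-dimensional embedding of latent codes
#'
#' Thin wrapper over established embedding implementations (UMAP via
#' uwot, t-SNE via Rtsne); only parameter plumbing and seeding are
#' handled here.  Deterministic under a fixed seed per the backends'
#' single-threaded contracts.
#'
#' @param codes latent-code tibble or numeric matrix (>= 10 rows).
#' @param method `"umap"` or `"tsne"`.
#' @param n_neighbors UMAP graph neighborhood size (default 25); for
#'   t-SNE the perplexity is `min(30, (n - 1) / 3)`.
#' @param seed integer seed.
#' @return n x 2 matrix of embedding coordinates (class `embed2d`).
#' @export
embed_2d <- function(codes, method = c("umap", "tsne"), n_neighbors = 25L,
                     seed = 1L) {
  method <- match.arg(method)
  X <- if (is.data.frame(codes)) codes_matrix(codes) else as.matrix(codes)
  if (nrow(X) < 10) stop("need >= 10 shapes to embed")
  if (n_neighbors >= nrow(X)) stop("`n_neighbors` must be < number of shapes")
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(seed)
  emb <- if (method == "umap") {
    uwot::umap(X, n_neighbors = n_neighbors, n_components = 2,
               n_threads = 1, n_sgd_threads = 1)
  } else {
    Rtsne::Rtsne(X, dims = 2, perplexity = min(30, (nrow(X) - 1) / 3),
                 check_duplicates = FALSE, pca = FALSE, num_threads = 1)$Y
  }
  dimnames(emb) <- list(rownames(X), c("dim1", "dim2"))
  structure(emb, class = c("embed2d", class(emb)), method = method)
}
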