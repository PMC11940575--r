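#' Signed distance from points to a watertight mesh
#'
#' The magnitude is the exact distance to the nearest point of the triangle
#' surface (interior projection and edge clamping per face); the sign is
#' negative inside, resolved by the generalized winding number (robust for
#' near-degenerate geometry).
#'
#' @param mesh a watertight `beak_mesh`.
#' @param points K x 3 matrix of query points.
#' @return numeric vector of K signed distances.
#' @export
signed_distance <- function(mesh, points) {
  if (!is_watertight(mesh))
    stop("sign undefined: mesh is not watertight")
  points <- rbind(points, deparse.level = 0)
  ud <- unsigned_mesh_distance(mesh, points)
  w <- winding_number(mesh, points)
  ifelse(abs(w) > 0.5, -ud, ud)
}

# exact unsigned distance, blocked over (point, face) pairs so all inner
# products run through BLAS; per-pair squared distances are expanded in
# dot products of precomputed face data
unsigned_mesh_distance <- function(mesh, points, chunk = 256L) {
  v <- mesh$vertices; f <- mesh$faces
  A <- v[f[, 1], , drop = FALSE]
  B <- v[f[, 2], , drop = FALSE]
  C <- v[f[, 3], , drop = FALSE]
  E0 <- B - A; E1 <- C - A
  a <- rowSums(E0^2); b <- rowSums(E0 * E1); cc <- rowSums(E1^2)
  det <- pmax(a * cc - b^2, 1e-300)
  AA <- rowSums(A^2); AE0 <- rowSums(A * E0); AE1 <- rowSums(A * E1)
  segS <- list(A, A, B)
  segD <- list(E0, E1, C - B)
  segL <- lapply(segD, function(D) pmax(rowSums(D^2), 1e-300))
  segSS <- lapply(segS, function(S) rowSums(S^2))
  segSD <- lapply(1:3, function(k) rowSums(segS[[k]] * segD[[k]]))

  nP <- nrow(points)
  out <- numeric(nP)
  # work on M x m blocks (faces down the rows) so per-face vectors recycle
  # down columns without explicit expansion
  for (b0 in seq(1, nP, by = chunk)) {
    rows <- b0:min(b0 + chunk - 1, nP)
    P <- points[rows, , drop = FALSE]
    pp <- rowSums(P^2)
    Pt <- t(P)
    # D = A - p per pair; d = E0.D, e = E1.D, DD = |D|^2  (M x m each)
    d <- AE0 - E0 %*% Pt
    e <- AE1 - E1 %*% Pt
    DD <- sweep(AA - 2 * (A %*% Pt), 2, pp, "+")
    s <- (b * e - cc * d) / det
    t_ <- (b * d - a * e) / det
    best <- DD + s * s * a + t_ * t_ * cc + 2 * (s * d + t_ * e + s * t_ * b)
    best[!(s >= 0 & t_ >= 0 & (s + t_) <= 1)] <- Inf
    for (k in 1:3) {
      sd_ <- segSD[[k]] - segD[[k]] %*% Pt
      tt <- pmin(pmax(-sd_ / segL[[k]], 0), 1)
      ss <- sweep(segSS[[k]] - 2 * (segS[[k]] %*% Pt), 2, pp, "+")
      best <- pmin(best, ss + 2 * tt * sd_ + tt * tt * segL[[k]])
    }
    out[rows] <- sqrt(pmax(apply(best, 2, min), 0))
  }
  out
}

#' Generalized winding number
#'
#' Sum of signed solid angles of all faces about each query point, divided
#' by 4*pi; approximately 1 inside a closed outward-oriented surface and 0
#' outside.
#'
#' @param mesh a `beak_mesh`.
#' @param points K x 3 matrix.
#' @return numeric vector of K winding numbers.
#' @export
winding_number <- function(mesh, points, chunk = 256L) {
  v <- mesh$vertices; f <- mesh$faces
  V1 <- v[f[, 1], , drop = FALSE]
  V2 <- v[f[, 2], , drop = FALSE]
  V3 <- v[f[, 3], , drop = FALSE]
  points <- rbind(points, deparse.level = 0)
  # det[V1-p, V2-p, V3-p] is linear in p: det0 - p . W with
  # W = V2 x V3 - V1 x V3 + V1 x V2 per face
  cross3 <- function(X, Y) cbind(X[, 2] * Y[, 3] - X[, 3] * Y[, 2],
                                 X[, 3] * Y[, 1] - X[, 1] * Y[, 3],
                                 X[, 1] * Y[, 2] - X[, 2] * Y[, 1])
  W <- cross3(V2, V3) - cross3(V1, V3) + cross3(V1, V2)
  det0 <- rowSums(V1 * cross3(V2, V3))
  s11 <- rowSums(V1^2); s22 <- rowSums(V2^2); s33 <- rowSums(V3^2)
  s12 <- rowSums(V1 * V2); s23 <- rowSums(V2 * V3); s13 <- rowSums(V1 * V3)

  nP <- nrow(points)
  out <- numeric(nP)
  for (b0 in seq(1, nP, by = chunk)) {
    rows <- b0:min(b0 + chunk - 1, nP)
    P <- points[rows, , drop = FALSE]
    pp <- rowSums(P^2)
    Pt <- t(P)
    p1 <- V1 %*% Pt; p2 <- V2 %*% Pt; p3 <- V3 %*% Pt   # M x m
    la <- sqrt(pmax(sweep(s11 - 2 * p1, 2, pp, "+"), 0))
    lb <- sqrt(pmax(sweep(s22 - 2 * p2, 2, pp, "+"), 0))
    lc <- sqrt(pmax(sweep(s33 - 2 * p3, 2, pp, "+"), 0))
    ab <- sweep(s12 - p1 - p2, 2, pp, "+")
    bc <- sweep(s23 - p2 - p3, 2, pp, "+")
    ca <- sweep(s13 - p1 - p3, 2, pp, "+")
    det <- det0 - W %*% Pt
    denom <- la * lb * lc + ab * lc + bc * la + ca * lb
    out[rows] <- colSums(2 * atan2(det, denom)) / (4 * pi)
  }
  out
}

#' Analytic signed distance of simple primitives
#'
#' Exact SDF oracles for a sphere of radius `r` and an axis-aligned box of
#' given half extents, both centered at the origin.
#'
#' @param primitive `"sphere"` or `"box"`.
#' @param points K x 3 matrix.
#' @param r sphere radius (positive).
#' @param half_extents box half extents (3 positive reals).
#' @return numeric vector of K signed distances.
#' @export
analytic_sdf <- function(primitive = c("sphere", "box"), points, r = 1,
                         half_extents = c(1, 1, 1)) {
  primitive <- match.arg(primitive)
  points <- rbind(points, deparse.level = 0)
  if (primitive == "sphere") {
    if (r <= 0) stop("sphere radius must be positive")
    sqrt(rowSums(points^2)) - r
  } else {
    if (any(half_extents <= 0)) stop("box half extents must be positive")
    q <- abs(points) - matrix(half_extents, nrow(points), 3, byrow = TRUE)
    outside <- sqrt(rowSums(pmax(q, 0)^2))
    inside <- pmin(apply(q, 1, max), 0)
    outside + inside
  }
}

#' Draw the two-part Monte-Carlo SDF training sample
#'
#' Draws `n_uniform` points uniformly in the unit ball (radius-inversion
#' sampling) and `n_surface` points on the mesh surface (area-uniform)
#' jittered by isotropic Gaussian noise of sd `noise_sd`, then computes
#' their signed distances.  Points jittered outside the unit ball are
#' radially projected back to its boundary.
#'
#' @param mesh normalized watertight `beak_mesh` (inside the unit sphere).
#' @param n_uniform number of uniform-in-ball points.
#' @param n_surface number of near-surface points; defaults to `n_uniform`
#'   (the two parts are equal-sized by default).
#' @param noise_sd positive Gaussian jitter sd, unit-sphere units.
#' @param seed integer seed.
#' @param shape_id identifier stored with the sample.
#' @return an `sdf_sample`: list with `shape_id`, `points` (K x 3),
#'   `distances` (K), `near_surface` (K logical), `seed`.
#' @export
sample_sdf <- function(mesh, n_uniform = 1000, n_surface = n_uniform,
                       noise_sd = 0.01, seed = 1L, shape_id = "shape") {
  if (noise_sd <= 0) stop("`noise_sd` must be positive")
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(seed)
  # uniform in ball
  g <- matrix(stats::rnorm(3 * n_uniform), ncol = 3)
  g <- g / sqrt(rowSums(g^2))
  rad <- stats::runif(n_uniform)^(1 / 3)
  p_unif <- g * rad
  # near-surface
  p_surf <- sample_surface_points(mesh, n_surface) +
    matrix(stats::rnorm(3 * n_surface, 0, noise_sd), ncol = 3)
  nrm <- sqrt(rowSums(p_surf^2))
  over <- nrm > 1
  if (any(over)) p_surf[over, ] <- p_surf[over, , drop = FALSE] / nrm[over]
  pts <- rbind(p_unif, p_surf)
  structure(list(
    shape_id = shape_id,
    points = pts,
    distances = signed_distance(mesh, pts),
    near_surface = rep(c(FALSE, TRUE), c(n_uniform, n_surface)),
    seed = as.integer(seed)), class = "sdf_sample")
}

#' @export
print.sdf_sample <- function(x, ...) {
  cat("<sdf_sample> ", x$shape_id, ": ", nrow(x$points), " points (",
      sum(x$near_surface), " near-surface), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @rdname sample_sdf
#' @param x an `sdf_sample`.
#' @param ... ignored.
#' @exportS3Method tibble::as_tibble
as_tibble.sdf_sample <- function(x, ...) {
  s <- x   # keep the sample out of the data mask: a column is named `x`
  tibble::tibble(shape_id = s$shape_id,
                 x = s$points[, 1], y = s$points[, 2], z = s$points[, 3],
                 distance = s$distances, near_surface = s$near_surface)
}

#' Persist SDF samples
#'
#' One R serialization file per shape plus a CSV manifest
#' (`shape_id, file, n, seed`).
#'
#' @param samples list of `sdf_sample` objects.
#' @param dir output directory.
#' @return manifest tibble, invisibly.
#' @export
write_sdf_samples <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- purrr::map_dfr(samples, function(s) {
    file <- paste0(s$shape_id, ".rds")
    saveRDS(s, file.path(dir, file))
    tibble::tibble(shape_id = s$shape_id, file = file,
                   n = nrow(s$points), seed = s$seed)
  })
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' @rdname write_sdf_samples
#' @export
read_sdf_samples <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(man)), function(i)
    readRDS(file.path(dir, man$file[i])))
}
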