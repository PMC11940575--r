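#' Evaluate a latent code on a dense SDF grid
#'
#' Evaluates the decoder at a cell-centered `resolution^3` lattice over an
#' axis-aligned cube (lattice coordinate `i` of `R` maps to
#' `lo + (i - 0.5) * (hi - lo) / R`, recorded in the result so meshes are
#' reproducible bit-exactly).
#'
#' @param params a trained `sdf_decoder`.
#' @param code latent vector of length `latent_dim`.
#' @param resolution lattice size per axis (>= 8).
#' @param bounds numeric length-2 cube bounds, default `c(-1, 1)`.
#' @param chunk evaluation batch size.
#' @return an `sdf_grid`: list with `values` (R x R x R array), `bounds`,
#'   `resolution`, `coords` (lattice coordinates per axis).
#' @export
predict_sdf_grid <- function(params, code, resolution = 64L,
                             bounds = c(-1, 1), chunk = 65536L) {
  resolution <- as.integer(resolution)
  if (resolution < 8L) stop("`resolution` must be >= 8")
  coords <- bounds[1] + (seq_len(resolution) - 0.5) * diff(bounds) / resolution
  pts <- as.matrix(expand.grid(x = coords, y = coords, z = coords))
  vals <- numeric(nrow(pts))
  for (b0 in seq(1, nrow(pts), by = chunk)) {
    rows <- b0:min(b0 + chunk - 1, nrow(pts))
    vals[rows] <- decode_sdf(params, code, pts[rows, , drop = FALSE])
  }
  structure(list(values = array(vals, rep(resolution, 3)), bounds = bounds,
                 resolution = resolution, coords = coords),
            class = "sdf_grid")
}

#' Wrap an array of SDF values as a grid object
#'
#' Mainly for testing extraction against analytic fields.
#'
#' @param values R x R x R numeric array.
#' @param bounds numeric length-2 cube bounds.
#' @return an `sdf_grid`.
#' @export
sdf_grid <- function(values, bounds = c(-1, 1)) {
  resolution <- dim(values)[1]
  if (resolution < 8L) stop("grid resolution must be >= 8")
  coords <- bounds[1] + (seq_len(resolution) - 0.5) * diff(bounds) / resolution
  structure(list(values = values, bounds = bounds, resolution = resolution,
                 coords = coords), class = "sdf_grid")
}

# Kuhn 6-tetrahedra cube subdivision (corner offsets in x, y, z); shared
# cube-face diagonals agree between neighboring cells, so the extracted
# surface is watertight wherever the level set stays inside the grid.
.tet_offsets <- local({
  corner <- function(...) rbind(...)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  lapply(perms, function(p) {
    pts <- matrix(0, 4, 3)
    for (i in 1:3) { pts[i + 1, ] <- pts[i, ]; pts[i + 1, p[i]] <- 1 }
    pts
  })
})

#' Extract the level-set mesh from an SDF grid
#'
#' Marching-tetrahedra isosurface extraction (each lattice cell split into
#' six tetrahedra): watertight by construction for level sets contained in
#' the grid interior, with outward (toward positive SDF) orientation.
#'
#' @param grid an `sdf_grid`.
#' @param level isovalue (default 0, the surface).
#' @return a `beak_mesh`.
#' @export
extract_mesh <- function(grid, level = 0) {
  V <- grid$values
  R <- grid$resolution
  if (all(V > level) || all(V < level))
    stop("empty isosurface: grid values do not cross the level")
  # nudge exact hits so interpolation parameters stay in (0, 1)
  V[V == level] <- level + 1e-12 * max(abs(V) + 1)
  co <- grid$coords

  # candidate cells: those whose 8 corners straddle the level
  idx <- expand.grid(i = seq_len(R - 1), j = seq_len(R - 1), k = seq_len(R - 1))
  gid <- function(i, j, k) i + (j - 1L) * R + (k - 1L) * R * R
  corners <- mapply(function(di, dj, dk) gid(idx$i + di, idx$j + dj, idx$k + dk),
                    c(0, 1, 0, 1, 0, 1, 0, 1), c(0, 0, 1, 1, 0, 0, 1, 1),
                    c(0, 0, 0, 0, 1, 1, 1, 1))
  Vc <- matrix(V[corners], nrow(idx), 8)
  lo <- Vc[, 1] < level; hi <- Vc[, 1] > level
  for (c_ in 2:8) { lo <- lo | Vc[, c_] < level; hi <- hi | Vc[, c_] > level }
  act <- which(lo & hi)
  if (!length(act)) stop("empty isosurface: no cell crosses the level")
  idx <- idx[act, , drop = FALSE]

  # global ids of the 4 corners of each tetrahedron of each active cell
  tets <- do.call(rbind, lapply(.tet_offsets, function(off) {
    cbind(gid(idx$i + off[1, 1], idx$j + off[1, 2], idx$k + off[1, 3]),
          gid(idx$i + off[2, 1], idx$j + off[2, 2], idx$k + off[2, 3]),
          gid(idx$i + off[3, 1], idx$j + off[3, 2], idx$k + off[3, 3]),
          gid(idx$i + off[4, 1], idx$j + off[4, 2], idx$k + off[4, 3]))
  }))
  tv <- matrix(V[tets], nrow(tets), 4)
  inside <- tv < level
  ncase <- inside %*% c(1L, 2L, 4L, 8L)
  keep <- ncase > 0L & ncase < 15L
  tets <- tets[keep, , drop = FALSE]
  inside <- inside[keep, , drop = FALSE]
  if (!nrow(tets)) stop("empty isosurface: no tetrahedron crosses the level")

  # reorder each tet's corners so inside vertices come first
  ord <- t(apply(inside, 1, order, decreasing = TRUE))
  row_i <- seq_len(nrow(tets))
  g <- function(col) tets[cbind(row_i, ord[, col])]
  t1 <- g(1); t2 <- g(2); t3 <- g(3); t4 <- g(4)
  n_in <- rowSums(inside)

  # edge crossing points, deduplicated by global lattice-point pair
  edges <- rbind(cbind(t1, t2), cbind(t1, t3), cbind(t1, t4),
                 cbind(t2, t3), cbind(t2, t4), cbind(t3, t4))
  ek <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  uniq <- !duplicated(ek)
  ue <- edges[uniq, , drop = FALSE]
  pos_of <- function(gids) {
    i <- (gids - 1L) %% R + 1L
    j <- ((gids - 1L) %/% R) %% R + 1L
    k <- (gids - 1L) %/% (R * R) + 1L
    cbind(co[i], co[j], co[k])
  }
  va <- V[ue[, 1]]; vb <- V[ue[, 2]]
  tt <- (level - va) / (vb - va)
  tt[!is.finite(tt)] <- 0.5
  P <- pos_of(ue[, 1]) + pmin(pmax(tt, 0), 1) * (pos_of(ue[, 2]) - pos_of(ue[, 1]))
  vid <- match(ek, ek[uniq])                    # edge -> new vertex index
  nr <- nrow(tets)
  e12 <- vid[row_i]; e13 <- vid[nr + row_i]; e14 <- vid[2 * nr + row_i]
  e23 <- vid[3 * nr + row_i]; e24 <- vid[4 * nr + row_i]
  e34 <- vid[5 * nr + row_i]

  tris <- list()
  c1 <- n_in == 1L            # triangle on edges from the inside vertex
  if (any(c1)) tris[[1]] <- cbind(e12, e13, e14)[c1, , drop = FALSE]
  c3 <- n_in == 3L            # triangle on edges from the outside vertex
  if (any(c3)) tris[[2]] <- cbind(e14, e24, e34)[c3, , drop = FALSE]
  c2 <- n_in == 2L            # quad split into two triangles
  if (any(c2)) {
    tris[[3]] <- cbind(e13, e14, e24)[c2, , drop = FALSE]
    tris[[4]] <- cbind(e13, e24, e23)[c2, , drop = FALSE]
  }
  f <- do.call(rbind, tris)
  which_tet <- c(if (any(c1)) which(c1), if (any(c3)) which(c3),
                 if (any(c2)) which(c2), if (any(c2)) which(c2))

  # orient every triangle so its normal points toward the outside region
  a <- P[f[, 1], , drop = FALSE]
  b <- P[f[, 2], , drop = FALSE]
  cc <- P[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  ref_in <- pos_of(t1[which_tet])               # an inside lattice point
  flip <- rowSums(nrm * (ref_in - a)) > 0
  f[flip, ] <- f[flip, c(1, 3, 2), drop = FALSE]

  mesh <- beak_mesh(P, f, provenance = sprintf(
    "extract_mesh(resolution=%d, level=%g)", R, level))
  clean_mesh(mesh, component_frac = 0)
}

#' Symmetric chamfer distance between two meshes
#'
#' Mean nearest-neighbor distance between area-uniform surface samples,
#' averaged over both directions.  Each mesh's sample is drawn with the
#' same seed, so `chamfer_distance(a, b)` equals `chamfer_distance(b, a)`
#' exactly.
#'
#' @param a,b `beak_mesh` objects.
#' @param n_points surface samples per mesh.
#' @param seed integer seed.
#' @return non-negative scalar.
#' @export
chamfer_distance <- function(a, b, n_points = 2500L, seed = 1L) {
  if (nrow(a$faces) == 0 || nrow(b$faces) == 0) stop("degenerate mesh")
  pa <- sample_surface_points(a, n_points, seed = seed)
  pb <- sample_surface_points(b, n_points, seed = seed)
  (mean(nn_dist(pa, pb)) + mean(nn_dist(pb, pa))) / 2
}

# nearest-neighbor distances from each row of A to the point set B
nn_dist <- function(A, B, chunk = 512L) {
  nb2 <- rowSums(B^2)
  out <- numeric(nrow(A))
  for (b0 in seq(1, nrow(A), by = chunk)) {
    rows <- b0:min(b0 + chunk - 1, nrow(A))
    Ak <- A[rows, , drop = FALSE]
    d2 <- outer(rowSums(Ak^2), nb2, "+") - 2 * tcrossprod(Ak, B)
    out[rows] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Reconstruct a mesh from a latent code
#'
#' Convenience composition of [predict_sdf_grid()] and [extract_mesh()].
#'
#' @inheritParams predict_sdf_grid
#' @param level isovalue.
#' @return a `beak_mesh`.
#' @export
reconstruct_mesh <- function(params, code, resolution = 64L,
                             bounds = c(-1, 1), level = 0) {
  extract_mesh(predict_sdf_grid(params, code, resolution, bounds), level)
}
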