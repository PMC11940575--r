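#' Clean a triangle mesh
#'
#' Merges duplicate vertices, drops degenerate (zero-area or repeated-index)
#' faces and duplicate faces, removes small disconnected debris components
#' (< `component_frac` of total faces), and verifies edge-manifoldness.
#'
#' @param mesh a `beak_mesh`.
#' @param tol vertices closer than this (per coordinate) are merged.
#' @param component_frac connected components with fewer than this fraction
#'   of faces are removed (scanner-debris heuristic).
#' @return cleaned `beak_mesh`.
#' @export
clean_mesh <- function(mesh, tol = 1e-9, component_frac = 0.01) {
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(v) == 0 || nrow(f) == 0) stop("empty mesh")

  # merge duplicate vertices (quantized key)
  q <- round(v / tol)
  key <- paste(q[, 1], q[, 2], q[, 3])
  keep <- !duplicated(key)
  map <- match(key, key[keep])
  v <- v[keep, , drop = FALSE]
  f[] <- map[f]

  # degenerate faces: repeated indices or (numerically) zero area
  rep_idx <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  f <- f[!rep_idx, , drop = FALSE]
  cr <- face_cross(beak_mesh(v, f))
  f <- f[sqrt(rowSums(cr^2)) > 1e-14, , drop = FALSE]

  # duplicate faces (same vertex set, any winding/rotation)
  fkey <- apply(f, 1, function(r) paste(sort(r), collapse = "_"))
  f <- f[!duplicated(fkey), , drop = FALSE]

  # small-component removal via vertex connectivity
  g <- igraph::graph_from_edgelist(
    rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(v) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  face_comp <- comp[f[, 1]]
  sizes <- table(face_comp)
  big <- names(sizes)[sizes >= component_frac * nrow(f)]
  f <- f[face_comp %in% as.integer(big), , drop = FALSE]

  # drop now-unreferenced vertices
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(v)); remap[used] <- seq_along(used)
  v <- v[used, , drop = FALSE]
  f[] <- remap[f]

  # manifoldness diagnostic
  tab <- table(mesh_edge_keys(f))
  bad <- sum(tab > 2L)
  if (bad > 0)
    stop("unrepairable non-manifold topology: ", bad,
         " edges shared by more than two faces")

  out <- beak_mesh(v, f, landmarks = mesh$landmarks,
                   provenance = c(mesh$provenance, "clean_mesh"))
  out
}

# Rotation/translation mapping the landmark frame to canonical pose:
# +x = base-center -> tip, +z = component of base bottom -> top orthogonal
# to x, y = z cross x (right-handed).  Returns list(rotation, translation)
# with new = rotation %*% old + translation.
landmark_frame <- function(landmarks) {
  need <- c("tip", "base_top", "base_bottom")
  if (is.null(landmarks) || !all(need %in% rownames(landmarks)))
    stop("orientation undefined: landmarks tip/base_top/base_bottom required")
  tip <- landmarks["tip", ]; bt <- landmarks["base_top", ]
  bb <- landmarks["base_bottom", ]
  bc <- (bt + bb) / 2
  xhat <- tip - bc
  nx <- sqrt(sum(xhat^2))
  up <- bt - bb
  if (nx < 1e-12 || sqrt(sum(up^2)) < 1e-12)
    stop("orientation undefined: coincident landmarks")
  xhat <- xhat / nx
  zres <- up - sum(up * xhat) * xhat
  nz <- sqrt(sum(zres^2))
  if (nz < 1e-9 * sqrt(sum(up^2)))
    stop("orientation undefined: collinear landmarks")
  zhat <- zres / nz
  yhat <- c(zhat[2] * xhat[3] - zhat[3] * xhat[2],
            zhat[3] * xhat[1] - zhat[1] * xhat[3],
            zhat[1] * xhat[2] - zhat[2] * xhat[1])
  R <- rbind(xhat, yhat, zhat)
  dimnames(R) <- NULL
  list(rotation = R, translation = as.vector(-R %*% bc))
}

apply_rigid <- function(mesh, transform) {
  R <- transform$rotation; tr <- transform$translation
  mesh$vertices <- sweep(mesh$vertices %*% t(R), 2, tr, "+")
  if (!is.null(mesh$landmarks))
    mesh$landmarks <- sweep(mesh$landmarks %*% t(R), 2, tr, "+")
  mesh
}

canonicalize_pose <- function(mesh) {
  apply_rigid(mesh, landmark_frame(mesh$landmarks))
}

#' Reorient a mesh into the canonical landmark frame
#'
#' Rigidly (rotation + translation only, det = +1, no scaling or
#' reflection) maps the mesh so the base-center-to-tip direction lies on
#' +x and the base bottom-to-top direction lies in the x-z plane, with the
#' base center at the origin.
#'
#' @param mesh a `beak_mesh` with `tip`, `base_top`, `base_bottom`
#'   landmarks (non-collinear).
#' @return list with elements `mesh` (reoriented) and `transform`
#'   (list `rotation` 3x3 with det +1, `translation` 3-vector;
#'   `new = rotation %*% old + translation`).
#' @export
reorient_mesh <- function(mesh) {
  tf <- landmark_frame(mesh$landmarks)
  out <- apply_rigid(mesh, tf)
  out$provenance <- c(out$provenance, "reorient_mesh")
  list(mesh = out, transform = tf)
}

# --- minimal enclosing sphere of a small point set (exact, brute force
# over support subsets of size <= 4; adequate for the five hull points) ---

circumsphere2 <- function(p) {
  c_ <- colMeans(p); list(center = c_, r = sqrt(sum((p[1, ] - c_)^2)))
}
circumsphere3 <- function(p) {
  a <- p[1, ]; b <- p[2, ]; c_ <- p[3, ]
  ab <- b - a; ac <- c_ - a
  ab2 <- sum(ab^2); ac2 <- sum(ac^2)
  cr <- c(ab[2] * ac[3] - ab[3] * ac[2], ab[3] * ac[1] - ab[1] * ac[3],
          ab[1] * ac[2] - ab[2] * ac[1])
  d <- 2 * sum(cr^2)
  if (d < 1e-300) return(NULL)
  # circumcenter in the triangle plane
  o <- (ab2 * (c(ac[2] * cr[3] - ac[3] * cr[2], ac[3] * cr[1] - ac[1] * cr[3],
                 ac[1] * cr[2] - ac[2] * cr[1])) +
        ac2 * (c(cr[2] * ab[3] - cr[3] * ab[2], cr[3] * ab[1] - cr[1] * ab[3],
                 cr[1] * ab[2] - cr[2] * ab[1]))) / d
  list(center = a + o, r = sqrt(sum(o^2)))
}
circumsphere4 <- function(p) {
  A <- cbind(2 * sweep(p[2:4, , drop = FALSE], 2, p[1, ], "-"))
  b <- rowSums(p[2:4, , drop = FALSE]^2) - sum(p[1, ]^2)
  ctr <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(ctr)) return(NULL)
  list(center = ctr, r = sqrt(sum((p[1, ] - ctr)^2)))
}

min_enclosing_sphere <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  best <- NULL
  consider <- function(s) {
    if (is.null(s) || !all(is.finite(c(s$center, s$r)))) return()
    d <- sqrt(rowSums(sweep(points, 2, s$center)^2))
    if (all(d <= s$r * (1 + 1e-9))) {
      if (is.null(best) || s$r < best$r) best <<- s
    }
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    consider(circumsphere2(points[c(i, j), , drop = FALSE]))
  if (n >= 3)
    for (s in utils::combn(n, 3, simplify = FALSE))
      consider(circumsphere3(points[s, , drop = FALSE]))
  if (n >= 4)
    for (s in utils::combn(n, 4, simplify = FALSE))
      consider(circumsphere4(points[s, , drop = FALSE]))
  if (is.null(best)) stop("could not compute enclosing sphere")
  best
}

#' Five bill hull points
#'
#' The tip, upper and lower base (landmarks) plus the extreme left/right
#' vertices within a base slab of thickness 5% of the bill length,
#' measured along the base-center-to-tip axis.
#'
#' @param mesh a `beak_mesh` with landmarks.
#' @return 5 x 3 matrix.
#' @export
bill_hull_points <- function(mesh) {
  lm <- mesh$landmarks
  tf <- landmark_frame(lm)
  # work in the canonical frame, report in the original frame
  vc <- sweep(mesh$vertices %*% t(tf$rotation), 2, tf$translation, "+")
  L <- max(vc[, 1]) - min(vc[, 1])
  slab <- vc[, 1] <= 0.05 * L   # base center sits at x = 0
  if (!any(slab)) slab <- vc[, 1] <= stats::quantile(vc[, 1], 0.05)
  i_left <- which(slab)[which.min(vc[slab, 2])]
  i_right <- which(slab)[which.max(vc[slab, 2])]
  rbind(tip = lm["tip", ], base_top = lm["base_top", ],
        base_bottom = lm["base_bottom", ],
        base_left = mesh$vertices[i_left, ],
        base_right = mesh$vertices[i_right, ])
}

#' Trim a mesh with its enclosing sphere and cap the hole
#'
#' Computes the minimal sphere enclosing the five bill hull points, removes
#' geometry outside it (faces crossing the sphere are cut at the sphere and
#' re-triangulated), and closes each resulting boundary loop with a
#' triangle fan to the loop centroid projected onto the sphere.
#'
#' @param mesh a `beak_mesh` with landmarks.
#' @return watertight trimmed `beak_mesh`.
#' @export
trim_and_cap <- function(mesh) {
  hull <- bill_hull_points(mesh)
  sph <- min_enclosing_sphere(hull)
  out <- clip_mesh_to_sphere(mesh, sph$center, sph$r)
  if (nrow(out$faces) < 0.1 * nrow(mesh$faces))
    stop("suspicious geometry: trimming removed more than 90% of faces")
  out$landmarks <- mesh$landmarks
  out$provenance <- c(mesh$provenance, "trim_and_cap")
  out
}

# Clip a mesh to the inside of a sphere and cap boundary loops.
clip_mesh_to_sphere <- function(mesh, center, r, tol = 1e-9) {
  v <- sweep(mesh$vertices, 2, center)
  f <- mesh$faces
  d <- sqrt(rowSums(v^2))
  inside <- d <= r * (1 + tol)
  n_in <- inside[f[, 1]] + inside[f[, 2]] + inside[f[, 3]]

  if (all(n_in == 3L) && is_watertight(mesh)) {  # untouched
    out <- mesh
    out$provenance <- c(out$provenance, "clip: no-op")
    return(out)
  }

  keep_faces <- f[n_in == 3L, , drop = FALSE]
  cross_faces <- f[n_in %in% c(1L, 2L), , drop = FALSE]

  new_v <- list()
  edge_cache <- new.env(hash = TRUE)
  nv0 <- nrow(v)
  edge_point <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    got <- edge_cache[[key]]
    if (!is.null(got)) return(got)
    a <- v[i, ]; b <- v[j, ]
    ab <- b - a
    # solve |a + t ab|^2 = r^2 for t in [0,1]
    A <- sum(ab^2); B <- 2 * sum(a * ab); C <- sum(a^2) - r^2
    disc <- max(B^2 - 4 * A * C, 0)
    ts <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
    t <- ts[ts >= -1e-9 & ts <= 1 + 1e-9][1]
    if (is.na(t)) t <- 0.5
    p <- a + min(max(t, 0), 1) * ab
    new_v[[length(new_v) + 1L]] <<- p
    idx <- nv0 + length(new_v)
    edge_cache[[key]] <- idx
    idx
  }

  tri_out <- list()
  boundary <- list()   # directed boundary edges (on the sphere)
  for (k in seq_len(nrow(cross_faces))) {
    tri <- cross_faces[k, ]
    ins <- inside[tri]
    # rotate so pattern starts at an inside vertex
    shift <- which(ins)[1] - 1L
    tri <- tri[((seq_len(3) - 1L + shift) %% 3L) + 1L]
    ins <- inside[tri]
    if (sum(ins) == 1L) {
      # one inside vertex a; cut edges a-b and a-c
      a <- tri[1]; b <- tri[2]; c_ <- tri[3]
      pab <- edge_point(a, b); pca <- edge_point(c_, a)
      tri_out[[length(tri_out) + 1L]] <- c(a, pab, pca)
      boundary[[length(boundary) + 1L]] <- c(pab, pca)
    } else {
      # two inside: rotate so the outside vertex is last
      while (ins[3]) { tri <- tri[c(2, 3, 1)]; ins <- inside[tri] }
      a <- tri[1]; b <- tri[2]; c_ <- tri[3]   # c outside
      pbc <- edge_point(b, c_); pca <- edge_point(c_, a)
      tri_out[[length(tri_out) + 1L]] <- c(a, b, pbc)
      tri_out[[length(tri_out) + 1L]] <- c(a, pbc, pca)
      boundary[[length(boundary) + 1L]] <- c(pbc, pca)
    }
  }

  v_all <- rbind(v, do.call(rbind, new_v))
  f_all <- rbind(keep_faces,
                 if (length(tri_out)) do.call(rbind, tri_out))
  if (is.null(f_all) || nrow(f_all) == 0)
    stop("suspicious geometry: trimming removed every face")

  # also collect pre-existing open boundary edges that survived (for
  # meshes that were open to begin with, e.g. hemisphere fixtures)
  ek <- mesh_edge_keys(f_all)
  open_edges <- names(table(ek))[table(ek) == 1L]
  if (length(open_edges)) {
    # recover directed form from faces
    fe <- rbind(f_all[, c(1, 2)], f_all[, c(2, 3)], f_all[, c(3, 1)])
    keys <- paste(pmin(fe[, 1], fe[, 2]), pmax(fe[, 1], fe[, 2]), sep = "_")
    dir_edges <- fe[keys %in% open_edges, , drop = FALSE]
    loops <- order_boundary_loops(dir_edges)
    for (loop in loops) {
      ctr <- colMeans(v_all[loop, , drop = FALSE])
      nc <- sqrt(sum(ctr^2))
      apex <- if (nc > 1e-12) ctr / nc * r else c(0, 0, r)
      v_all <- rbind(v_all, apex)
      ai <- nrow(v_all)
      # cap winding opposite to the boundary direction closes the surface
      m <- length(loop)
      cap <- cbind(loop, c(loop[-1], loop[1]), ai)[, c(2, 1, 3)]
      f_all <- rbind(f_all, cap)
    }
  }

  out <- beak_mesh(sweep(v_all, 2, center, "+"), f_all)
  out <- clean_mesh(out, component_frac = 0)
  orient_outward(out)
}

# Order directed boundary edges into closed loops (list of vertex cycles).
# Vertices may carry several boundary edges (jagged rims); edges are
# consumed one at a time, walking until the start vertex recurs.
order_boundary_loops <- function(edges) {
  if (nrow(edges) == 0) return(list())
  used <- rep(FALSE, nrow(edges))
  out_edges <- split(seq_len(nrow(edges)), edges[, 1])
  loops <- list()
  for (e0 in seq_len(nrow(edges))) {
    if (used[e0]) next
    start <- edges[e0, 1]
    loop <- integer(); cur_edge <- e0
    ok <- FALSE
    repeat {
      used[cur_edge] <- TRUE
      loop <- c(loop, edges[cur_edge, 1])
      nxt_v <- edges[cur_edge, 2]
      if (nxt_v == start) { ok <- TRUE; break }
      cand <- out_edges[[as.character(nxt_v)]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break                  # open chain; drop
      cur_edge <- cand[1]
    }
    if (ok && length(loop) >= 3) loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Normalize a mesh into the unit sphere
#'
#' Centers the mesh at its bounding-box midpoint and scales isotropically
#' so every vertex lies within radius 1 of the origin; the scale and center
#' are returned so reconstructions can be mapped back to model units
#' (`original = normalized / scale + center`).
#'
#' @param mesh a watertight `beak_mesh`.
#' @return list with `mesh`, `scale` (positive real) and `center`
#'   (3-vector).
#' @export
normalize_to_unit_sphere <- function(mesh) {
  v <- mesh$vertices
  rng <- apply(v, 2, range)
  if (any(!is.finite(rng)) || all(rng[2, ] - rng[1, ] < 1e-300))
    stop("degenerate mesh: zero extent")
  center <- colMeans(rng)
  rad <- sqrt(max(rowSums(sweep(v, 2, center)^2)))
  if (rad <= 0) stop("degenerate mesh: zero extent")
  scale <- 1 / rad
  mesh$vertices <- sweep(v, 2, center) * scale
  if (!is.null(mesh$landmarks))
    mesh$landmarks <- sweep(mesh$landmarks, 2, center) * scale
  mesh$provenance <- c(mesh$provenance, "normalize_to_unit_sphere")
  list(mesh = mesh, scale = scale, center = center)
}

#' Full mesh preprocessing pipeline
#'
#' Clean, reorient to the landmark frame, trim with the enclosing sphere
#' and cap, and normalize into the unit sphere, in that order.
#'
#' @param mesh a `beak_mesh` with landmarks.
#' @return list with `mesh` (preprocessed, unit-sphere units), `transform`
#'   (rigid reorientation), `scale`, `center`.
#' @export
preprocess_mesh <- function(mesh) {
  m <- clean_mesh(mesh)
  ro <- reorient_mesh(m)
  m <- trim_and_cap(ro$mesh)
  nz <- normalize_to_unit_sphere(m)
  list(mesh = nz$mesh, transform = ro$transform,
       scale = nz$scale, center = nz$center)
}
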