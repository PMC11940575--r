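#' Triangle mesh objects
#'
#' A `beak_mesh` is the package's shape carrier: a list with an `N x 3`
#' numeric `vertices` matrix (model units), an `M x 3` integer `faces`
#' matrix of 1-based vertex indices with consistent winding, an optional
#' `landmarks` matrix (rows named `tip`, `base_top`, `base_bottom`), and a
#' `provenance` character vector recording applied transforms.
#'
#' @param vertices N x 3 numeric matrix of vertex coordinates.
#' @param faces M x 3 matrix of 1-based vertex indices.
#' @param landmarks optional 3 x 3 matrix with rownames `tip`, `base_top`,
#'   `base_bottom`, one landmark per row.
#' @param provenance character vector of processing steps already applied.
#' @return An object of class `beak_mesh`.
#' @export
beak_mesh <- function(vertices, faces, landmarks = NULL, provenance = character()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("`vertices` must have 3 columns")
  if (ncol(faces) != 3L) stop("`faces` must have 3 columns")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range [1, nrow(vertices)]")
  if (!is.null(landmarks)) {
    landmarks <- as.matrix(landmarks)
    if (is.null(rownames(landmarks)))
      stop("`landmarks` must have rownames naming each landmark")
  }
  structure(
    list(vertices = vertices, faces = faces, landmarks = landmarks,
         provenance = as.character(provenance)),
    class = "beak_mesh"
  )
}

#' @export
print.beak_mesh <- function(x, ...) {
  cat("<beak_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces", sep = "")
  if (!is.null(x$landmarks))
    cat(", landmarks: ", paste(rownames(x$landmarks), collapse = ", "), sep = "")
  cat("\n")
  if (length(x$provenance))
    cat("  provenance: ", paste(x$provenance, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

# Undirected edge table: one row per half-edge, key = "lo_hi".
mesh_edge_keys <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "_")
}

#' Watertightness check
#'
#' A mesh is watertight (closed 2-manifold) when every undirected edge is
#' shared by exactly two faces and the two incident faces traverse it in
#' opposite directions (consistent orientation).
#'
#' @param mesh a `beak_mesh`.
#' @return `TRUE`/`FALSE`.
#' @export
is_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(FALSE)
  keys <- mesh_edge_keys(mesh$faces)
  tab <- table(keys)
  if (any(tab != 2L)) return(FALSE)
  # orientation consistency: each directed edge must appear exactly once
  f <- mesh$faces
  dir_keys <- c(paste(f[, 1], f[, 2]), paste(f[, 2], f[, 3]), paste(f[, 3], f[, 1]))
  !anyDuplicated(dir_keys)
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume by the divergence theorem (sum of signed tetrahedra to the
#' origin); positive for outward-facing windings.
#'
#' @param mesh a `beak_mesh`.
#' @param signed return the signed value rather than its absolute value.
#' @return scalar volume in model units cubed.
#' @export
mesh_volume <- function(mesh, signed = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
    a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  vol <- sum(det6) / 6
  if (signed) vol else abs(vol)
}

# Per-face doubled area vectors (cross products); rows correspond to faces.
face_cross <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Total surface area
#' @param mesh a `beak_mesh`.
#' @return scalar area.
#' @export
mesh_area <- function(mesh) {
  cr <- face_cross(mesh)
  sum(sqrt(rowSums(cr^2))) / 2
}

# Flip winding so enclosed volume is positive (outward normals).
orient_outward <- function(mesh) {
  if (mesh_volume(mesh, signed = TRUE) < 0)
    mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

#' Area-uniform surface sampling
#'
#' Draws points uniformly over the mesh surface: faces sampled with
#' probability proportional to area, positions by uniform barycentric
#' coordinates.
#'
#' @param mesh a `beak_mesh`.
#' @param n number of points.
#' @param seed integer seed (RNG state is restored on exit).
#' @return n x 3 matrix of surface points.
#' @export
sample_surface_points <- function(mesh, n, seed = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(set_rng_state(old))
    set.seed(seed)
  }
  cr <- face_cross(mesh)
  area <- sqrt(rowSums(cr^2))
  idx <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = area)
  r1 <- sqrt(stats::runif(n)); r2 <- stats::runif(n)
  w1 <- 1 - r1; w2 <- r1 * (1 - r2); w3 <- r1 * r2
  v <- mesh$vertices; f <- mesh$faces[idx, , drop = FALSE]
  w1 * v[f[, 1], , drop = FALSE] + w2 * v[f[, 2], , drop = FALSE] +
    w3 * v[f[, 3], , drop = FALSE]
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

#' Read and write triangle meshes
#'
#' Minimal readers/writers for ASCII PLY, OBJ and ASCII STL carrying
#' vertices and triangular faces (no color/texture attributes).
#'
#' @param mesh a `beak_mesh`.
#' @param path file path; format chosen by extension (`.ply`, `.obj`, `.stl`).
#' @return `write_mesh` returns `path` invisibly; `read_mesh` a `beak_mesh`.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w"); on.exit(close(con))
  if (ext == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(v)),
                 "property double x", "property double y", "property double z",
                 paste("element face", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    utils::write.table(format(v, digits = 17, scientific = FALSE, trim = TRUE),
                       con, row.names = FALSE, col.names = FALSE, quote = FALSE)
    utils::write.table(cbind(3L, f - 1L), con, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  } else if (ext == "obj") {
    writeLines(paste("v", v[, 1], v[, 2], v[, 3]), con)
    writeLines(paste("f", f[, 1], f[, 2], f[, 3]), con)
  } else if (ext == "stl") {
    cr <- face_cross(mesh)
    nrm <- cr / pmax(sqrt(rowSums(cr^2)), .Machine$double.eps)
    writeLines("solid beakmorph", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        sprintf("facet normal %g %g %g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
        "  outer loop",
        sprintf("    vertex %g %g %g", v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
        "  endloop", "endfacet"), con)
    }
    writeLines("endsolid beakmorph", con)
  } else stop("unsupported mesh format: ", ext)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "ply") {
    hdr_end <- which(lines == "end_header")[1]
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)[1]))
    nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)[1]))
    vl <- lines[(hdr_end + 1):(hdr_end + nv)]
    fl <- lines[(hdr_end + nv + 1):(hdr_end + nv + nf)]
    v <- matrix(scan(text = vl, quiet = TRUE), ncol = 3, byrow = TRUE)
    fraw <- matrix(scan(text = fl, quiet = TRUE), ncol = 4, byrow = TRUE)
    beak_mesh(v, fraw[, 2:4] + 1L)
  } else if (ext == "obj") {
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    v <- matrix(scan(text = sub("^v ", "", vl), quiet = TRUE), ncol = 3, byrow = TRUE)
    # face entries may carry /texture/normal suffixes
    f <- t(vapply(strsplit(sub("^f ", "", fl), "\\s+"), function(p)
      as.integer(sub("/.*$", "", p[1:3])), integer(3)))
    beak_mesh(v, f)
  } else if (ext == "stl") {
    vx <- grep("^\\s*vertex", lines, value = TRUE)
    v <- matrix(scan(text = sub("^\\s*vertex", "", vx), quiet = TRUE),
                ncol = 3, byrow = TRUE)
    nf <- nrow(v) / 3
    # merge exactly-equal vertices so the result can be watertight
    key <- apply(v, 1, paste, collapse = "|")
    uk <- !duplicated(key)
    map <- match(key, key[uk])
    beak_mesh(v[uk, , drop = FALSE], matrix(map, ncol = 3, byrow = TRUE))
  } else stop("unsupported mesh format: ", ext)
}

#' Icosphere test mesh
#'
#' Subdivided icosahedron projected onto a sphere; a standard watertight
#' fixture whose analytic signed distance is known.
#'
#' @param subdiv number of 4-to-1 subdivision rounds (level 0 = icosahedron).
#' @param radius sphere radius.
#' @param center sphere center (3-vector).
#' @return a `beak_mesh` with `20 * 4^subdiv` faces.
#' @export
icosphere <- function(subdiv = 3, radius = 1, center = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_env <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      got <- mid_env[[key]]
      if (!is.null(got)) return(got)
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1L]] <<- m
      idx <- nv + length(newv)
      mid_env[[key]] <- idx
      idx
    }
    newf <- matrix(0L, nrow(f) * 4, 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c_ <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newf[(k - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c_, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  v <- sweep(v * radius, 2, center, "+")
  orient_outward(beak_mesh(v, f, provenance = sprintf("icosphere(subdiv=%d)", subdiv)))
}
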