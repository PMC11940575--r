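#' Parametric beak-like mesh
#'
#' Generates a watertight, manifold, outward-oriented triangle mesh from a
#' small set of shape parameters.  The family is a tapered body with
#' elliptical cross-sections (semi-axes `width/2`, `depth/2` at the base,
#' shrinking to a point at the tip), closed at the back by an ellipsoidal
#' cap, with optional dorsal `curvature` and a tip-downturn `hook`.  After
#' construction the mesh is placed in canonical pose (tip on the +x axis,
#' base top towards +z) and rescaled anisotropically so its bounding
#' extents equal (`length`, `width`, `depth`) exactly.  Three landmarks
#' (`tip`, `base_top`, `base_bottom`) are emitted analytically.
#'
#' @param params a list or one-row data frame with fields `length`,
#'   `width`, `depth` (positive reals, model units), `curvature` (real,
#'   0 = straight), `hook` (real in `[0, 1]`), and optionally `species_id`,
#'   `niche`.
#' @param resolution positive integer >= 8 controlling ring counts; the
#'   mesh has about `resolution^2` vertices.
#' @return a `beak_mesh` with landmarks.
#' @examples
#' m <- make_beak_mesh(list(length = 4, width = 1, depth = 1), resolution = 16)
#' is_watertight(m)
#' @export
make_beak_mesh <- function(params, resolution = 48) {
  p <- as.list(params)
  for (nm in c("length", "width", "depth")) {
    if (is.null(p[[nm]]) || !is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("invalid parameter: `", nm, "` must be a positive real")
  }
  curvature <- if (is.null(p$curvature)) 0 else p$curvature
  hook <- if (is.null(p$hook)) 0 else p$hook
  if (hook < 0 || hook > 1) stop("invalid parameter: `hook` must lie in [0, 1]")
  resolution <- as.integer(resolution)
  if (resolution < 8L) stop("`resolution` must be >= 8")

  m <- 4L * max(2L, resolution %/% 4L)         # ring size, multiple of 4
  nb <- resolution                              # body rings (t = 0 .. 1-)
  nc <- max(3L, resolution %/% 4L)              # cap rings
  # cap depth as a fraction of the unit-length body; kept shallower than
  # the 10% base slab used for width/depth measurement so the slab always
  # reaches the full-width base ring
  h <- 0.08

  theta <- 2 * pi * (seq_len(m) - 1L) / m
  ct <- cos(theta); st <- sin(theta)
  ay <- p$width / 2; az <- p$depth / 2
  profile <- function(t) (1 - t)^0.65
  center_z <- function(t) p$depth * (curvature * t^2 - hook * t^5)

  verts <- list()
  # cap pole then cap rings (phi = 0 at pole, pi/2 at base rim, rim excluded)
  verts[[1]] <- c(-h, 0, center_z(0))
  for (k in seq_len(nc - 1L)) {
    phi <- (pi / 2) * k / nc
    r <- sin(phi)
    verts[[length(verts) + 1L]] <-
      cbind(-h * cos(phi), ay * r * ct, az * r * st + center_z(0))
  }
  # body rings t = 0 (base rim) .. just short of tip
  tb <- (seq_len(nb) - 1L) / nb
  for (t in tb) {
    r <- profile(t)
    verts[[length(verts) + 1L]] <-
      cbind(t, ay * r * ct, az * r * st + center_z(t))
  }
  verts[[length(verts) + 1L]] <- c(1, 0, center_z(1))  # tip pole
  v <- do.call(rbind, verts)

  n_rings <- (nc - 1L) + nb
  ring_start <- function(i) 2L + (i - 1L) * m     # first vertex of ring i
  tip_idx <- nrow(v)
  faces <- vector("list", n_rings + 1L)
  # pole fan at cap
  j2 <- c(2:m, 1L)
  faces[[1]] <- cbind(1L, ring_start(1L) + j2 - 1L, ring_start(1L) + seq_len(m) - 1L)
  for (i in seq_len(n_rings - 1L)) {
    a <- ring_start(i) + seq_len(m) - 1L
    b <- ring_start(i + 1L) + seq_len(m) - 1L
    a2 <- ring_start(i) + j2 - 1L
    b2 <- ring_start(i + 1L) + j2 - 1L
    faces[[i + 1L]] <- rbind(cbind(a, a2, b2), cbind(a, b2, b))
  }
  last <- ring_start(n_rings) + seq_len(m) - 1L
  last2 <- ring_start(n_rings) + j2 - 1L
  faces[[n_rings + 1L]] <- cbind(last, last2, tip_idx)
  f <- do.call(rbind, faces)

  base_ring <- ring_start(nc)                    # first body ring (t = 0)
  i_top <- base_ring + which.min(abs(theta - pi / 2)) - 1L
  i_bot <- base_ring + which.min(abs(theta - 3 * pi / 2)) - 1L
  lm <- rbind(tip = v[tip_idx, ], base_top = v[i_top, ], base_bottom = v[i_bot, ])

  mesh <- beak_mesh(v, f, landmarks = lm)
  mesh <- canonicalize_pose(mesh)
  # exact bounding extents
  targets <- c(p$length, p$width, p$depth)
  rng <- apply(mesh$vertices, 2, range)
  sc <- targets / (rng[2, ] - rng[1, ])
  mesh$vertices <- sweep(mesh$vertices, 2, sc, "*")
  mesh$landmarks <- sweep(mesh$landmarks, 2, sc, "*")
  mesh <- orient_outward(mesh)
  mesh$provenance <- sprintf("make_beak_mesh(resolution=%d)", resolution)
  mesh
}

#' Sample class-structured shape parameter tables
#'
#' Draws per-specimen shape parameters from class-specific normal
#' distributions, emulating trait tables with controllable class imbalance.
#'
#' @param class_spec data frame with one row per class: columns `niche`,
#'   `n` (count >= 1), and `<trait>_mean` / `<trait>_sd` pairs for the
#'   traits `length`, `width`, `depth`, `curvature`, `hook` (all `_sd` >= 0).
#' @param seed integer seed.
#' @param niche_levels optional declared label set; any class label in
#'   `class_spec` outside it is an error.
#' @return tibble with `sum(class_spec$n)` rows and columns `species_id`,
#'   `length`, `width`, `depth`, `curvature`, `hook`, `niche`.
#' @export
sample_class_params <- function(class_spec, seed = 1L, niche_levels = NULL) {
  class_spec <- as.data.frame(class_spec)
  stopifnot(all(c("niche", "n") %in% names(class_spec)))
  if (any(class_spec$n < 1)) stop("class counts must be >= 1")
  if (!is.null(niche_levels) && !all(class_spec$niche %in% niche_levels))
    stop("unknown class label in spec: ",
         paste(setdiff(class_spec$niche, niche_levels), collapse = ", "))
  traits <- c("length", "width", "depth", "curvature", "hook")
  for (tr in traits) {
    sdcol <- paste0(tr, "_sd")
    if (sdcol %in% names(class_spec) && any(class_spec[[sdcol]] < 0))
      stop("trait SDs must be >= 0")
  }
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(seed)
  rows <- lapply(seq_len(nrow(class_spec)), function(i) {
    cs <- class_spec[i, ]
    n <- cs$n
    out <- list()
    for (tr in traits) {
      is_size <- tr %in% c("length", "width", "depth")
      # absent columns fall back to unit size / zero shape modifiers
      mu <- if (!is.null(cs[[paste0(tr, "_mean")]])) cs[[paste0(tr, "_mean")]]
            else if (is_size) 1 else 0
      sd <- if (!is.null(cs[[paste0(tr, "_sd")]])) cs[[paste0(tr, "_sd")]] else 0
      if (is_size && mu <= 0 && sd == 0)
        stop("size trait `", tr, "` has non-positive mean and zero SD")
      x <- stats::rnorm(n, mu, sd)
      if (is_size) {
        bad <- which(x <= 0)
        while (length(bad)) {   # resample non-physical draws
          x[bad] <- stats::rnorm(length(bad), mu, sd)
          bad <- which(x <= 0)
        }
      }
      if (tr == "hook") x <- pmin(pmax(x, 0), 1)
      out[[tr]] <- x
    }
    tibble::tibble(niche = as.character(cs$niche), !!!out)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out,
    species_id = sprintf("sp%04d", dplyr::row_number()), .before = 1)
  dplyr::relocate(out, "niche", .after = "hook")
}

#' Simulate a clade with Brownian-motion shape evolution
#'
#' Pure-birth (Yule) ultrametric tree via [ape::rphylo()], with continuous
#' shape parameters evolved along it by Brownian motion so phylogenetic
#' signal is known by construction.  Size traits (`length`, `width`,
#' `depth`) evolve on the log scale and are exponentiated, keeping them
#' positive; other traits evolve on the natural scale.
#'
#' @param n_tips number of tips (>= 3).
#' @param birth_rate speciation rate of the pure-birth process.
#' @param sigma named vector of BM rates (per unit branch length; >= 0),
#'   one per trait.  Unnamed entries are recycled against `root_state`.
#' @param root_state named vector of root trait values (natural scale;
#'   size traits must be positive).
#' @param seed integer seed controlling both topology and traits.
#' @return an object of class `sim_clade`: list with `tree` (ape `phylo`),
#'   `tip_params` (tibble keyed by `species_id`), `sigma`, `root_state`.
#' @export
simulate_clade <- function(n_tips, birth_rate = 1, sigma, root_state, seed = 1L) {
  if (n_tips < 3) stop("`n_tips` must be >= 3")
  if (any(sigma < 0)) stop("`sigma` entries must be >= 0")
  if (is.null(names(root_state)))
    names(root_state) <- paste0("trait_", seq_along(root_state))
  sigma <- rep_len(sigma, length(root_state))
  names(sigma) <- names(root_state)
  size_traits <- intersect(names(root_state), c("length", "width", "depth"))
  if (any(root_state[size_traits] <= 0))
    stop("size traits in `root_state` must be positive")

  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  tree$tip.label <- sprintf("sp%04d", seq_len(n_tips))

  x_root <- root_state
  x_root[size_traits] <- log(root_state[size_traits])
  X <- bm_on_tree(tree, sigma, x_root)
  X[, size_traits] <- exp(X[, size_traits, drop = FALSE])

  tip_params <- tibble::as_tibble(X, rownames = "species_id")
  structure(list(tree = tree, tip_params = tip_params,
                 sigma = sigma, root_state = root_state),
            class = "sim_clade")
}

# Brownian motion along tree edges; returns tips x traits matrix
# (preorder edge walk, one rnorm call per edge for seed stability).
bm_on_tree <- function(tree, sigma, root_state) {
  k <- length(root_state)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  vals <- matrix(NA_real_, n_node, k)
  root <- n_tip + 1L
  vals[root, ] <- root_state
  edge <- tree$edge
  ord <- order(edge[, 1])                       # parents before children
  # ensure preorder: repeatedly fill reachable edges (tree edges are
  # already parent-sorted for rphylo output, loop is defensive)
  todo <- ord
  while (length(todo)) {
    ready <- todo[!is.na(vals[edge[todo, 1], 1])]
    if (!length(ready)) stop("tree edges are not connected to the root")
    for (e in ready) {
      len <- tree$edge.length[e]
      vals[edge[e, 2], ] <- vals[edge[e, 1], ] +
        stats::rnorm(k, 0, sigma * sqrt(len))
    }
    todo <- setdiff(todo, ready)
  }
  out <- vals[seq_len(n_tip), , drop = FALSE]
  dimnames(out) <- list(tree$tip.label, names(root_state))
  out
}

#' @export
print.sim_clade <- function(x, ...) {
  cat("<sim_clade> ", length(x$tree$tip.label), " tips, traits: ",
      paste(names(x$root_state), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Clade-membership labels
#'
#' Cuts an ultrametric tree into `k` groups of tips by their cophenetic
#' distances; used to construct labels that are phylogenetically structured
#' by design.
#'
#' @param tree an ape `phylo`.
#' @param k number of groups.
#' @return factor of group labels named by tip.
#' @export
clade_labels <- function(tree, k) {
  d <- stats::as.dist(ape::cophenetic.phylo(tree))
  cl <- stats::cutree(stats::hclust(d, method = "average"), k = k)
  out <- factor(paste0("clade_", cl[tree$tip.label]))
  names(out) <- tree$tip.label
  out
}

#' Write a simulated clade to plain-text files
#'
#' @param clade a `sim_clade`.
#' @param dir output directory (`tree.nwk`, `tip_params.csv`).
#' @return `dir`, invisibly.
#' @export
write_clade <- function(clade, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(clade$tree, file.path(dir, "tree.nwk"))
  utils::write.csv(clade$tip_params, file.path(dir, "tip_params.csv"),
                   row.names = FALSE)
  invisible(dir)
}
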