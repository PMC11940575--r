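# Independent oracles and small fixtures used across test files.

# Blomberg's K by the literal published recipe, coded independently of the
# package's trace kernel (explicit GLS mean, explicit quadratic forms).
blomberg_K_direct <- function(x, tree) {
  C <- ape::vcv.phylo(tree)
  x <- x[rownames(C)]
  n <- length(x)
  Ci <- solve(C)
  ahat <- as.numeric(t(rep(1, n)) %*% Ci %*% x) / sum(Ci)
  r <- x - ahat
  mse0 <- as.numeric(t(r) %*% r) / (n - 1)
  mse <- as.numeric(t(r) %*% Ci %*% r) / (n - 1)
  (mse0 / mse) / ((sum(diag(C)) - n / sum(Ci)) / (n - 1))
}

# axis-aligned box as a watertight beak_mesh with canonical landmarks
box_mesh <- function(lx = 4, ly = 1, lz = 1) {
  v <- as.matrix(expand.grid(x = c(0, lx), y = c(-ly / 2, ly / 2),
                             z = c(-lz / 2, lz / 2)))
  f <- rbind(
    c(1, 3, 7), c(1, 7, 5), c(2, 6, 8), c(2, 8, 4),  # x faces
    c(1, 5, 6), c(1, 6, 2), c(3, 4, 8), c(3, 8, 7),  # y faces
    c(1, 2, 4), c(1, 4, 3), c(5, 7, 8), c(5, 8, 6))  # z faces
  lm <- rbind(tip = c(lx, 0, 0), base_top = c(0, 0, lz / 2),
              base_bottom = c(0, 0, -lz / 2))
  beakmorph:::orient_outward(beak_mesh(v, f, landmarks = lm))
}

random_rigid <- function(seed) {
  set.seed(seed)
  th <- stats::runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  list(R = Rz %*% Ry %*% Rx, t = stats::runif(3, -2, 2))
}

apply_rigid_raw <- function(mesh, R, t) {
  mesh$vertices <- sweep(mesh$vertices %*% t(R), 2, t, "+")
  if (!is.null(mesh$landmarks))
    mesh$landmarks <- sweep(mesh$landmarks %*% t(R), 2, t, "+")
  mesh
}

# trilinear interpolation of an sdf_grid at a point
grid_interp <- function(grid, p) {
  co <- grid$coords; R <- grid$resolution
  h <- co[2] - co[1]
  ix <- pmin(pmax(floor((p - co[1]) / h) + 1, 1), R - 1)
  fr <- (p - co[ix]) / h
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- prod(ifelse(c(dx, dy, dz) == 1, fr, 1 - fr))
    acc <- acc + w * grid$values[ix[1] + dx, ix[2] + dy, ix[3] + dz]
  }
  acc
}
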