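test_that("clean_mesh merges duplicates and preserves clean meshes", {
  ico <- icosphere(2)
  expect_identical(nrow(clean_mesh(ico)$vertices), nrow(ico$vertices))

  # duplicated vertex referenced by one face corner
  dup <- ico
  dup$vertices <- rbind(dup$vertices, dup$vertices[1, ])
  extra <- nrow(dup$vertices)
  i <- which(dup$faces[, 1] == 1L)[1]
  dup$faces[i, 1] <- as.integer(extra)
  cleaned <- clean_mesh(dup)
  expect_identical(nrow(cleaned$vertices), nrow(ico$vertices))
  expect_true(is_watertight(cleaned))
})

test_that("duplicate overlapping faces are removed and watertightness restored", {
  ico <- icosphere(1)
  dup <- beak_mesh(ico$vertices, rbind(ico$faces, ico$faces[5, ]))
  expect_false(is_watertight(dup))
  cleaned <- clean_mesh(dup)
  expect_identical(nrow(cleaned$faces), nrow(ico$faces))
  tab <- table(beakmorph:::mesh_edge_keys(cleaned$faces))
  expect_true(all(tab == 2L))
})

test_that("reorientation is a proper rigid round trip", {
  m <- make_beak_mesh(list(length = 4, width = 1, depth = 1,
                           curvature = 0.3, hook = 0.4), resolution = 24)
  rt <- random_rigid(42)
  moved <- apply_rigid_raw(m, rt$R, rt$t)
  out <- reorient_mesh(moved)
  expect_lt(max(abs(out$mesh$vertices - m$vertices)), 1e-6)
  expect_equal(det(out$transform$rotation), 1, tolerance = 1e-9)
  expect_lt(max(abs(crossprod(out$transform$rotation) - diag(3))), 1e-9)

  # already-canonical mesh: transform is the identity
  out2 <- reorient_mesh(m)
  expect_lt(max(abs(out2$transform$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(out2$transform$translation)), 1e-9)

  # a reflected mesh still yields det +1 (reflections never introduced)
  refl <- m
  refl$vertices[, 2] <- -refl$vertices[, 2]
  refl$landmarks[, 2] <- -refl$landmarks[, 2]
  out3 <- reorient_mesh(refl)
  expect_equal(det(out3$transform$rotation), 1, tolerance = 1e-9)
})

test_that("rigid reorientation preserves pairwise distances", {
  m <- make_beak_mesh(list(length = 3, width = 1, depth = 1), resolution = 16)
  rt <- random_rigid(7)
  moved <- apply_rigid_raw(m, rt$R, rt$t)
  out <- reorient_mesh(moved)$mesh
  idx <- seq(1, nrow(m$vertices), by = 17)
  expect_lt(max(abs(dist(out$vertices[idx, ]) - dist(moved$vertices[idx, ]))),
            1e-9)
})

test_that("collinear landmarks make orientation undefined", {
  m <- icosphere(1)
  m$landmarks <- rbind(tip = c(1, 0, 0), base_top = c(0.5, 0, 0),
                       base_bottom = c(0, 0, 0))
  expect_error(reorient_mesh(m), "collinear")
  m$landmarks <- NULL
  expect_error(reorient_mesh(m), "landmarks")
})

test_that("a closed mesh inside the enclosing sphere passes trim untouched", {
  # landmarks well outside the mesh so their enclosing sphere contains it
  ico <- icosphere(2, radius = 1)
  ico$landmarks <- rbind(tip = c(2.5, 0, 0), base_top = c(-2.5, 0, 2.5),
                         base_bottom = c(-2.5, 0, -2.5))
  out <- trim_and_cap(ico)
  expect_identical(out$vertices, ico$vertices)
  expect_identical(out$faces, ico$faces)
  expect_match(paste(out$provenance, collapse = ";"), "trim_and_cap")
})

test_that("an open hemisphere is capped into a watertight solid", {
  ico <- icosphere(3)
  f <- ico$faces
  cx <- (ico$vertices[f[, 1], 1] + ico$vertices[f[, 2], 1] +
           ico$vertices[f[, 3], 1]) / 3
  hemi <- beak_mesh(ico$vertices, f[cx > 0, , drop = FALSE],
                    landmarks = rbind(tip = c(1, 0, 0),
                                      base_top = c(0, 0, 1),
                                      base_bottom = c(0, 0, -1)))
  out <- trim_and_cap(hemi)
  expect_true(is_watertight(out))
  expect_gt(mesh_volume(out), 0)
})

test_that("a head collar beyond the base is trimmed off at the sphere", {
  m <- make_beak_mesh(list(length = 3, width = 1, depth = 1), resolution = 24)
  # stretch the cap region into a long collar sticking out the back
  collar <- m
  behind <- collar$vertices[, 1] < 0
  collar$vertices[behind, 1] <- collar$vertices[behind, 1] * 8
  trimmed <- trim_and_cap(collar)
  expect_true(is_watertight(trimmed))
  expect_lt(nrow(trimmed$faces), nrow(collar$faces) + 200)

  # oracle: Monte-Carlo volume of (collar mesh) intersect (enclosing sphere)
  sph <- beakmorph:::min_enclosing_sphere(bill_hull_points(collar))
  set.seed(99)
  lo <- apply(collar$vertices, 2, min); hi <- apply(collar$vertices, 2, max)
  P <- cbind(runif(15000, lo[1], hi[1]), runif(15000, lo[2], hi[2]),
             runif(15000, lo[3], hi[3]))
  inside_sph <- rowSums(sweep(P, 2, sph$center)^2) <= sph$r^2
  w <- abs(winding_number(collar, P[inside_sph, , drop = FALSE])) > 0.5
  vol_mc <- prod(hi - lo) * sum(w) / nrow(P)
  expect_lt(abs(mesh_volume(trimmed) - vol_mc) / vol_mc, 0.05)
})

test_that("trimming away almost everything is flagged as suspicious", {
  # a small landmarked bill dwarfed by a huge distant blob: the enclosing
  # sphere keeps only a sliver of the combined geometry
  small <- icosphere(1, radius = 1)
  blob <- icosphere(3, radius = 5, center = c(40, 0, 0))
  comb <- beak_mesh(rbind(small$vertices, blob$vertices),
                    rbind(small$faces, blob$faces + nrow(small$vertices)),
                    landmarks = rbind(tip = c(1, 0, 0),
                                      base_top = c(-0.7, 0, 0.7),
                                      base_bottom = c(-0.7, 0, -0.7)))
  expect_error(trim_and_cap(comb), "suspicious")
})

test_that("unit-sphere normalization is exact and invertible", {
  s <- icosphere(2, radius = 2, center = c(1, 0, 0))
  nz <- normalize_to_unit_sphere(s)
  expect_equal(nz$scale, 0.5, tolerance = 1e-12)
  expect_equal(nz$center, c(1, 0, 0), tolerance = 1e-12)
  expect_lte(sqrt(max(rowSums(nz$mesh$vertices^2))), 1 + 1e-9)
  back <- sweep(nz$mesh$vertices / nz$scale, 2, nz$center, "+")
  expect_lt(max(abs(back - s$vertices)), 1e-9)
  degen <- beak_mesh(matrix(0, 3, 3), matrix(c(1, 2, 3), 1))
  expect_error(normalize_to_unit_sphere(degen), "degenerate")
})

test_that("the full preprocessing pipeline is idempotent", {
  m <- make_beak_mesh(list(length = 4, width = 1.2, depth = 0.9,
                           curvature = 0.2, hook = 0.3), resolution = 24)
  rt <- random_rigid(3)
  p1 <- preprocess_mesh(apply_rigid_raw(m, rt$R, rt$t))
  expect_true(is_watertight(p1$mesh))
  p2 <- preprocess_mesh(p1$mesh)
  expect_lt(max(abs(p2$mesh$vertices - p1$mesh$vertices)), 1e-6)
})

test_that("mesh files round-trip through PLY, OBJ and STL", {
  m <- make_beak_mesh(list(length = 2, width = 1, depth = 1), resolution = 8)
  for (ext in c("ply", "obj", "stl")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_mesh(m, path)
    back <- read_mesh(path)
    expect_true(is_watertight(back))
    expect_equal(mesh_volume(back), mesh_volume(m), tolerance = 1e-6)
  }
})
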