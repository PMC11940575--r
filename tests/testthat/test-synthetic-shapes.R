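test_that("generated beak meshes are watertight with exact requested extents", {
  set.seed(7)
  for (i in 1:4) {
    p <- list(length = runif(1, 2, 6), width = runif(1, 0.5, 2),
              depth = runif(1, 0.5, 2), curvature = runif(1, -0.3, 0.5),
              hook = runif(1, 0, 0.9))
    m <- make_beak_mesh(p, resolution = 24)
    expect_true(is_watertight(m))
    ext <- apply(m$vertices, 2, function(v) diff(range(v)))
    expect_equal(ext, c(p$length, p$width, p$depth), tolerance = 1e-9)
    expect_gt(mesh_volume(m, signed = TRUE), 0)  # outward orientation
  }
})

test_that("symmetric parameters give a mesh mirror-symmetric about the x-z plane", {
  m <- make_beak_mesh(list(length = 3, width = 1.2, depth = 1.2,
                           curvature = 0, hook = 0), resolution = 16)
  v <- m$vertices
  refl <- v; refl[, 2] <- -refl[, 2]
  # every reflected vertex must coincide with some original vertex
  d2 <- outer(rowSums(refl^2), rowSums(v^2), "+") - 2 * tcrossprod(refl, v)
  expect_lt(max(apply(d2, 1, min)), 1e-12)
})

test_that("measured elongation matches the generating parameters", {
  m <- make_beak_mesh(list(length = 4, width = 1, depth = 1), resolution = 64)
  expect_equal(measure_beak(m)$elongation, 4, tolerance = 0.1 / 4)
})

test_that("mesh volume converges with resolution", {
  p <- list(length = 3, width = 1, depth = 0.8, curvature = 0.2, hook = 0.3)
  v64 <- mesh_volume(make_beak_mesh(p, resolution = 64))
  v128 <- mesh_volume(make_beak_mesh(p, resolution = 128))
  expect_lt(abs(v128 - v64) / v128, 0.01)
})

test_that("elongation increases strictly along a length ladder", {
  es <- vapply(seq(2, 6, length.out = 5), function(L)
    measure_beak(make_beak_mesh(list(length = L, width = 1, depth = 1),
                                resolution = 32))$elongation, numeric(1))
  expect_true(all(diff(es) > 0))
})

test_that("invalid shape parameters are rejected", {
  expect_error(make_beak_mesh(list(length = -1, width = 1, depth = 1)),
               "invalid parameter")
  expect_error(make_beak_mesh(list(length = 1, width = 0, depth = 1)),
               "invalid parameter")
  expect_error(make_beak_mesh(list(length = 1, width = 1, depth = 1),
                              resolution = 4), "resolution")
})

test_that("every generated mesh passes cleaning with zero repairs", {
  set.seed(11)
  for (i in 1:3) {
    m <- make_beak_mesh(list(length = runif(1, 2, 5), width = 1, depth = 1,
                             curvature = 0.1, hook = 0.4), resolution = 32)
    cl <- clean_mesh(m)
    expect_identical(nrow(cl$vertices), nrow(m$vertices))
    expect_identical(nrow(cl$faces), nrow(m$faces))
  }
})

test_that("class parameter tables honor counts, degeneracy and determinism", {
  # class sizes of the most and least abundant trophic niches in the
  # published table: 877 invertivores, 13 scavengers
  spec <- tibble::tibble(
    niche = c("A", "B"), n = c(877L, 13L),
    length_mean = c(3, 5), length_sd = c(0.4, 0.2),
    width_mean = c(1, 0.7), width_sd = c(0.1, 0))
  t1 <- sample_class_params(spec, seed = 3)
  expect_identical(nrow(t1), 890L)
  expect_identical(t1, sample_class_params(spec, seed = 3))
  # zero SD makes all class members identical
  expect_identical(length(unique(t1$width[t1$niche == "B"])), 1L)
  # empirical means within 3 SE of the specification
  mA <- mean(t1$length[t1$niche == "A"])
  expect_lt(abs(mA - 3), 3 * 0.4 / sqrt(877))
  expect_error(sample_class_params(spec, niche_levels = c("A")), "unknown class")
  bad <- spec; bad$length_sd[1] <- -1
  expect_error(sample_class_params(bad), "SD")
})

test_that("simulated clades have known Brownian structure", {
  rs <- c(length = 3, width = 1, curvature = 0)
  cl0 <- simulate_clade(8, 1, sigma = c(0, 0, 0), root_state = rs, seed = 5)
  expect_true(all(abs(cl0$tip_params$length - 3) < 1e-12))
  expect_true(all(abs(cl0$tip_params$curvature) < 1e-12))

  cl <- simulate_clade(12, 1, sigma = c(0.3, 0.3, 0.1), root_state = rs,
                       seed = 6)
  expect_identical(length(cl$tree$tip.label), 12L)
  depths <- ape::node.depth.edgelength(cl$tree)[seq_len(12)]
  expect_lt(diff(range(depths)), 1e-9)              # ultrametric
  expect_true(all(cl$tip_params$length > 0))        # log-scale positivity
  cl2 <- simulate_clade(12, 1, sigma = c(0.3, 0.3, 0.1), root_state = rs,
                        seed = 6)
  expect_identical(cl$tip_params, cl2$tip_params)   # bit-identical replay
  expect_error(simulate_clade(2, 1, sigma = 0.1, root_state = rs), "n_tips")
  expect_error(simulate_clade(8, 1, sigma = -1, root_state = rs), "sigma")
})

test_that("clade export writes newick and csv", {
  cl <- simulate_clade(6, 1, sigma = 0.2, root_state = c(length = 2), seed = 9)
  dir <- withr::local_tempdir()
  write_clade(cl, dir)
  tr <- ape::read.tree(file.path(dir, "tree.nwk"))
  expect_setequal(tr$tip.label, cl$tree$tip.label)
  tab <- utils::read.csv(file.path(dir, "tip_params.csv"))
  expect_identical(nrow(tab), 6L)
})
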