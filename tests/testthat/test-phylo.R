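test_that("the BM covariance encodes shared path lengths", {
  st <- ape::stree(8, "star"); st$edge.length <- rep(3, 8)
  C <- phylo_covariance(st)
  expect_lt(max(abs(unclass(C) - 3 * diag(8))), 1e-12)

  tr <- ape::read.tree(text = "((A:1,B:1):2,C:3);")
  C2 <- phylo_covariance(tr)
  expect_equal(C2["A", "B"], 2)
  expect_equal(C2["A", "A"], 3)
  expect_equal(C2["A", "C"], 0)

  # equivariance under tip permutation
  tr2 <- ape::rotate(tr, 4)
  C3 <- phylo_covariance(tr2)
  expect_equal(unclass(C3)[rownames(C2), colnames(C2)], unclass(C2),
               ignore_attr = TRUE)

  nobl <- tr; nobl$edge.length <- NULL
  expect_error(phylo_covariance(nobl), "branch lengths")
})

test_that("Blomberg's K matches independent oracles exactly", {
  set.seed(60)
  for (i in 1:5) {
    tr <- ape::rphylo(6, 1, 0)
    x <- setNames(rnorm(6), tr$tip.label)
    expect_equal(blomberg_K(x, tr), blomberg_K_direct(x, tr),
                 tolerance = 1e-10)
  }
  tr <- ape::rphylo(24, 1, 0)
  x <- setNames(cumsum(rnorm(24)) / 3 + rnorm(24), tr$tip.label)
  k_pkg <- blomberg_K(x, tr)
  k_phytools <- as.numeric(phytools::phylosig(tr, x, method = "K"))
  expect_equal(k_pkg, k_phytools, tolerance = 1e-8)

  # affine invariance is exact
  expect_equal(blomberg_K(5 - 2 * x, tr), k_pkg, tolerance = 1e-12)
  expect_error(blomberg_K(setNames(rep(1, 24), tr$tip.label), tr), "constant")
})

test_that("Kmult reduces to univariate K and ignores duplicated columns", {
  set.seed(61)
  tr <- ape::rphylo(16, 1, 0)
  x <- setNames(rnorm(16), tr$tip.label)
  X1 <- matrix(x, ncol = 1, dimnames = list(names(x), NULL))
  expect_equal(multivariate_K(X1, tr), blomberg_K(x, tr), tolerance = 1e-10)
  expect_equal(multivariate_K(cbind(X1, X1), tr), blomberg_K(x, tr),
               tolerance = 1e-10)
})

test_that("phylogenetic PCA reduces to ordinary PCA on a star tree", {
  set.seed(62)
  st <- ape::stree(16, "star"); st$edge.length <- rep(2, 16)
  X <- matrix(rnorm(16 * 4), 16, 4, dimnames = list(st$tip.label, NULL))
  pp <- phylo_pca(X, st)
  pr <- stats::prcomp(X)
  expect_lt(max(abs(abs(pp$scores) - abs(pr$x))), 1e-8)
  expect_true(all(pp$eigenvalues >= 0))
  # reconstruction identity at full rank
  rec <- pp$scores %*% t(pp$vectors) + rep(1, 16) %*% t(pp$mean)
  expect_lt(max(abs(rec - X)), 1e-8)
  # phytools cross-check of the evolutionary eigenvalues on a real tree
  tr <- ape::rphylo(20, 1, 0)
  X2 <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(tr$tip.label, NULL))
  pp2 <- phylo_pca(X2, tr)
  ph <- phytools::phyl.pca(tr, X2)
  expect_equal(pp2$eigenvalues, unname(diag(ph$Eval)), tolerance = 1e-6)
})

test_that("PACA aligns its first axis with planted phylogenetic structure", {
  set.seed(63)
  tr <- ape::rphylo(48, 1, 0)
  cl <- simulate_clade(48, 1, sigma = 2, root_state = c(bm = 0), seed = 63)
  b <- setNames(cl$tip_params$bm, cl$tip_params$species_id)
  X <- cbind(b[cl$tree$tip.label],
             matrix(rnorm(48 * 5, 0, 0.5), 48, 5))
  rownames(X) <- cl$tree$tip.label
  pc <- paca(X, cl$tree)
  expect_gt(abs(pc$components[1, 1]), 0.95)
  expect_lt(max(abs(crossprod(pc$components) - diag(6))), 1e-9)
})

test_that("statistics are invariant to consistent tip permutation", {
  set.seed(64)
  cl <- simulate_clade(20, 1, sigma = c(1, 1, 1),
                       root_state = c(a = 0, b = 0, c = 0), seed = 64)
  X <- as.matrix(cl$tip_params[, c("a", "b", "c")])
  rownames(X) <- cl$tip_params$species_id
  perm <- sample(nrow(X))
  expect_equal(multivariate_K(X[perm, ], cl$tree), multivariate_K(X, cl$tree),
               tolerance = 1e-12)
  expect_equal(blomberg_K(X[perm, 1], cl$tree), blomberg_K(X[, 1], cl$tree),
               tolerance = 1e-12)
})

test_that("signal profiles flag constant columns and preserve order", {
  set.seed(65)
  cl <- simulate_clade(16, 1, sigma = c(1, 1), root_state = c(a = 0, b = 0),
                       seed = 65)
  X <- as.matrix(cl$tip_params[, c("a", "b")])
  rownames(X) <- cl$tip_params$species_id
  X <- cbind(X, flat = 1)
  expect_warning(prof <- signal_profile(X, cl$tree), "constant")
  expect_identical(as.character(prof$axis), c("a", "b", "flat"))
  expect_true(is.na(prof$K[3]))
  expect_true(all(prof$K[1:2] > 0))
})

test_that("permuting tip labels destroys phylogenetic signal", {
  set.seed(66)
  cl <- simulate_clade(40, 1, sigma = 1.5, root_state = c(t = 0), seed = 66)
  x <- setNames(cl$tip_params$t, cl$tip_params$species_id)
  k_true <- blomberg_K(x, cl$tree)
  k_perm <- mean(replicate(20, {
    xp <- x; names(xp) <- sample(names(x))
    blomberg_K(xp, cl$tree)
  }))
  expect_gt(k_true, k_perm)
})

test_that("axis removal with drop 0 reproduces the baseline protocol", {
  set.seed(67)
  cl <- simulate_clade(45, 1, sigma = rep(1, 6),
                       root_state = setNames(rep(0, 6), paste0("t", 1:6)),
                       seed = 67)
  X <- as.matrix(cl$tip_params[, -1]); rownames(X) <- cl$tip_params$species_id
  labs <- clade_labels(cl$tree, 2)
  grid <- data.frame(trees = 200L, mtry = 2L, min_n = 2L)
  a0 <- axis_removal_experiment(X, cl$tree, labs, drop_axes = 0, grid = grid,
                                n_mc_splits = 4, seed = 68)
  # manual baseline: same split/tune/evaluate on the full PACA scores
  S <- paca(X, cl$tree)$scores
  sp <- stratified_split(labs[rownames(S)], 0.2, seed = 68)
  clf <- tune_and_fit(S[sp$train, ], labs[rownames(S)][sp$train], grid = grid,
                      n_mc_splits = 4, seed = 68)
  rep_ <- evaluate(clf, S[sp$test, ], labs[rownames(S)][sp$test])
  expect_identical(a0$report$confusion, rep_$confusion)
  expect_identical(a0$dropped, character(0))
  expect_identical(a1 <- axis_removal_experiment(
    X, cl$tree, labs, drop_axes = 1, grid = grid, n_mc_splits = 4,
    seed = 68)$dropped, "PaC1")
})

test_that("removing the lead axis hurts only phylogenetically confounded labels", {
  set.seed(69)
  cl <- simulate_clade(60, 1, sigma = rep(1, 8),
                       root_state = setNames(rep(0, 8), paste0("t", 1:8)),
                       seed = 52)
  X <- as.matrix(cl$tip_params[, -1]); rownames(X) <- cl$tip_params$species_id
  grid <- data.frame(trees = 300L, mtry = 3L, min_n = 2L)

  # labels = clades: classification rides on phylogenetic structure
  labs_p <- clade_labels(cl$tree, 3)
  b0 <- suppressWarnings(axis_removal_experiment(
    X, cl$tree, labs_p, drop_axes = 0, grid = grid, n_mc_splits = 5,
    seed = 60))
  b1 <- suppressWarnings(axis_removal_experiment(
    X, cl$tree, labs_p, drop_axes = 1, grid = grid, n_mc_splits = 5,
    seed = 60))
  expect_lt(b1$report$balanced_accuracy, b0$report$balanced_accuracy)

  # labels independent of phylogeny: removal changes little
  set.seed(61)
  labs_i <- setNames(factor(sample(c("a", "b", "c"), 60, TRUE)), rownames(X))
  d0 <- vapply(1:10, function(s) suppressWarnings(axis_removal_experiment(
    X, cl$tree, labs_i, drop_axes = 0, grid = grid, n_mc_splits = 5,
    seed = 60 + s))$report$balanced_accuracy, numeric(1))
  d1 <- vapply(1:10, function(s) suppressWarnings(axis_removal_experiment(
    X, cl$tree, labs_i, drop_axes = 1, grid = grid, n_mc_splits = 5,
    seed = 60 + s))$report$balanced_accuracy, numeric(1))
  expect_lt(abs(mean(d1) - mean(d0)), 0.05)
})
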