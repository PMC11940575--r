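#' Brownian-motion phylogenetic covariance
#'
#' The n x n matrix of shared root-to-MRCA path lengths implied by a
#' rooted tree with branch lengths; the trait covariance among tips under
#' Brownian motion.  Zero-length terminal branches are bumped by 1e-8
#' (with a warning) so the matrix stays positive definite for GLS.
#'
#' @param tree a rooted ape `phylo` with branch lengths.
#' @return a `phylo_cov`: the covariance matrix with tip labels as
#'   dimnames, `tip_order` attribute recording the order.
#' @export
phylo_covariance <- function(tree) {
  # a star phylogeny (single basal polytomy) counts as rooted here
  if (!ape::is.rooted(tree) && tree$Nnode > 1) stop("tree must be rooted")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be positive")
  term <- tree$edge[, 2] <= length(tree$tip.label)
  if (any(tree$edge.length[term] == 0)) {
    warning("zero-length terminal branches bumped by 1e-8")
    tree$edge.length[term & tree$edge.length == 0] <- 1e-8
  }
  C <- ape::vcv.phylo(tree)
  structure(C, class = c("phylo_cov", "matrix"), tip_order = rownames(C))
}

# align a trait matrix/vector to the covariance tip order
align_traits <- function(x, C) {
  X <- as.matrix(x)
  tips <- rownames(C)
  if (!is.null(rownames(X))) {
    if (!setequal(rownames(X), tips))
      stop("trait rows and tree tips do not match")
    X <- X[tips, , drop = FALSE]
  } else if (nrow(X) != nrow(C)) {
    stop("trait rows and tree tips do not match")
  }
  X
}

#' Blomberg's K phylogenetic signal statistic
#'
#' `K = (MSE0 / MSE) / E[MSE0 / MSE]`, where MSE0 is the mean squared
#' deviation of tip values from the phylogenetic (GLS) mean, MSE the
#' C-inverse-weighted counterpart, and the expectation
#' `(tr(C) - n / sum(C^-1)) / (n - 1)` its Brownian-motion value.  K is
#' about 1 under Brownian motion and below 1 when relatives resemble each
#' other less than BM predicts.
#'
#' @param x named per-tip numeric vector (names = tip labels).
#' @param tree rooted ape `phylo` (>= 4 tips), or a precomputed
#'   `phylo_cov`.
#' @return non-negative scalar K.
#' @export
blomberg_K <- function(x, tree) {
  C <- if (inherits(tree, "phylo_cov")) tree else phylo_covariance(tree)
  X <- align_traits(x, C)
  if (ncol(X) != 1) stop("`x` must be a single trait; see multivariate_K()")
  if (nrow(X) < 4) stop("need >= 4 tips")
  if (stats::sd(X) == 0) stop("K undefined for a constant trait")
  k_stat(X, C)
}

# shared K / Kmult kernel: trace form over p traits
k_stat <- function(X, C) {
  n <- nrow(C)
  Cinv <- solve(C)
  one <- rep(1, n)
  denom_a <- sum(Cinv)
  a <- crossprod(one, Cinv %*% X) / denom_a      # 1 x p GLS mean
  D <- X - one %*% a
  mse0 <- sum(D^2) / (n - 1)
  mse <- sum(D * (Cinv %*% D)) / (n - 1)
  expected <- (sum(diag(C)) - n / denom_a) / (n - 1)
  (mse0 / mse) / expected
}

#' Multivariate Blomberg's K
#'
#' Generalization of [blomberg_K()] to trait matrices using summed squared
#' deviations across traits (the distance-based Kmult of the geometric
#' morphometrics literature); reduces exactly to the univariate K when
#' `p = 1`.
#'
#' @param X n x p matrix of tip traits (rownames = tip labels).
#' @param tree rooted ape `phylo` or `phylo_cov`.
#' @return non-negative scalar.
#' @export
multivariate_K <- function(X, tree) {
  C <- if (inherits(tree, "phylo_cov")) tree else phylo_covariance(tree)
  X <- align_traits(X, C)
  if (nrow(X) < 4) stop("need >= 4 tips")
  if (all(apply(X, 2, stats::sd) == 0)) stop("K undefined for constant traits")
  k_stat(X, C)
}

#' Phylogenetic principal components analysis
#'
#' Eigen-decomposition of the GLS-estimated evolutionary covariance
#' `R = (X - 1 a)' C^-1 (X - 1 a) / (n - 1)` (a = phylogenetic mean);
#' scores are the GLS-centered data projected on the eigenvectors.  On a
#' star phylogeny this reduces to ordinary PCA.
#'
#' @param X n x p trait matrix (rownames = tip labels).
#' @param tree rooted ape `phylo` or `phylo_cov`.
#' @return list with `scores` (n x p), `vectors` (p x p), `eigenvalues`.
#' @export
phylo_pca <- function(X, tree) {
  C <- if (inherits(tree, "phylo_cov")) tree else phylo_covariance(tree)
  X <- align_traits(X, C)
  n <- nrow(X)
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("singular phylogenetic covariance"))
  one <- rep(1, n)
  a <- crossprod(one, Cinv %*% X) / sum(Cinv)
  Xc <- X - one %*% a
  R <- crossprod(Xc, Cinv %*% Xc) / (n - 1)
  eg <- eigen((R + t(R)) / 2, symmetric = TRUE)
  scores <- Xc %*% eg$vectors
  colnames(scores) <- paste0("pPC", seq_len(ncol(scores)))
  list(scores = scores, vectors = eg$vectors,
       eigenvalues = pmax(eg$values, 0), mean = as.numeric(a))
}

#' Phylogenetically aligned components analysis (PACA)
#'
#' Rotates the (centered) data so leading axes maximize covariation with
#' the phylogenetic structure implied by C: the rotation is the right
#' singular basis of `t(C_c) %*% X_c` (both column-centered), i.e. the
#' alignment of the data to the tree covariance rather than to maximum
#' variance.
#'
#' @param X n x p trait matrix (rownames = tip labels).
#' @param tree rooted ape `phylo` or `phylo_cov`.
#' @return list with `components` (p x p orthonormal columns), `scores`
#'   (n x p), `singular_values`.
#' @export
paca <- function(X, tree) {
  C <- if (inherits(tree, "phylo_cov")) tree else phylo_covariance(tree)
  X <- align_traits(X, C)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Ac <- scale(unclass(C), center = TRUE, scale = FALSE)
  sv <- svd(crossprod(Ac, Xc))
  comp <- sv$v
  scores <- Xc %*% comp
  colnames(scores) <- paste0("PaC", seq_len(ncol(scores)))
  list(components = comp, scores = scores, singular_values = sv$d)
}

#' Per-axis phylogenetic signal profile
#'
#' Blomberg's K applied column-wise to an axis table (latent dimensions,
#' PC scores, PACA scores ...), order preserved.
#'
#' @param X n x p matrix (rownames = tip labels).
#' @param tree rooted ape `phylo` or `phylo_cov`.
#' @return a `signal_profile` tibble with columns `axis`, `K`
#'   (NA for constant columns, with a warning).
#' @export
signal_profile <- function(X, tree) {
  C <- if (inherits(tree, "phylo_cov")) tree else phylo_covariance(tree)
  X <- align_traits(X, C)
  axes <- colnames(X)
  if (is.null(axes)) axes <- paste0("axis_", seq_len(ncol(X)))
  K <- vapply(seq_len(ncol(X)), function(j) {
    if (stats::sd(X[, j]) == 0) return(NA_real_)
    k_stat(X[, j, drop = FALSE], C)
  }, numeric(1))
  if (anyNA(K)) warning("constant columns flagged with K = NA")
  out <- tibble::tibble(axis = factor(axes, levels = axes), K = K)
  class(out) <- c("signal_profile", class(out))
  out
}

#' Niche classification after removing leading PACA axes
#'
#' Computes PACA scores, drops the first `drop_axes` columns (default 1,
#' the most phylogenetically aligned axis), then runs the full
#' tune/fit/evaluate classification protocol on the remainder.  With
#' `drop_axes = 0` this reproduces the baseline classification on the
#' full PACA rotation (an orthonormal rotation of the original space).
#'
#' @param X n x p trait matrix (rownames = tip labels).
#' @param tree rooted ape `phylo`.
#' @param labels class labels in tip order of `X`'s rownames.
#' @param drop_axes number of leading PACA axes to remove.
#' @param model,grid,n_mc_splits,seed passed to [tune_and_fit()].
#' @param test_prop held-out fraction for the final evaluation.
#' @return list with `report` (an `eval_report`), `classifier`,
#'   `dropped` (axis names removed).
#' @export
axis_removal_experiment <- function(X, tree, labels, drop_axes = 1L,
                                    model = "random_forest", grid = NULL,
                                    n_mc_splits = 20L, test_prop = 0.2,
                                    seed = 1L) {
  pc <- paca(X, tree)
  S <- pc$scores
  labels <- as.factor(labels)
  if (!is.null(names(labels))) labels <- labels[rownames(S)]
  dropped <- character()
  if (drop_axes > 0) {
    dropped <- colnames(S)[seq_len(drop_axes)]
    S <- S[, -seq_len(drop_axes), drop = FALSE]
  }
  sp <- stratified_split(labels, test_prop = test_prop, seed = seed)
  clf <- tune_and_fit(S[sp$train, , drop = FALSE], labels[sp$train],
                      model = model, grid = grid, n_mc_splits = n_mc_splits,
                      seed = seed)
  rep_ <- evaluate(clf, S[sp$test, , drop = FALSE], labels[sp$test])
  list(report = rep_, classifier = clf, dropped = dropped)
}
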