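#' Inverse-class-size case weights
#'
#' Assigns each observation in class j the weight `1 / n_j`, so every
#' class contributes equal total weight to model training regardless of
#' its sample size.
#'
#' @param labels factor or character vector of class labels.
#' @return tibble with columns `label` and `weight`; within each class all
#'   weights equal `1 / n_j` and sum to 1.
#' @export
assign_case_weights <- function(labels) {
  if (length(labels) == 0) stop("empty label vector")
  labels <- as.factor(labels)
  nj <- table(labels)
  tibble::tibble(label = labels, weight = as.numeric(1 / nj[as.character(labels)]))
}

#' Stratified train/test split
#'
#' Holds out `round(n_j * test_prop)` members of each class (at least one
#' when the class has two or more members), sampled without replacement.
#'
#' @param labels class labels.
#' @param test_prop held-out fraction in (0, 1); default 0.2.
#' @param seed integer seed.
#' @return list with integer vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(labels, test_prop = 0.2, seed = 1L) {
  if (test_prop <= 0 || test_prop >= 1) stop("`test_prop` must be in (0, 1)")
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(seed)
  labels <- as.factor(labels)
  test <- integer()
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    k <- round(length(idx) * test_prop)
    if (k == 0 && length(idx) >= 2) k <- 1L
    if (k >= length(idx)) k <- length(idx) - 1L
    if (k > 0) test <- c(test, sample(idx, k))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

#' Balanced accuracy and confusion matrix
#'
#' Balanced accuracy is the macro average over classes of
#' `(sensitivity_j + specificity_j) / 2` in one-vs-rest form.
#'
#' @param truth,predicted class label vectors of equal length.
#' @return an `eval_report`: list with `accuracy`, `balanced_accuracy`,
#'   `confusion` (rows = truth, columns = prediction), `per_class` tibble
#'   of sensitivities/specificities.
#' @export
evaluate_predictions <- function(truth, predicted) {
  if (length(truth) == 0) stop("empty test set")
  lv <- union(levels(as.factor(truth)), levels(as.factor(predicted)))
  truth <- factor(truth, levels = lv)
  predicted <- factor(predicted, levels = lv)
  cm <- table(truth = truth, predicted = predicted)
  total <- sum(cm)
  acc <- sum(diag(cm)) / total
  per <- purrr::map_dfr(lv, function(cl) {
    tp <- cm[cl, cl]
    fn <- sum(cm[cl, ]) - tp
    fp <- sum(cm[, cl]) - tp
    tn <- total - tp - fn - fp
    tibble::tibble(class = cl, n_truth = tp + fn,
                   sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                   specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  })
  present <- !is.na(per$sensitivity) & !is.na(per$specificity)
  if (any(!present))
    warning("classes absent from truth excluded from the macro average: ",
            paste(per$class[!present], collapse = ", "))
  bal <- mean((per$sensitivity[present] + per$specificity[present]) / 2)
  structure(list(accuracy = acc, balanced_accuracy = bal, confusion = cm,
                 per_class = per),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> accuracy ", round(x$accuracy, 3),
      ", balanced accuracy ", round(x$balanced_accuracy, 3), "\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.eval_report <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$confusion, responseName = "n"))
}

#' @exportS3Method generics::glance
glance.eval_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy,
                 balanced_accuracy = x$balanced_accuracy,
                 n = sum(x$confusion))
}

# fit one model family on (X, y, w) with fixed hyperparameters
fit_one <- function(X, y, w, model, hp, seed) {
  if (model == "random_forest") {
    ranger::ranger(x = X, y = y, case.weights = w,
                   num.trees = hp$trees %||% 300L,
                   mtry = min(hp$mtry %||% floor(sqrt(ncol(X))), ncol(X)),
                   min.node.size = hp$min_n %||% 5L,
                   seed = seed, num.threads = 1L,
                   respect.unordered.factors = TRUE)
  } else {
    glmnet::glmnet(as.matrix(X), y, family = "multinomial", weights = w,
                   alpha = hp$alpha %||% 0.5,
                   lambda = hp$lambda %||% 0.01)
  }
}

predict_labels <- function(fit, X, model) {
  if (model == "random_forest") {
    stats::predict(fit, data = X, num.threads = 1L)$predictions
  } else {
    drop(stats::predict(fit, as.matrix(X), type = "class"))
  }
}

#' Tune and fit a niche classifier by Monte-Carlo cross-validation
#'
#' Repeated stratified validation splits of the training data (default 20
#' splits, each holding out 20%); each hyperparameter point is scored by
#' its mean validation balanced accuracy and the winner is refit on all
#' training rows with the case weights.
#'
#' @param features data frame / matrix of predictors (rows = specimens).
#' @param labels class labels (same length); case weights `1/n_j` are
#'   derived internally via [assign_case_weights()].
#' @param model `"random_forest"` (ranger) or `"multinomial_elasticnet"`
#'   (glmnet); solver internals are delegated, this function owns
#'   weighting, splitting, the MC-CV protocol and selection.
#' @param grid data frame of hyperparameter points: `trees`, `mtry`,
#'   `min_n` for the forest; `alpha`, `lambda` for the elastic net.
#'   Defaults to a small standard grid.
#' @param n_mc_splits Monte-Carlo validation splits (default 20).
#' @param val_prop validation fraction per split (default 0.2).
#' @param seed integer seed.
#' @return a `niche_classifier`: list with `fit`, `model`, `best`
#'   (chosen hyperparameters), `cv` (per-point mean validation balanced
#'   accuracy), `levels`.
#' @export
tune_and_fit <- function(features, labels,
                         model = c("random_forest", "multinomial_elasticnet"),
                         grid = NULL, n_mc_splits = 20L, val_prop = 0.2,
                         seed = 1L) {
  model <- match.arg(model)
  features <- as.data.frame(features)
  labels <- droplevels(as.factor(labels))
  if (nrow(features) != length(labels)) stop("features/labels length mismatch")
  if (is.null(grid)) {
    grid <- if (model == "random_forest") {
      expand.grid(trees = c(200L, 500L),
                  mtry = unique(pmax(1L, floor(c(sqrt(ncol(features)),
                                                 ncol(features) / 3)))),
                  min_n = c(2L, 5L))
    } else {
      expand.grid(alpha = c(0.1, 0.5, 0.9), lambda = c(0.001, 0.01, 0.1))
    }
  }
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0) stop("empty hyperparameter grid")
  w <- assign_case_weights(labels)$weight

  splits <- lapply(seq_len(n_mc_splits), function(k)
    stratified_split(labels, test_prop = val_prop, seed = seed * 1000L + k))
  scores <- matrix(NA_real_, nrow(grid), n_mc_splits)
  for (gi in seq_len(nrow(grid))) {
    hp <- as.list(grid[gi, , drop = FALSE])
    for (k in seq_len(n_mc_splits)) {
      tr <- splits[[k]]$train; va <- splits[[k]]$test
      ytr <- droplevels(labels[tr])
      fit <- fit_one(features[tr, , drop = FALSE], ytr, w[tr], model, hp,
                     seed = seed + k)
      pred <- predict_labels(fit, features[va, , drop = FALSE], model)
      rep_ <- withCallingHandlers(
        evaluate_predictions(labels[va], pred),
        warning = function(wn) {
          message("MC-CV split ", k, ": ", conditionMessage(wn))
          invokeRestart("muffleWarning")
        })
      scores[gi, k] <- rep_$balanced_accuracy
    }
  }
  mean_scores <- rowMeans(scores)
  best_i <- which.max(mean_scores)
  best <- as.list(grid[best_i, , drop = FALSE])
  final <- fit_one(features, labels, w, model, best, seed = seed)
  structure(list(fit = final, model = model, best = best,
                 cv = dplyr::bind_cols(tibble::as_tibble(grid),
                                       tibble::tibble(mean_balanced_accuracy = mean_scores)),
                 levels = levels(labels)),
            class = "niche_classifier")
}

#' @export
print.niche_classifier <- function(x, ...) {
  cat("<niche_classifier> ", x$model, "; best: ",
      paste(names(x$best), unlist(x$best), sep = "=", collapse = ", "),
      " (CV balanced accuracy ",
      round(max(x$cv$mean_balanced_accuracy), 3), ")\n", sep = "")
  invisible(x)
}

#' Evaluate a fitted classifier on held-out data
#'
#' @param classifier a `niche_classifier`.
#' @param features_test held-out predictors.
#' @param labels_test held-out labels.
#' @return an `eval_report`.
#' @export
evaluate <- function(classifier, features_test, labels_test) {
  pred <- predict_labels(classifier$fit, as.data.frame(features_test),
                         classifier$model)
  evaluate_predictions(labels_test, pred)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a
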