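#' Classification metrics bundle
#'
#' Computes accuracy plus macro-averaged (unweighted per-class one-vs-rest)
#' precision, recall and F1, all expressed in percent, together with the
#' confusion matrix (rows = true class). A class never predicted gets
#' precision 0 (zero-division convention, warned); `average = "weighted"`
#' weights per-class scores by class prevalence instead.
#'
#' @param y_true,y_pred equal-length label vectors; predicted labels must
#'   belong to the known class set.
#' @param levels optional explicit class set; defaults to the levels of
#'   `y_true`.
#' @param average `"macro"` (default) or `"weighted"`.
#' @return a `metric_bundle`: list with `accuracy`, `precision`, `recall`,
#'   `f1` (percent) and `confusion`.
#' @export
evaluate_metrics <- function(y_true, y_pred, levels = NULL,
                             average = c("macro", "weighted")) {
  average <- match.arg(average)
  if (length(y_true) != length(y_pred) || length(y_true) < 1L) {
    rlang::abort("`y_true` and `y_pred` must have equal length >= 1.")
  }
  lv <- levels %||% levels(factor(y_true))
  if (!all(as.character(y_pred) %in% lv) ||
      !all(as.character(y_true) %in% lv)) {
    rlang::abort("labels outside the known class set.")
  }
  yt <- factor(as.character(y_true), levels = lv)
  yp <- factor(as.character(y_pred), levels = lv)
  cm <- table(true = yt, predicted = yp)
  tp <- diag(cm)
  pred_n <- colSums(cm)
  true_n <- rowSums(cm)
  if (any(pred_n == 0 & true_n > 0)) {
    rlang::warn("some classes were never predicted; their precision is set to 0.")
  }
  prec <- ifelse(pred_n > 0, tp / pred_n, 0)
  rec <- ifelse(true_n > 0, tp / true_n, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  w <- if (average == "macro") {
    rep(1 / length(lv), length(lv))
  } else {
    true_n / sum(true_n)
  }
  structure(list(
    accuracy = 100 * sum(tp) / sum(cm),
    precision = 100 * sum(w * prec),
    recall = 100 * sum(w * rec),
    f1 = 100 * sum(w * f1),
    confusion = cm
  ), class = "metric_bundle")
}

metric_row <- function(m) {
  tibble::tibble(accuracy = m$accuracy, precision = m$precision,
                 recall = m$recall, f1 = m$f1)
}

#' Add Gaussian perturbation noise to a feature matrix
#'
#' Adds independent `N(0, sigma^2)` noise to every entry, the perturbation
#' used to probe the robustness of the discriminant feature space.
#' `sigma = 0` returns the input bit-identically; deterministic given `seed`.
#'
#' @param x numeric matrix.
#' @param sigma noise standard deviation (default 0.01).
#' @param seed integer seed.
#' @return the perturbed matrix.
#' @export
add_gaussian_noise <- function(x, sigma = 0.01, seed = 1) {
  check_number(sigma, "sigma", lower = 0)
  if (sigma == 0) return(x)
  with_seed(seed, x + matrix(stats::rnorm(length(x), 0, sigma),
                             nrow = nrow(x)))
}

#' Classifier configuration
#'
#' Declares a classifier family and its hyperparameter grid. Defaults follow
#' small-sample tremor-classification practice: an RBF-kernel SVM with
#' `C` in \{0.1, 1\} and `gamma = 0.1`; k-NN with `k` in 5..10 and Euclidean
#' distance; a 100-tree random forest; or LDA used directly as classifier.
#' Grids with more than one candidate are resolved by inner grid search
#' during validation.
#'
#' @param kind one of `"svm_rbf"`, `"knn"`, `"random_forest"`, `"lda"`.
#' @param grid named list of hyperparameter candidates overriding the
#'   defaults.
#' @return a `classifier_spec` list.
#' @export
classifier_spec <- function(kind = c("svm_rbf", "knn", "random_forest", "lda"),
                            grid = NULL) {
  kind <- match.arg(kind)
  default <- switch(kind,
    svm_rbf = list(cost = c(0.1, 1), gamma = 0.1),
    knn = list(k = 5:10),
    random_forest = list(ntree = 100),
    lda = list()
  )
  grid <- utils::modifyList(default, grid %||% list())
  if (kind != "lda" && any(lengths(grid) == 0L)) {
    rlang::abort("hyperparameter grids must be nonempty.")
  }
  structure(list(kind = kind, grid = grid), class = "classifier_spec")
}

fit_classifier <- function(kind, x, y, pars, seed) {
  y <- factor(y)
  model <- switch(kind,
    svm_rbf = e1071::svm(x = x, y = y, kernel = "radial",
                         cost = pars$cost, gamma = pars$gamma,
                         scale = FALSE),
    knn = list(train = x, cl = y, k = pars$k),
    random_forest = with_seed(seed,
      randomForest::randomForest(x = x, y = y, ntree = pars$ntree)),
    lda = MASS::lda(x, grouping = y, tol = 1e-10)
  )
  list(kind = kind, model = model, levels = levels(y), seed = seed)
}

predict_classifier <- function(fit, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  out <- switch(fit$kind,
    svm_rbf = stats::predict(fit$model, x),
    # knn tie-breaks are randomized; a fixed local seed keeps them reproducible
    knn = with_seed(fit$seed + 7L,
      class::knn(train = fit$model$train, test = x, cl = fit$model$cl,
                 k = min(fit$model$k, nrow(fit$model$train)))),
    random_forest = stats::predict(fit$model, x),
    lda = stats::predict(fit$model, x)$class
  )
  factor(as.character(out), levels = fit$levels)
}

# expand a named list grid into a list of parameter combinations
grid_rows <- function(grid) {
  if (length(grid) == 0L) return(list(list()))
  df <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

# stratified fold assignment: within each class, shuffled round-robin
stratified_fold_ids <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in levels(factor(y))) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep(seq_len(k), length.out = length(idx))
    }
    fold
  })
}

plain_fold_ids <- function(n, k, seed) {
  with_seed(seed, {
    fold <- rep(seq_len(k), length.out = n)
    fold[sample.int(n)]
  })
}

# inner CV accuracy-based hyperparameter selection on training data only
grid_search <- function(spec, x, y, seed, inner_k = 3L) {
  combos <- grid_rows(spec$grid)
  if (length(combos) == 1L) return(combos[[1L]])
  k <- min(inner_k, min(table(y)))
  if (k < 2L) return(combos[[1L]])
  fold <- stratified_fold_ids(y, k, seed = seed + 13L)
  acc <- vapply(combos, function(pars) {
    correct <- 0L
    for (f in seq_len(k)) {
      tr <- fold != f
      fit <- fit_classifier(spec$kind, x[tr, , drop = FALSE], y[tr], pars,
                            seed = seed + f)
      pred <- predict_classifier(fit, x[!tr, , drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    correct / length(y)
  }, numeric(1))
  combos[[which.max(acc)]] # ties resolve to the first (deterministic) combo
}

validation_folds <- function(y, scheme, seed, holdout_frac) {
  n <- length(y)
  switch(scheme,
    loo = lapply(seq_len(n), identity),
    holdout = {
      fold <- stratified_fold_ids(y, max(2L, round(1 / holdout_frac)),
                                  seed = seed)
      list(which(fold == 1L))
    },
    kfold5 = {
      fold <- plain_fold_ids(n, 5L, seed = seed)
      lapply(1:5, function(f) which(fold == f))
    },
    stratified5 = ,
    noise = {
      fold <- stratified_fold_ids(y, 5L, seed = seed)
      lapply(1:5, function(f) which(fold == f))
    }
  )
}

#' Run a validation scheme over the PCA-LDA-classifier pipeline
#'
#' Evaluates the full stack under one of five schemes: leave-one-out
#' (`"loo"`), a stratified 80/20 hold-out (`"holdout"`), plain 5-fold
#' (`"kfold5"`), stratified 5-fold (`"stratified5"`), or stratified 5-fold
#' on Gaussian-perturbed discriminant features (`"noise"`).
#'
#' By default every fold refits PCA and LDA on its training portion only and
#' chooses hyperparameters by inner 3-fold grid search on training data, so
#' no statistic of any test subject can influence the fitted transforms
#' (no leakage). With `paper_mode = TRUE` the reduction is instead fitted
#' once on all data before splitting and only the classifier is
#' cross-validated; this optimistic protocol is provided for comparison and
#' inspection.
#'
#' Test metrics pool the predictions of all folds into one confusion matrix;
#' train metrics average the per-fold training scores. All randomness (fold
#' assignment, forests, tie-breaks, noise) derives from `seed`, so the same
#' configuration reproduces the identical report.
#'
#' @param fm a [as_feature_matrix()] result.
#' @param spec a [classifier_spec()].
#' @param scheme validation scheme, see above.
#' @param seed integer seed.
#' @param var_target,n_components reduction settings, see [fit_reduction()].
#' @param paper_mode fit the reduction on all data before splitting?
#' @param holdout_frac test fraction for the hold-out scheme.
#' @param noise_sigma perturbation sd for the `"noise"` scheme (default 0.01).
#' @return a `validation_report`: list with `scheme`, `classifier`,
#'   `metrics_test`, `metrics_train`, `confusion`, `failed_subject_ids`,
#'   `fold_scores`, `predictions`, `seed`, `config`.
#' @export
run_validation <- function(fm, spec = classifier_spec("svm_rbf"),
                           scheme = c("loo", "holdout", "kfold5",
                                      "stratified5", "noise"),
                           seed = 1, var_target = 0.95, n_components = 2,
                           paper_mode = FALSE, holdout_frac = 0.2,
                           noise_sigma = 0.01) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(fm, "feature_matrix"), inherits(spec, "classifier_spec"))
  y <- droplevels(fm$y)
  n <- length(y)
  counts <- table(y)
  if (scheme %in% c("stratified5", "noise", "kfold5") && min(counts) < 5L) {
    rlang::abort(sprintf(
      "scheme `%s` needs at least 5 members per class (smallest class has %d).",
      scheme, min(counts)))
  }
  folds <- validation_folds(y, scheme, seed = seed,
                            holdout_frac = holdout_frac)

  reduction_all <- NULL
  z_all <- NULL
  if (paper_mode) {
    reduction_all <- fit_reduction(fm$X, y, var_target = var_target,
                                   n_components = n_components)
    z_all <- predict(reduction_all)
    if (scheme == "noise") {
      z_all <- add_gaussian_noise(z_all, sigma = noise_sigma,
                                  seed = seed + 101L)
    }
  }

  pred <- factor(rep(NA_character_, n), levels = levels(y))
  fold_scores <- numeric(length(folds))
  train_rows <- vector("list", length(folds))

  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_len(n), test_idx)
    y_train <- y[train_idx]
    if (length(unique(y_train)) < length(levels(y))) {
      rlang::abort(sprintf("class absent from the training data of fold %d.", f))
    }
    if (paper_mode) {
      z_train <- z_all[train_idx, , drop = FALSE]
      z_test <- z_all[test_idx, , drop = FALSE]
    } else {
      red <- fit_reduction(fm$X[train_idx, , drop = FALSE], y_train,
                           var_target = var_target,
                           n_components = n_components)
      z_train <- predict(red)
      z_test <- predict(red, newdata = fm$X[test_idx, , drop = FALSE])
      if (scheme == "noise") {
        z_train <- add_gaussian_noise(z_train, sigma = noise_sigma,
                                      seed = seed + 200L + f)
        z_test <- add_gaussian_noise(z_test, sigma = noise_sigma,
                                     seed = seed + 400L + f)
      }
    }
    pars <- grid_search(spec, z_train, y_train, seed = seed + f)
    fit <- fit_classifier(spec$kind, z_train, y_train, pars, seed = seed + f)
    pred[test_idx] <- predict_classifier(fit, z_test)
    train_pred <- predict_classifier(fit, z_train)
    train_rows[[f]] <- metric_row(
      suppressWarnings(evaluate_metrics(y_train, train_pred,
                                        levels = levels(y))))
    fold_scores[f] <- 100 * mean(pred[test_idx] == y[test_idx])
  }

  tested <- !is.na(pred)
  metrics_test <- suppressWarnings(
    evaluate_metrics(y[tested], pred[tested], levels = levels(y)))
  metrics_train <- dplyr::summarise(dplyr::bind_rows(train_rows),
                                    dplyr::across(dplyr::everything(), mean))
  failed <- fm$subject_ids[!is.na(pred) & pred != y]
  structure(list(
    scheme = scheme,
    classifier = spec$kind,
    metrics_test = metrics_test,
    metrics_train = metrics_train,
    confusion = metrics_test$confusion,
    failed_subject_ids = failed,
    fold_scores = fold_scores,
    predictions = tibble::tibble(subject_id = fm$subject_ids,
                                 truth = as.character(y),
                                 prediction = as.character(pred)),
    seed = seed,
    config = list(var_target = var_target, n_components = n_components,
                  paper_mode = paper_mode, holdout_frac = holdout_frac,
                  noise_sigma = noise_sigma, grid = spec$grid,
                  feature_kind = fm$kind)
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s / %s (seed %d)\n",
              x$classifier, x$scheme, x$seed))
  cat(sprintf("  test:  acc %.2f%%  prec %.2f%%  rec %.2f%%  F1 %.2f%%\n",
              x$metrics_test$accuracy, x$metrics_test$precision,
              x$metrics_test$recall, x$metrics_test$f1))
  cat(sprintf("  train: acc %.2f%%  prec %.2f%%  rec %.2f%%  F1 %.2f%%\n",
              x$metrics_train$accuracy, x$metrics_train$precision,
              x$metrics_train$recall, x$metrics_train$f1))
  if (length(x$failed_subject_ids) > 0L) {
    cat("  misclassified:", paste(x$failed_subject_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method tidy validation_report
#' @export
tidy.validation_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(metric_row(x$metrics_test), split = "test"),
    dplyr::mutate(x$metrics_train, split = "train")
  ) |>
    dplyr::relocate("split")
}

#' @method glance validation_report
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(
    scheme = x$scheme, classifier = x$classifier,
    test_accuracy = x$metrics_test$accuracy,
    train_accuracy = x$metrics_train$accuracy,
    n = nrow(x$predictions),
    n_failed = length(x$failed_subject_ids),
    seed = x$seed
  )
}
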