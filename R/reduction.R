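#' Build a feature matrix for classification
#'
#' Stacks a feature-series table into the subjects-by-L numeric matrix the
#' classification pipeline consumes, together with the response labels:
#' either the three-level severity code (0 control / 1 low / 2 high) or the
#' binary control/ET contrast.
#'
#' @param features a [feature_series()] table with metadata columns (from
#'   [extract_features()]).
#' @param response `"tremor_level"` (default, 3-class severity) or `"group"`
#'   (binary).
#' @return a `feature_matrix`: list with `X` (n x L matrix), `y` (factor),
#'   `subject_ids`, `kind`.
#' @export
as_feature_matrix <- function(features,
                              response = c("tremor_level", "group")) {
  response <- match.arg(response)
  stopifnot(inherits(features, "feature_series"))
  if (is.null(features[[response]])) {
    rlang::abort(sprintf("`features` must carry a `%s` column.", response))
  }
  x <- do.call(rbind, features$values)
  rownames(x) <- features$subject_id
  if (!all(is.finite(x))) rlang::abort("feature matrix has missing values.")
  y <- factor(features[[response]])
  structure(list(X = x, y = y, subject_ids = features$subject_id,
                 kind = features$kind[1L]),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d subjects x %d features (%s), classes: %s\n",
              nrow(x$X), ncol(x$X), x$kind,
              paste(sprintf("%s=%d", levels(x$y), table(x$y)),
                    collapse = ", ")))
  invisible(x)
}

#' Fit a variance-targeted PCA
#'
#' Mean-centers the columns and keeps the smallest number of principal
#' components whose cumulative explained-variance ratio reaches
#' `var_target`. By construction the reconstruction error from the retained
#' components is at most `1 - var_target` of the total variance.
#'
#' @param x numeric matrix, subjects in rows (>= 2).
#' @param var_target cumulative explained-variance target in (0, 1\].
#' @return a `spiral_pca`: list with the [stats::prcomp()] fit, `n_pca`,
#'   `explained_variance` (per-component ratios) and `var_target`.
#' @export
fit_pca <- function(x, var_target = 0.95) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) < 2L) rlang::abort("PCA requires at least 2 rows.")
  if (!is.numeric(var_target) || length(var_target) != 1L ||
      var_target <= 0 || var_target > 1) {
    rlang::abort("`var_target` must lie in (0, 1].")
  }
  pca <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  var <- pca$sdev^2
  total <- sum(var)
  if (total < .Machine$double.eps) {
    rlang::abort("feature matrix has zero variance.")
  }
  evr <- var / total
  cum <- cumsum(evr)
  n_pca <- which(cum >= var_target - 1e-9)[1L]
  structure(list(pca = pca, n_pca = n_pca, explained_variance = evr,
                 var_target = var_target),
            class = "spiral_pca")
}

pca_scores <- function(model, newdata = NULL) {
  sc <- if (is.null(newdata)) {
    model$pca$x
  } else {
    stats::predict(model$pca, newdata = newdata)
  }
  sc[, seq_len(model$n_pca), drop = FALSE]
}

#' Fit a linear discriminant projection
#'
#' Finds the discriminant axes maximizing between-class over within-class
#' scatter via [MASS::lda()]. At most `n_classes - 1` axes exist; requests
#' beyond that bound are reduced with a warning, so a 3-class problem yields
#' exactly 2 axes. If the within-class scatter is singular, a
#' ridge-regularized fallback (small multiple of the identity added to the
#' pooled covariance) is used and reported.
#'
#' @param x numeric matrix of reduced features (subjects in rows).
#' @param y class labels; every class needs >= 2 members.
#' @param n_components requested number of discriminant axes.
#' @return a `spiral_lda`: list with `scaling` (projection matrix), `xbar`
#'   (centering vector), `classes`, `n_components`, `lda` (the MASS fit or
#'   `NULL` when the fallback was used).
#' @export
fit_lda <- function(x, y, n_components = 2) {
  if (!is.matrix(x)) x <- as.matrix(x)
  y <- factor(y)
  y <- droplevels(y)
  counts <- table(y)
  if (length(counts) < 2L) rlang::abort("LDA requires at least 2 classes.")
  if (any(counts < 2L)) {
    rlang::abort(paste0("every class needs at least 2 members; too small: ",
                        paste(names(counts)[counts < 2L], collapse = ", ")))
  }
  max_axes <- min(length(counts) - 1L, ncol(x))
  if (n_components > max_axes) {
    rlang::warn(sprintf(
      "reducing `n_components` from %d to %d (at most n_classes - 1 axes exist).",
      n_components, max_axes))
    n_components <- max_axes
  }
  fit <- tryCatch(MASS::lda(x, grouping = y, tol = 1e-8),
                  error = function(e) NULL)
  xbar <- colMeans(x)
  if (!is.null(fit)) {
    scaling <- fit$scaling[, seq_len(n_components), drop = FALSE]
  } else {
    rlang::inform("within-class scatter singular; using ridge-regularized LDA.")
    scaling <- ridge_lda_scaling(x, y, n_components)
    fit <- NULL
  }
  structure(list(scaling = scaling, xbar = xbar, classes = levels(y),
                 n_components = n_components, lda = fit),
            class = "spiral_lda")
}

# eigen-solution of (Sw + ridge I)^{-1} Sb, used when MASS::lda cannot invert
ridge_lda_scaling <- function(x, y, n_components) {
  p <- ncol(x)
  xbar <- colMeans(x)
  sw <- matrix(0, p, p)
  sb <- matrix(0, p, p)
  for (cl in levels(y)) {
    xi <- x[y == cl, , drop = FALSE]
    mi <- colMeans(xi)
    ci <- sweep(xi, 2L, mi)
    sw <- sw + crossprod(ci)
    d <- mi - xbar
    sb <- sb + nrow(xi) * tcrossprod(d)
  }
  lambda <- 1e-6 * mean(diag(sw)) + 1e-12
  e <- eigen(solve(sw + lambda * diag(p)) %*% sb)
  scaling <- Re(e$vectors[, seq_len(n_components), drop = FALSE])
  colnames(scaling) <- paste0("LD", seq_len(n_components))
  rownames(scaling) <- colnames(x)
  scaling
}

lda_project <- function(model, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  z <- sweep(x, 2L, model$xbar) %*% model$scaling
  colnames(z) <- paste0("LD", seq_len(ncol(z)))
  z
}

#' Fit the PCA-LDA reduction stack
#'
#' Chains [fit_pca()] (variance-targeted, default 95%) and [fit_lda()]
#' (default 2 discriminant axes) on a feature matrix, producing the
#' low-dimensional representation on which the classifiers operate.
#'
#' @param fm a [as_feature_matrix()] result, or a plain matrix with `y`.
#' @param y class labels when `fm` is a matrix.
#' @param var_target PCA cumulative explained-variance target.
#' @param n_components number of discriminant axes.
#' @return a `spiral_reduction`: list with `pca` (`spiral_pca`), `lda`
#'   (`spiral_lda`) and `class_means` (per-class centroids in LDA space).
#' @export
fit_reduction <- function(fm, y = NULL, var_target = 0.95, n_components = 2) {
  if (inherits(fm, "feature_matrix")) {
    x <- fm$X
    y <- fm$y
  } else {
    x <- as.matrix(fm)
    if (is.null(y)) rlang::abort("`y` is required when `fm` is a matrix.")
  }
  pca <- fit_pca(x, var_target = var_target)
  scores <- pca_scores(pca)
  lda <- fit_lda(scores, y, n_components = n_components)
  z <- lda_project(lda, scores)
  centers <- rowsum(z, group = factor(y)) / as.vector(table(factor(y)))
  structure(list(pca = pca, lda = lda, class_means = centers),
            class = "spiral_reduction")
}

#' Project data through a fitted reduction
#'
#' @param object a `spiral_reduction`.
#' @param newdata matrix in the original feature space; omit to return the
#'   training projection.
#' @param ... unused.
#' @return matrix of LDA-space coordinates.
#' @export
predict.spiral_reduction <- function(object, newdata = NULL, ...) {
  scores <- pca_scores(object$pca, newdata = newdata)
  lda_project(object$lda, scores)
}

#' Feature contributions to the discriminant axes
#'
#' Maps the discriminant loadings back through the PCA rotation to the
#' original feature indices and reports the absolute contribution of every
#' input feature to each discriminant axis, sorted per axis. A feature that
#' is identical across subjects has zero contribution on every axis.
#'
#' @param model a `spiral_reduction` from [fit_reduction()].
#' @return a tibble with columns `axis`, `feature`, `magnitude`, sorted by
#'   decreasing magnitude within axis.
#' @export
lda_contributions <- function(model) {
  if (!inherits(model, "spiral_reduction")) {
    rlang::abort("`model` must be a fitted `spiral_reduction`.")
  }
  rot <- model$pca$pca$rotation[, seq_len(model$pca$n_pca), drop = FALSE]
  w <- rot %*% model$lda$scaling # original features x axes
  tibble::tibble(
    axis = rep(colnames(model$lda$scaling) %||%
                 paste0("LD", seq_len(ncol(w))), each = nrow(w)),
    feature = rep(seq_len(nrow(w)), times = ncol(w)),
    magnitude = abs(as.vector(w))
  ) |>
    dplyr::group_by(.data$axis) |>
    dplyr::arrange(dplyr::desc(.data$magnitude), .by_group = TRUE) |>
    dplyr::ungroup()
}

#' @method tidy spiral_reduction
#' @export
tidy.spiral_reduction <- function(x, ...) {
  evr <- x$pca$explained_variance
  tibble::tibble(
    component = seq_along(evr),
    explained_variance = evr,
    cumulative = cumsum(evr),
    retained = seq_along(evr) <= x$pca$n_pca
  )
}

#' @method glance spiral_reduction
#' @export
glance.spiral_reduction <- function(x, ...) {
  tibble::tibble(
    n_pca = x$pca$n_pca,
    cumulative_variance = sum(x$pca$explained_variance[seq_len(x$pca$n_pca)]),
    n_lda_axes = x$lda$n_components,
    n_classes = length(x$lda$classes)
  )
}
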