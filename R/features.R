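#' Orthonormal discrete cosine transform (DCT-II) and its inverse
#'
#' `dct_type2()` computes the orthonormal DCT-II
#' \deqn{c_k = w_k \sum_{n=0}^{N-1} x_n \cos\!\big(\pi k (2n+1)/(2N)\big),}
#' with \eqn{w_0 = \sqrt{1/N}} and \eqn{w_k = \sqrt{2/N}} otherwise, via a
#' zero-padded FFT; `idct_type2()` is its exact inverse (DCT-III). With the
#' orthonormal scaling the transform preserves energy (Parseval) and the
#' round trip reproduces the input to machine precision.
#'
#' @param x numeric vector (length >= 1).
#' @param coef orthonormal DCT-II coefficients.
#' @return numeric vector of coefficients (or the reconstructed signal).
#' @export
dct_type2 <- function(x) {
  if (length(x) == 0L) rlang::abort("empty input to `dct_type2`.")
  if (!all(is.finite(x))) rlang::abort("`x` must be finite.")
  n <- length(x)
  if (n == 1L) return(as.double(x))
  padded <- stats::fft(c(x, rep(0, n)))
  k <- 0:(n - 1L)
  raw <- Re(exp(-1i * pi * k / (2 * n)) * padded[seq_len(n)])
  w <- c(sqrt(1 / n), rep(sqrt(2 / n), n - 1L))
  w * raw
}

#' @rdname dct_type2
#' @export
idct_type2 <- function(coef) {
  if (length(coef) == 0L) rlang::abort("empty input to `idct_type2`.")
  n <- length(coef)
  if (n == 1L) return(as.double(coef))
  w <- c(sqrt(1 / n), rep(sqrt(2 / n), n - 1L))
  k <- 0:(n - 1L)
  b <- w * coef * exp(1i * pi * k / (2 * n))
  v <- stats::fft(c(b, rep(0, n)), inverse = TRUE)
  Re(v[seq_len(n)])
}

#' DCT-residue series of a trajectory
#'
#' Reconstructs each coordinate series from its first `k_keep` DCT
#' coefficients (the slow spiral ramp) and takes the remainder, which carries
#' the localized high-frequency content where tremor lives. The x and y
#' residuals are combined pointwise as the rotation-insensitive magnitude
#' \eqn{\sqrt{res_x^2 + res_y^2}} (default) or concatenated.
#'
#' @param x,y equal-length coordinate series.
#' @param k_keep number of leading DCT coefficients defining the
#'   low-frequency reconstruction, `1 <= k_keep < length(x)`. The default 32
#'   keeps content below roughly `32 / (2 * T)` Hz for a drawing of `T`
#'   seconds, leaving the 4--12 Hz band in the residue.
#' @param combine `"magnitude"` (pointwise, length L) or `"concat"`
#'   (length 2L).
#' @return numeric residue vector.
#' @export
dct_residue <- function(x, y, k_keep = 32, combine = c("magnitude", "concat")) {
  combine <- match.arg(combine)
  if (length(x) != length(y)) {
    rlang::abort("`x` and `y` must have equal length.")
  }
  l <- length(x)
  if (!is.numeric(k_keep) || length(k_keep) != 1L || k_keep < 1L ||
      k_keep >= l || k_keep != round(k_keep)) {
    rlang::abort(sprintf("`k_keep` must be an integer in [1, %d).", l))
  }
  residual <- function(v) {
    cf <- dct_type2(v)
    cf[(k_keep + 1L):l] <- 0
    v - idct_type2(cf)
  }
  rx <- residual(x)
  ry <- residual(y)
  if (combine == "magnitude") sqrt(rx^2 + ry^2) else c(rx, ry)
}

#' Pearson correlation matrix of a feature-series group
#'
#' Quantifies the drawing-to-drawing consistency of one group. In
#' `"inter_subject"` mode the matrix is subjects x subjects: each entry is
#' the Pearson correlation of two subjects' curves over time points, so a
#' high off-diagonal mean means the group draws consistently similar spirals.
#' In `"inter_temporal"` mode the matrix correlates time points over
#' subjects, computed on a `grid`-point downsampled time axis. Off-diagonal
#' summary statistics (mean, sd, min) exclude the unit diagonal and use each
#' unordered pair once.
#'
#' @param series a [feature_series()] table (>= 2 rows, equal lengths, each
#'   series non-constant).
#' @param mode correlation axis, see above.
#' @param group optional group label stored on the result.
#' @param grid time-axis size for `"inter_temporal"` mode.
#' @return a `correlation_summary`: list with elements `group`, `mode`,
#'   `matrix`, `offdiag_mean`, `offdiag_sd`, `offdiag_min`, `n`.
#' @export
group_correlation_matrix <- function(series,
                                     mode = c("inter_subject",
                                              "inter_temporal"),
                                     group = NULL, grid = 64) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "feature_series"))
  if (nrow(series) < 2L) {
    rlang::abort("at least 2 series are required for a correlation matrix.")
  }
  sds <- vapply(series$values, stats::sd, numeric(1))
  if (any(sds < .Machine$double.eps)) {
    bad <- series$subject_id[sds < .Machine$double.eps]
    rlang::abort(paste0("correlation undefined for constant series: ",
                        paste(bad, collapse = ", ")))
  }
  m <- do.call(rbind, series$values)
  rownames(m) <- series$subject_id
  if (mode == "inter_subject") {
    cm <- stats::cor(t(m))
  } else {
    idx <- unique(round(seq(1L, ncol(m), length.out = min(grid, ncol(m)))))
    sub <- m[, idx, drop = FALSE]
    keep <- apply(sub, 2L, stats::sd) > .Machine$double.eps
    if (sum(keep) < 2L) {
      rlang::abort("too few non-constant time points for inter-temporal mode.")
    }
    cm <- stats::cor(sub[, keep, drop = FALSE])
  }
  cm <- (cm + t(cm)) / 2
  diag(cm) <- 1
  cm <- pmin(pmax(cm, -1), 1)
  off <- cm[upper.tri(cm)]
  structure(list(
    group = group, mode = mode, matrix = cm,
    offdiag_mean = mean(off), offdiag_sd = stats::sd(off),
    offdiag_min = min(off), n = nrow(cm)
  ), class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat(sprintf(
    "<correlation_summary> %s, %s: %d x %d, offdiag mean %.3f (sd %.3f, min %.3f)\n",
    x$group %||% "ungrouped", x$mode, x$n, x$n,
    x$offdiag_mean, x$offdiag_sd, x$offdiag_min))
  invisible(x)
}

offdiag_values <- function(summary) summary$matrix[upper.tri(summary$matrix)]

#' Group correlation consistency analysis
#'
#' Computes the per-group correlation summaries for the control and ET
#' subjects of a feature table, then compares the pooled off-diagonal
#' correlation values between groups with a two-sided Mann-Whitney U test.
#' Tremor disrupts movement consistency, so the expected direction of effect
#' is a higher off-diagonal mean in the control group.
#'
#' @param features a [feature_series()] table carrying a `group` column
#'   (as produced by [extract_features()]).
#' @param mode,grid passed to [group_correlation_matrix()].
#' @return a `consistency_report`: list with `control` and `et` correlation
#'   summaries and `test`, the [mann_whitney_u()] result.
#' @export
correlation_consistency <- function(features, mode = "inter_subject",
                                    grid = 64) {
  stopifnot(inherits(features, "feature_series"))
  if (is.null(features$group)) {
    rlang::abort("`features` must carry a `group` column.")
  }
  ctrl <- group_correlation_matrix(
    features[features$group == "control", , drop = FALSE],
    mode = mode, group = "control", grid = grid)
  et <- group_correlation_matrix(
    features[features$group == "ET", , drop = FALSE],
    mode = mode, group = "ET", grid = grid)
  test <- mann_whitney_u(offdiag_values(ctrl), offdiag_values(et))
  structure(list(control = ctrl, et = et, test = test),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat("<consistency_report>\n")
  print(x$control)
  print(x$et)
  cat(sprintf("  Mann-Whitney U = %.1f, p = %.3g (%s)\n",
              x$test$u_statistic, x$test$p_value, x$test$method))
  invisible(x)
}

#' Off-diagonal correlation distribution report
#'
#' Summarizes and visualizes the off-diagonal correlation distributions of
#' two group summaries: a per-group table of mean, sd, median and IQR, plus a
#' histogram and a boxplot contrasting the groups.
#'
#' @param ctrl,et `correlation_summary` objects of the same mode.
#' @return an `offdiag_report`: list with `table` (tibble), `histogram` and
#'   `boxplot` (ggplot objects).
#' @export
offdiag_distributions <- function(ctrl, et) {
  stopifnot(inherits(ctrl, "correlation_summary"),
            inherits(et, "correlation_summary"))
  if (ctrl$mode != et$mode) {
    rlang::abort("correlation summaries have different modes.")
  }
  df <- dplyr::bind_rows(
    tibble::tibble(group = ctrl$group %||% "control",
                   correlation = offdiag_values(ctrl)),
    tibble::tibble(group = et$group %||% "ET",
                   correlation = offdiag_values(et))
  )
  tab <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      mean = mean(.data$correlation),
      sd = stats::sd(.data$correlation),
      median = stats::median(.data$correlation),
      iqr = stats::IQR(.data$correlation),
      n_pairs = dplyr::n(),
      .groups = "drop"
    )
  hist <- ggplot2::ggplot(df, ggplot2::aes(x = .data$correlation,
                                           fill = .data$group)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 30) +
    ggplot2::labs(x = "pairwise correlation", y = "count",
                  title = "Off-diagonal correlation distribution") +
    ggplot2::theme_minimal()
  box <- ggplot2::ggplot(df, ggplot2::aes(x = .data$group,
                                          y = .data$correlation,
                                          fill = .data$group)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "pairwise correlation",
                  title = "Off-diagonal correlations by group") +
    ggplot2::theme_minimal()
  structure(list(table = tab, histogram = hist, boxplot = box),
            class = "offdiag_report")
}

#' @export
print.offdiag_report <- function(x, ...) {
  cat("<offdiag_report>\n")
  print(x$table)
  invisible(x)
}
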