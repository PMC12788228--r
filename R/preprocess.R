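#' Construct a feature-series table
#'
#' A feature series is one per-subject curve of fixed length: either the
#' spiral radius \eqn{r_n = \sqrt{x_n^2 + y_n^2}} or the DCT-residue
#' magnitude. Collections are tibbles with one row per subject and the curve
#' in a `values` list-column, so they stack directly into the subjects-by-L
#' matrix consumed by the classification pipeline.
#'
#' @param subject_id character vector of subject ids.
#' @param kind `"radius"` or `"dct_residue"`.
#' @param values list of equal-length numeric vectors.
#' @param smoothed,normalized logical flags recording applied transforms.
#' @return a `feature_series` tibble.
#' @export
feature_series <- function(subject_id, kind = c("radius", "dct_residue"),
                           values, smoothed = FALSE, normalized = FALSE) {
  kind <- match.arg(kind)
  if (!is.list(values)) values <- list(values)
  lens <- lengths(values)
  if (length(unique(lens)) != 1L) {
    rlang::abort("all feature series must have the same length.")
  }
  if (!all(vapply(values, function(v) all(is.finite(v)), logical(1)))) {
    rlang::abort("feature series values must be finite.")
  }
  out <- tibble::tibble(
    subject_id = as.character(subject_id),
    kind = kind,
    smoothed = smoothed,
    normalized = normalized,
    values = values
  )
  class(out) <- c("feature_series", class(tibble::tibble()))
  out
}

series_length <- function(series) length(series$values[[1L]])

#' Drop pen-up samples from a drawing
#'
#' Retains only samples with `pen_state == 1`, concatenated in time order.
#' The fraction of samples removed is attached as the `fraction_removed`
#' attribute for logging.
#'
#' @param record a [spiral_record()].
#' @return a [spiral_record()] of the pen-down samples.
#' @export
filter_pen_down <- function(record) {
  validate_spiral_record(record)
  keep <- record$pen_state == 1
  if (!any(keep)) {
    rlang::abort(sprintf("drawing %s has no pen-down samples.",
                         subject_id(record)))
  }
  frac <- 1 - mean(keep)
  if (all(keep)) {
    out <- record
  } else {
    kept <- tibble::as_tibble(record)[keep, , drop = FALSE]
    out <- new_spiral_record(kept, subject_id = subject_id(record),
                            hand = record_hand(record),
                            sampling_rate = sampling_rate(record))
    validate_spiral_record(out)
  }
  attr(out, "fraction_removed") <- frac
  out
}

#' Resample a drawing to a fixed number of points
#'
#' Linearly interpolates every channel onto `n` points uniformly spaced in
#' normalized cumulative time, so drawings of different durations and sample
#' counts become comparable. The first and last samples are preserved
#' exactly; the binary pen-state channel is re-thresholded at 0.5 after
#' interpolation. The default length of 4096 points is the canonical series
#' length used throughout the pipeline.
#'
#' @param record a [spiral_record()].
#' @param n target number of samples (>= 2).
#' @return a [spiral_record()] of length `n`.
#' @export
resample_fixed <- function(record, n = 4096) {
  validate_spiral_record(record)
  if (!is.numeric(n) || length(n) != 1L || n < 2L || n != round(n)) {
    rlang::abort("`n` must be an integer >= 2.")
  }
  n <- as.integer(n)
  m <- nrow(record)
  span <- record$t[m] - record$t[1L]
  u <- if (span > 0) (record$t - record$t[1L]) / span else
    seq(0, 1, length.out = m)
  target <- seq(0, 1, length.out = n)
  interp <- function(v) {
    stats::approx(u, v, xout = target, ties = "ordered", rule = 2)$y
  }
  pen <- as.double(interp(record$pen_state) >= 0.5)
  new_rate <- if (span > 0) (n - 1L) / span else sampling_rate(record)
  rec <- spiral_record(
    x = interp(record$x), y = interp(record$y),
    t = record$t[1L] + target * max(span, 0),
    pen_state = pen,
    azimuth = interp(record$azimuth), altitude = interp(record$altitude),
    pressure = interp(record$pressure),
    subject_id = subject_id(record), hand = record_hand(record),
    sampling_rate = new_rate
  )
  rec
}

#' Radius series of a drawing
#'
#' Collapses the two-dimensional trajectory into the polar radius
#' \eqn{r_n = \sqrt{x_n^2 + y_n^2}} per sample, the compact global-shape
#' feature in which tremor appears as oscillation around the ideal ramp
#' \eqn{a + b\theta}.
#'
#' @param record a [spiral_record()].
#' @return a one-row [feature_series()] of kind `"radius"`.
#' @export
to_radius <- function(record) {
  validate_spiral_record(record)
  feature_series(subject_id(record), kind = "radius",
                 values = list(sqrt(record$x^2 + record$y^2)))
}

# centered rolling mean with shrinking windows at the edges (no padding)
rolling_mean <- function(v, w) {
  l <- length(v)
  idx <- seq_len(l)
  lo <- pmax(1L, idx - (w - 1L) %/% 2L)
  hi <- pmin(l, idx + w %/% 2L)
  s <- c(0, cumsum(v))
  (s[hi + 1L] - s[lo]) / (hi - lo + 1L)
}

#' Smooth feature series with a rolling mean
#'
#' Applies a centered moving average of window `w = round(l / denom)`, where
#' `l` is the series length. At the edges the window shrinks symmetrically
#' instead of padding, so no boundary values are invented and the output
#' length equals the input length. The default `denom = 256` gives a
#' 16-sample window at `l = 4096`, which suppresses sample-level jitter while
#' passing most of the 4--12 Hz tremor band of a roughly 20 s drawing.
#'
#' @param series a [feature_series()] table.
#' @param denom window divisor (>= 1).
#' @return the smoothed [feature_series()] with `smoothed = TRUE`.
#' @export
smooth_rolling <- function(series, denom = 256) {
  stopifnot(inherits(series, "feature_series"))
  check_number(denom, "denom", lower = 1)
  l <- series_length(series)
  w <- max(1L, as.integer(round(l / denom)))
  if (w >= l) {
    rlang::abort(sprintf(
      "smoothing window %d must be smaller than the series length %d.", w, l))
  }
  series$values <- purrr::map(series$values, rolling_mean, w = w)
  series$smoothed <- TRUE
  series
}

#' Z-score normalize feature series
#'
#' Centers and scales each series to mean 0 and (population) standard
#' deviation 1, aligning the scale of DCT residues with radius features so
#' the two kinds can be analyzed jointly. A constant series maps to all
#' zeros rather than dividing by zero.
#'
#' @param series a [feature_series()] table.
#' @return the normalized [feature_series()] with `normalized = TRUE`.
#' @export
normalize_series <- function(series) {
  stopifnot(inherits(series, "feature_series"))
  series$values <- purrr::map2(series$values, series$subject_id, function(v, id) {
    m <- mean(v)
    sdev <- sqrt(mean((v - m)^2))
    if (!is.finite(sdev) || sdev < .Machine$double.eps) {
      rlang::inform(sprintf("constant series for %s mapped to zeros.", id))
      return(rep(0, length(v)))
    }
    (v - m) / sdev
  })
  series$normalized <- TRUE
  series
}

#' Extract aligned feature series from a dataset
#'
#' Runs the per-drawing preprocessing chain (pen-down filtering, fixed-length
#' resampling, radius or DCT-residue transform, rolling-mean smoothing and
#' optional z-score normalization) over every record of a dataset and returns
#' the resulting feature table joined with the subject metadata.
#'
#' @param dataset a [spiral_dataset()].
#' @param kind `"radius"` or `"dct_residue"`.
#' @param n resample length (default 4096).
#' @param denom rolling-mean window divisor (default 256).
#' @param k_keep number of leading DCT coefficients removed from the residue
#'   (only for `kind = "dct_residue"`).
#' @param smooth apply [smooth_rolling()]?
#' @param normalize apply [normalize_series()]? Off by default: correlation
#'   analyses are scale-invariant and the classification path keeps the
#'   severity-scaled amplitude information.
#' @param combine residue combination mode, see [dct_residue()].
#' @return a [feature_series()] tibble with metadata columns `group`,
#'   `trs_score` and `tremor_level` attached.
#' @export
extract_features <- function(dataset, kind = c("radius", "dct_residue"),
                             n = 4096, denom = 256, k_keep = 32,
                             smooth = TRUE, normalize = FALSE,
                             combine = c("magnitude", "concat")) {
  kind <- match.arg(kind)
  combine <- match.arg(combine)
  stopifnot(inherits(dataset, "spiral_dataset"))
  values <- purrr::map(dataset$spiral, function(rec) {
    rec <- resample_fixed(filter_pen_down(rec), n = n)
    if (kind == "radius") {
      sqrt(rec$x^2 + rec$y^2)
    } else {
      dct_residue(rec$x, rec$y, k_keep = k_keep, combine = combine)
    }
  })
  out <- feature_series(dataset$subject_id, kind = kind, values = values)
  if (smooth) out <- smooth_rolling(out, denom = denom)
  if (normalize) out <- normalize_series(out)
  out$group <- dataset$group
  out$trs_score <- dataset$trs_score
  out$tremor_level <- dataset$tremor_level
  out
}
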