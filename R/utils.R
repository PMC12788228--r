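# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG state
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so package functions are deterministic without
#' clobbering user-level random streams.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    rlang::abort("`seed` must be a single finite number.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# smooth unit-variance noise: white Gaussian noise low-pass filtered in the
# frequency domain below `cutoff_hz`, rescaled to sd 1 (zeros if degenerate)
smooth_noise <- function(n, sampling_rate, cutoff_hz) {
  if (n < 2L) return(rep(0, n))
  w <- stats::rnorm(n)
  f <- seq(0, sampling_rate, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, sampling_rate - f) # two-sided frequency axis
  spec <- stats::fft(w)
  spec[f > cutoff_hz] <- 0
  s <- Re(stats::fft(spec, inverse = TRUE)) / n
  sdev <- stats::sd(s)
  if (!is.finite(sdev) || sdev < .Machine$double.eps) return(rep(0, n))
  (s - mean(s)) / sdev
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    rlang::abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower && x <= lower) {
    rlang::abort(sprintf("`%s` must be > %s.", name, format(lower)))
  }
  if (!strict_lower && x < lower) {
    rlang::abort(sprintf("`%s` must be >= %s.", name, format(lower)))
  }
  if (x > upper) {
    rlang::abort(sprintf("`%s` must be <= %s.", name, format(upper)))
  }
  invisible(x)
}
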