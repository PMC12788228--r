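# shared fixtures: cohorts are expensive, so cache them per configuration
# within one test run

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(n_control = 29, n_low = 12, n_high = 12, seed = 1,
                          ...) {
  key <- paste(n_control, n_low, n_high, seed, ..., sep = "_")
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- make_cohort(
      cohort_config(n_control = n_control, n_low = n_low, n_high = n_high,
                    seed = seed, ...))
  }
  .cohort_cache[[key]]
}

.feature_cache <- new.env(parent = emptyenv())

cached_features <- function(dataset, kind, tag) {
  key <- paste(kind, tag, sep = "_")
  if (is.null(.feature_cache[[key]])) {
    .feature_cache[[key]] <- extract_features(dataset, kind)
  }
  .feature_cache[[key]]
}

# small hand-built record for IO and preprocessing unit tests
toy_record <- function(n = 20, subject_id = "toy") {
  t <- (seq_len(n) - 1) / 200
  spiral_record(
    x = cos(t * 3) * (1 + t), y = sin(t * 3) * (1 + t), t = t,
    pen_state = rep(1, n), azimuth = rep(45, n), altitude = rep(60, n),
    pressure = seq(400, 600, length.out = n),
    subject_id = subject_id, sampling_rate = 200
  )
}

# band power of a series between lo and hi Hz via the raw periodogram
band_power <- function(v, fs, lo = 4, hi = 12) {
  n <- length(v)
  v <- v - mean(v)
  p <- Mod(stats::fft(v))[2:(n %/% 2)]^2
  f <- seq_along(p) * fs / n
  sum(p[f >= lo & f <= hi])
}
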