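test_that("pen-down filtering keeps only touching samples in time order", {
  rec <- toy_record(3)
  kept_all <- filter_pen_down(rec) # all pen-down: identity
  expect_equal(attr(kept_all, "fraction_removed"), 0)
  attr(kept_all, "fraction_removed") <- NULL
  expect_identical(kept_all, rec)

  rec2 <- spiral_record(x = 1:3, y = 1:3, t = c(0, 1, 2),
                        pen_state = c(1, 0, 1))
  kept <- filter_pen_down(rec2)
  expect_equal(nrow(kept), 2L)
  expect_equal(kept$x, c(1, 3))
  expect_equal(attr(kept, "fraction_removed"), 1 / 3)

  rec3 <- spiral_record(x = 1:2, y = 1:2, t = c(0, 1), pen_state = c(0, 0))
  expect_error(filter_pen_down(rec3), "no pen-down")
})

test_that("fixed-length resampling interpolates linearly and keeps endpoints", {
  rec <- spiral_record(x = c(0, 1), y = c(5, 3), t = c(0, 1))
  out <- resample_fixed(rec, n = 11)
  expect_equal(out$x, seq(0, 1, length.out = 11))
  expect_equal(out$y, seq(5, 3, length.out = 11))
  expect_equal(out$t[c(1, 11)], c(0, 1))

  # uniform grid of the target length passes through unchanged
  rec2 <- toy_record(64)
  out2 <- resample_fixed(rec2, n = 64)
  expect_equal(out2$x, rec2$x, tolerance = 1e-12)
  expect_equal(out2$y, rec2$y, tolerance = 1e-12)

  expect_error(resample_fixed(rec, n = 1), ">= 2")
})

test_that("resampling a clean spiral stays within 1% of the dense trace", {
  p <- spiral_params(duration = 10, sampling_rate = 200) # 2000 samples
  rec <- make_clean_spiral(p)
  out <- resample_fixed(rec, n = 4096)
  dense <- seq(0, 1, length.out = 20000)
  u_in <- (rec$t - rec$t[1]) / (rec$t[nrow(rec)] - rec$t[1])
  u_out <- (out$t - out$t[1]) / (out$t[nrow(out)] - out$t[1])
  r_max <- max(sqrt(rec$x^2 + rec$y^2))
  for (ch in c("x", "y")) {
    a <- stats::approx(u_in, rec[[ch]], xout = dense)$y
    b <- stats::approx(u_out, out[[ch]], xout = dense)$y
    expect_lt(max(abs(a - b)), 0.01 * r_max)
  }
  expect_true(all(out$pen_state %in% c(0, 1)))
})

test_that("the radius transform is the pointwise Euclidean norm", {
  rec <- spiral_record(x = c(3, 0, 1), y = c(4, 0, 1), t = c(0, 1, 2))
  rs <- to_radius(rec)
  expect_equal(rs$values[[1]], c(5, 0, sqrt(2)))
  expect_equal(rs$kind, "radius")

  clean <- make_clean_spiral(spiral_params(a = 0, duration = 5))
  expect_lt(max(abs(to_radius(clean)$values[[1]] - attr(clean, "theta"))),
            1e-9)
})

test_that("rolling-mean smoothing follows the window law and its edge rules", {
  const <- feature_series("c", "radius", list(rep(3.5, 100)))
  expect_equal(smooth_rolling(const, 10)$values[[1]], rep(3.5, 100))

  v <- rnorm(50)
  fs <- feature_series("v", "radius", list(v))
  expect_equal(smooth_rolling(fs, denom = 50)$values[[1]], v) # w = 1 identity
  sm <- smooth_rolling(fs, denom = 10) # w = 5
  expect_length(sm$values[[1]], 50)
  expect_true(sm$smoothed[1])
  # smoothing never increases the range
  expect_gte(min(sm$values[[1]]), min(v))
  expect_lte(max(sm$values[[1]]), max(v))
  # interior value is the plain 5-point centered mean
  expect_equal(sm$values[[1]][10], mean(v[8:12]))

  expect_error(smooth_rolling(fs, denom = 1), "smaller than")
})

test_that("moving-average attenuation of a sinusoid matches the closed form", {
  fs_hz <- 200
  l <- 4096
  f <- 6
  tt <- (seq_len(l) - 1) / fs_hz
  v <- sin(2 * pi * f * tt)
  sm <- smooth_rolling(feature_series("s", "radius", list(v)),
                       denom = 256)$values[[1]] # w = 16
  w <- 16
  gain <- abs(sin(pi * f * w / fs_hz) / (w * sin(pi * f / fs_hz)))
  interior <- 200:3900 # away from the shrinking-window edges
  ratio <- sqrt(mean(sm[interior]^2)) / sqrt(mean(v[interior]^2))
  expect_equal(ratio, gain, tolerance = 0.01)
})

test_that("z-score normalization has unit-variance output and a constant guard", {
  fs <- feature_series("a", "radius", list(c(1, 2, 3)))
  out <- normalize_series(fs)
  expect_equal(out$values[[1]], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_true(out$normalized[1])

  v <- rnorm(500, 10, 4)
  z <- normalize_series(feature_series("b", "radius", list(v)))$values[[1]]
  expect_lt(abs(mean(z)), 1e-9)
  expect_equal(sqrt(mean((z - mean(z))^2)), 1, tolerance = 1e-9)

  expect_message(
    zc <- normalize_series(feature_series("c", "radius", list(rep(2, 10)))),
    "constant")
  expect_equal(zc$values[[1]], rep(0, 10))
})

test_that("extract_features preserves the canonical length and metadata", {
  ds <- cached_cohort(8, 6, 6, seed = 3)
  fr <- extract_features(ds, "radius", n = 512, denom = 64)
  expect_s3_class(fr, "feature_series")
  expect_equal(nrow(fr), nrow(ds))
  expect_true(all(lengths(fr$values) == 512L))
  expect_equal(fr$group, ds$group)
  expect_equal(fr$tremor_level, ds$tremor_level)
})
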