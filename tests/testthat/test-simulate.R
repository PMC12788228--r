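test_that("clean spirals satisfy the Archimedean closed form", {
  p <- spiral_params(a = 0, b = 1.3, n_turns = 4, duration = 10,
                     sampling_rate = 100)
  rec <- make_clean_spiral(p)
  theta <- attr(rec, "theta")
  r <- sqrt(rec$x^2 + rec$y^2)
  expect_equal(nrow(rec), 1000L)
  expect_equal(r[1], 0)
  expect_true(all(diff(r) >= -1e-12)) # radius nondecreasing from the origin
  expect_lt(max(abs(r - (p$a + p$b * theta))), 1e-9)
  expect_true(all(rec$pen_state == 1))
  expect_true(all(rec$pressure > 0))
  # approximately constant pen speed
  speed <- sqrt(diff(rec$x)^2 + diff(rec$y)^2)
  expect_lt(stats::sd(speed) / mean(speed), 0.01)
})

test_that("the default drawing geometry yields 4096 samples", {
  rec <- make_clean_spiral(spiral_params())
  expect_equal(nrow(rec), 4096L)
})

test_that("tremor injection honours its contracts", {
  rec <- make_clean_spiral(spiral_params(n_turns = 3, duration = 8))
  # amplitude zero is the identity
  expect_identical(add_tremor(rec, tremor_params(amplitude = 0), seed = 5), rec)
  # same seed gives bit-identical output
  tp <- tremor_params(amplitude = 1, frequency = 7)
  expect_identical(add_tremor(rec, tp, seed = 9), add_tremor(rec, tp, seed = 9))
  expect_false(identical(add_tremor(rec, tp, seed = 9),
                         add_tremor(rec, tp, seed = 10)))
  # super-Nyquist frequencies are rejected
  slow <- make_clean_spiral(spiral_params(duration = 10, sampling_rate = 20))
  expect_error(add_tremor(slow, tremor_params(amplitude = 1, frequency = 11),
                          seed = 1), "Nyquist")
  expect_error(tremor_params(amplitude = 1, frequency = 3), "\\[4, 12\\]")
})

test_that("injected tremor produces a radius spectral peak at its frequency", {
  rec <- make_clean_spiral(spiral_params())
  trem <- add_tremor(rec, tremor_params(amplitude = 2, frequency = 6,
                                        amp_jitter = 0, drift_sd = 0),
                     seed = 3)
  rad <- sqrt(trem$x^2 + trem$y^2)
  smoothed <- smooth_rolling(feature_series("s", "radius", list(rad)), 256)
  resid <- rad - smoothed$values[[1]]
  n <- length(resid)
  fs <- sampling_rate(trem)
  p <- Mod(stats::fft(resid - mean(resid)))[2:(n %/% 2)]^2
  f <- seq_along(p) * fs / n
  expect_lt(abs(f[which.max(p)] - 6), fs / n + 1e-9) # within one bin
})

test_that("cohorts are reproducible and structured as configured", {
  ds <- cached_cohort(seed = 1)
  expect_equal(nrow(ds), 53L)
  expect_equal(sum(ds$group == "control"), 29L)
  expect_equal(sum(ds$group == "ET"), 24L)
  expect_equal(unname(table(ds$tremor_level)), c(29L, 12L, 12L),
               ignore_attr = TRUE)
  expect_true(all(ds$trs_score[ds$tremor_level == 0] == 0))
  expect_true(all(ds$trs_score >= 0))
  # pure function of the config
  again <- make_cohort(cohort_config(seed = 1))
  expect_identical(ds$trs_score, again$trs_score)
  expect_identical(ds$spiral[[53]]$x, again$spiral[[53]]$x)
})

test_that("an all-control cohort has zero TRS and level everywhere", {
  ds <- make_cohort(cohort_config(n_control = 6, n_low = 0, n_high = 0,
                                  seed = 2))
  expect_true(all(ds$trs_score == 0))
  expect_true(all(ds$tremor_level == 0))
  expect_true(all(ds$group == "control"))
})

test_that("TRS scores track tremor level strongly in a large cohort", {
  ds <- cached_cohort(n_control = 80, n_low = 60, n_high = 60, seed = 11)
  r <- pearson_r(ds$trs_score, ds$tremor_level)
  expect_gt(r, 0.8)
})

test_that("radius band power increases strictly with severity level", {
  mono <- vapply(1:10, function(s) {
    ds <- make_cohort(cohort_config(n_control = 4, n_low = 4, n_high = 4,
                                    seed = s))
    bp <- vapply(ds$spiral,
                 function(r) band_power(sqrt(r$x^2 + r$y^2),
                                        sampling_rate(r)),
                 numeric(1))
    m <- tapply(bp, ds$tremor_level, mean)
    m[[1]] < m[[2]] && m[[2]] < m[[3]]
  }, logical(1))
  expect_equal(sum(mono), 10L)
})

test_that("cohort config invariants are enforced", {
  expect_error(cohort_config(n_low = -1), "nonnegative")
  expect_error(cohort_config(amplitude_by_level = c(0.1, 0.2, 0.3)),
               "start at 0")
  expect_error(cohort_config(amplitude_by_level = c(0, 0.3, 0.2)),
               "strictly increasing")
  expect_error(
    cohort_config(trs_map = list(c(0, 0), c(9, 3), c(6, 2))),
    "strictly increasing")
})

test_that("pen-up bursts shrink the pen-down record by the burst size", {
  rec <- make_clean_spiral(spiral_params(duration = 10))
  burst <- add_pen_up_burst(rec, fraction = 0.05, seed = 4)
  kept <- filter_pen_down(burst)
  expect_equal(nrow(kept), nrow(rec) - round(0.05 * nrow(rec)))
  expect_equal(attr(kept, "fraction_removed"),
               round(0.05 * nrow(rec)) / nrow(rec))
})
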