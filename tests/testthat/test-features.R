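test_that("DCT-II matches the direct cosine-sum evaluation", {
  set.seed(1)
  x <- rnorm(16)
  n <- length(x)
  brute <- vapply(0:(n - 1), function(k) {
    w <- if (k == 0) sqrt(1 / n) else sqrt(2 / n)
    w * sum(x * cos(pi * k * (2 * (0:(n - 1)) + 1) / (2 * n)))
  }, numeric(1))
  expect_lt(max(abs(dct_type2(x) - brute)), 1e-9)
})

test_that("DCT is orthonormal: round trip, Parseval, DC concentration", {
  set.seed(2)
  for (len in c(1, 2, 7, 64, 333)) {
    x <- rnorm(len)
    cf <- dct_type2(x)
    expect_lt(max(abs(idct_type2(cf) - x)), 1e-9)
    expect_lt(abs(sum(x^2) - sum(cf^2)), 1e-9)
  }
  cf <- dct_type2(rep(4, 32))
  expect_equal(cf[1], 4 * sqrt(32), tolerance = 1e-12)
  expect_lt(max(abs(cf[-1])), 1e-9)
  expect_error(dct_type2(numeric(0)), "empty")
})

test_that("DCT residues isolate content beyond the kept coefficients", {
  n <- 64
  idx <- 0:(n - 1)
  low <- cos(pi * 2 * (2 * idx + 1) / (2 * n)) # pure DCT index 2
  high <- cos(pi * 40 * (2 * idx + 1) / (2 * n)) # pure DCT index 40
  # below the cut: residue vanishes
  r_low <- dct_residue(low, rep(0, n), k_keep = 8)
  expect_lt(max(abs(r_low)), 1e-9)
  # above the cut: the full energy survives
  r_high <- dct_residue(high, rep(0, n), k_keep = 8)
  expect_equal(sum(r_high^2), sum(high^2), tolerance = 1e-9)
  # k_keep = L - 1 on a low-order signal reconstructs almost everything
  r_all <- dct_residue(low, low, k_keep = n - 1)
  expect_lt(max(abs(r_all)), 1e-9)
  expect_error(dct_residue(low, rep(0, n), k_keep = n), "k_keep")
  # concat mode stacks the two coordinate residuals
  expect_length(dct_residue(low, high, k_keep = 8, combine = "concat"), 2 * n)
})

test_that("residue energy is monotone nonincreasing in k_keep", {
  set.seed(3)
  x <- cumsum(rnorm(128))
  y <- cumsum(rnorm(128))
  energies <- vapply(c(2, 8, 16, 32, 64),
                     function(k) sum(dct_residue(x, y, k_keep = k)^2),
                     numeric(1))
  expect_true(all(diff(energies) <= 1e-9))
})

test_that("a tremor-injected spiral has more residue energy than a clean one", {
  clean <- resample_fixed(make_clean_spiral(spiral_params()), 4096)
  trem <- resample_fixed(
    add_tremor(make_clean_spiral(spiral_params()),
               tremor_params(amplitude = 1, frequency = 6), seed = 2),
    4096)
  e_clean <- sum(dct_residue(clean$x, clean$y, k_keep = 32)^2)
  e_trem <- sum(dct_residue(trem$x, trem$y, k_keep = 32)^2)
  expect_gt(e_trem, e_clean)
})

test_that("correlation matrices are symmetric, unit-diagonal and bounded", {
  ds <- cached_cohort(8, 6, 6, seed = 3)
  fr <- cached_features(ds, "radius", "small3")
  for (mode in c("inter_subject", "inter_temporal")) {
    cs <- group_correlation_matrix(fr, mode = mode)
    m <- cs$matrix
    expect_identical(m, t(m))
    expect_equal(unname(diag(m)), rep(1, nrow(m)))
    expect_true(all(m >= -1 & m <= 1))
    expect_equal(cs$offdiag_mean, mean(m[upper.tri(m)]))
  }
  expect_equal(group_correlation_matrix(fr, "inter_subject")$n, nrow(ds))
  expect_equal(group_correlation_matrix(fr, "inter_temporal", grid = 32)$n,
               32L)
})

test_that("degenerate correlation inputs raise informative errors", {
  dup <- feature_series(c("a", "b"), "radius",
                        list(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(group_correlation_matrix(dup)$offdiag_mean, 1)
  anti <- feature_series(c("a", "b"), "radius",
                         list(c(1, 2, 3, 4), -c(1, 2, 3, 4)))
  expect_equal(group_correlation_matrix(anti)$offdiag_mean, -1)
  single <- feature_series("a", "radius", list(1:4))
  expect_error(group_correlation_matrix(single), "at least 2")
  flat <- feature_series(c("a", "flat"), "radius",
                         list(c(1, 2, 3, 4), rep(2, 4)))
  expect_error(group_correlation_matrix(flat), "flat")
})

test_that("control drawings correlate more consistently than tremulous ones", {
  # direction of effect over ten independent cohorts, both feature kinds
  hits <- vapply(1:10, function(s) {
    ds <- cached_cohort(seed = s)
    fr <- cached_features(ds, "radius", paste0("coh", s))
    fd <- cached_features(ds, "dct_residue", paste0("coh", s))
    cr <- correlation_consistency(fr)
    cd <- correlation_consistency(fd)
    c(cr$control$offdiag_mean > cr$et$offdiag_mean,
      cd$control$offdiag_mean > cd$et$offdiag_mean)
  }, logical(2))
  expect_gte(sum(hits[1, ]), 9L)
  expect_gte(sum(hits[2, ]), 9L)
})

test_that("the off-diagonal distribution report summarizes both groups", {
  ds <- cached_cohort(8, 6, 6, seed = 3)
  fr <- cached_features(ds, "radius", "small3")
  cc <- correlation_consistency(fr)
  rep <- offdiag_distributions(cc$control, cc$et)
  expect_equal(nrow(rep$table), 2L)
  expect_s3_class(rep$histogram, "ggplot")
  expect_s3_class(rep$boxplot, "ggplot")
  # identical inputs give identical per-group statistics
  twin <- cc$control
  twin$group <- "control-copy"
  both <- offdiag_distributions(cc$control, twin)
  cols <- c("mean", "sd", "median", "iqr")
  expect_equal(both$table[1, cols], both$table[2, cols], ignore_attr = TRUE)
  # a wider spread is reported as a larger IQR
  widest <- which.max(rep$table$iqr)
  expect_equal(rep$table$group[widest],
               with(rep$table, group[which.max(iqr)]))
  # mode mismatch is refused
  other <- group_correlation_matrix(fr, "inter_temporal", group = "ET")
  expect_error(offdiag_distributions(cc$control, other), "mode")
})
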