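test_that("exact U test matches full enumeration on the textbook case", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$u_statistic, 0)
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, 1 / 3) # 2 of the 6 rank assignments are as extreme
})

test_that("identical samples give the central U and p = 1", {
  a <- c(2, 5, 9, 11)
  res <- mann_whitney_u(a, a) # ties force the tie-corrected approximation
  expect_equal(res$method, "normal_approx")
  expect_equal(res$u_statistic, length(a)^2 / 2)
  expect_equal(res$p_value, 1)
  expect_warning(mann_whitney_u(a, a, exact = TRUE), "ties")
})

test_that("exact enumeration agrees with wilcox.test and bounds the approximation", {
  set.seed(5)
  max_gap <- 0
  for (i in 1:20) {
    a <- rnorm(8)
    b <- rnorm(8)
    ours <- mann_whitney_u(a, b)
    expect_equal(ours$method, "exact")
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$u_statistic, unname(ref$statistic))
    approx_p <- mann_whitney_u(a, b, exact = FALSE)$p_value
    max_gap <- max(max_gap, abs(ours$p_value - approx_p))
  }
  expect_lt(max_gap, 0.02)
})

test_that("the normal approximation matches wilcox.test with ties present", {
  set.seed(6)
  a <- sample(1:6, 30, replace = TRUE)
  b <- sample(2:8, 25, replace = TRUE)
  ours <- mann_whitney_u(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(ours$method, "normal_approx")
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("the U test is invariant under strictly monotone transforms", {
  set.seed(7)
  a <- rexp(12)
  b <- rexp(15) * 1.5
  p0 <- mann_whitney_u(a, b)$p_value
  for (f in list(function(x) x^3, exp, function(x) 5 * x - 2)) {
    expect_equal(mann_whitney_u(f(a), f(b))$p_value, p0)
  }
})

test_that("type-I error under an exchangeable null sits near the nominal level", {
  set.seed(13)
  rejections <- vapply(seq_len(1000), function(i) {
    mann_whitney_u(rnorm(20), rnorm(20))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("pearson_r matches the direct covariance formula and rejects junk", {
  set.seed(8)
  a <- rnorm(10)
  b <- rnorm(10)
  direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_r(a, b), direct, tolerance = 1e-12)
  expect_equal(pearson_r(a, a), 1)
  expect_equal(pearson_r(a, -a), -1)
  expect_error(pearson_r(a, rep(1, 10)), "constant")
  expect_error(pearson_r(a, b[1:5]), "equal length")
})

test_that("metadata correlations reflect the cohort severity structure", {
  ds <- cached_cohort(n_control = 80, n_low = 60, n_high = 60, seed = 11)
  m <- metadata_correlations(ds)
  expect_identical(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 3))
  expect_gt(m["trs_score", "tremor_level"], 0.8)

  # a cohort where TRS equals the level exactly correlates perfectly
  toy <- tibble::tibble(trs_score = c(0, 1, 2, 0, 1, 2),
                        age = c(40, 50, 60, 45, 55, 65),
                        tremor_level = c(0, 1, 2, 0, 1, 2))
  expect_equal(metadata_correlations(toy)["trs_score", "tremor_level"], 1)

  bad <- tibble::tibble(subject_id = c("a", "b", "c"),
                        trs_score = c(0, NA, 2),
                        age = c(40, 50, 60),
                        tremor_level = c(0, 1, 2))
  expect_error(metadata_correlations(bad), "b")
})
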