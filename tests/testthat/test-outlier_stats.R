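test_that("fences follow the 1.5 IQR rule with interpolated quartiles", {
  mat <- matrix(c(1, 2, 3, 4, 5), ncol = 1)
  fe <- compute_fences(mat, k = 1.5)
  expect_equal(fe$q1, 2)
  expect_equal(fe$q3, 4)
  expect_equal(fe$lower, -1)
  expect_equal(fe$upper, 7)

  # k = 0 collapses the fences onto the quartiles
  fe0 <- compute_fences(mat, k = 0)
  expect_equal(fe0$lower, fe0$q1)
  expect_equal(fe0$upper, fe0$q3)

  # constant column: zero IQR, fences at the value
  fc <- compute_fences(matrix(rep(3.3, 5), ncol = 1))
  expect_equal(fc$iqr, 0)
  expect_equal(fc$lower, 3.3)
  expect_equal(fc$upper, 3.3)

  # Tukey hinges differ from interpolation at even n
  m4 <- matrix(1:4, ncol = 1)
  expect_equal(compute_fences(m4, method = "linear")$q1, 1.75)
  expect_equal(compute_fences(m4, method = "hinges")$q1, 1.5)
  expect_equal(compute_fences(m4, method = "hinges")$q3, 3.5)

  expect_error(compute_fences(matrix(1:3, ncol = 1)), "at least 4")
})

test_that("outlier counting is strict at the fences", {
  mat <- rbind(matrix(rep(c(1, 2, 3), 4), 4, byrow = TRUE), c(1, 2, 13))
  fe <- compute_fences(mat)
  expect_equal(count_outlier_points(mat, fe), 1L)

  ident <- matrix(rep(c(1, 2, 3), 5), 5, byrow = TRUE)
  expect_equal(count_outlier_points(ident, compute_fences(ident)), 0L)

  # boundary convention: a value exactly on a fence is not an outlier
  fe1 <- data.frame(q1 = 2, q3 = 4, iqr = 2, lower = -1, upper = 7)
  expect_equal(count_outlier_points(matrix(7), fe1), 0L)
  expect_equal(count_outlier_points(matrix(7 + 1e-9), fe1), 1L)
  expect_equal(count_outlier_points(matrix(-1), fe1), 0L)

  expect_error(count_outlier_points(matrix(1:4, 2), fe1), "wavelengths")
})

test_that("outlier counts match the brute-force oracle on random matrices", {
  set.seed(11)
  for (i in 1:25) {
    nr <- sample(5:10, 1)
    nc <- sample(1:10, 1)
    mat <- matrix(rnorm(nr * nc), nr, nc)
    k <- sample(c(0, 1, 1.5, 3), 1)
    fe <- compute_fences(mat, k = k)
    expect_identical(count_outlier_points(mat, fe), oracle_outlier_count(mat, k))
  }
})

test_that("a single planted outlier point gives f = 1/15 on a 5 x 3 cohort", {
  mat <- rbind(matrix(rep(c(0, 1, 2), 4), 4, byrow = TRUE), c(0, 1, 12))
  res <- cohort_outlier_fraction(mat, snv = FALSE)
  expect_equal(res$outlier_points, 1L)
  expect_equal(res$total_points, 15L)
  expect_equal(res$f, 1 / 15)
  expect_identical(res$outlier_points, oracle_outlier_count(mat, 1.5))
})

test_that("f is zero for scatter-only cohorts and bounded in [0, 1]", {
  set.seed(12)
  shape <- runif(8, 0.3, 1)
  mat <- t(sapply(1:6, function(i) runif(1, 0.5, 2) * shape + runif(1, -1, 1)))
  expect_equal(cohort_outlier_fraction(mat)$f, 0)

  for (i in 1:10) {
    m <- matrix(rnorm(48), nrow = 6)
    f <- cohort_outlier_fraction(m, snv = FALSE)$f
    expect_gte(f, 0)
    expect_lte(f, 1)
  }
})

test_that("f is invariant to per-scan affine scatter and to row/column order", {
  set.seed(13)
  mat <- matrix(rnorm(10 * 8, mean = 1), 10, 8)
  base <- cohort_outlier_fraction(mat)
  scattered <- mat * runif(10, 0.5, 2) + runif(10, -3, 3)
  expect_equal(cohort_outlier_fraction(scattered)$f, base$f)

  m2 <- mat[sample(10), sample(8)]
  expect_equal(cohort_outlier_fraction(m2)$f, base$f)
})

test_that("raising the fence multiplier never adds outliers", {
  set.seed(14)
  for (i in 1:10) {
    mat <- matrix(rnorm(60), nrow = 6)
    counts <- sapply(c(0, 0.5, 1, 1.5, 2, 3),
                     function(k) count_outlier_points(mat, compute_fences(mat, k = k)))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("pooled-cohort f is not the scan-weighted mean of sub-cohort f", {
  set.seed(15)
  # two sub-cohorts centred on different shapes: pooling shifts every fence
  shape_a <- sin(seq(0, pi, length.out = 12)) + 2
  shape_b <- cos(seq(0, pi, length.out = 12)) + 2
  a <- t(sapply(1:8, function(i) shape_a + rnorm(12, 0, 0.05)))
  b <- t(sapply(1:8, function(i) shape_b + rnorm(12, 0, 0.4)))
  fa <- cohort_outlier_fraction(a)$f
  fb <- cohort_outlier_fraction(b)$f
  pooled <- cohort_outlier_fraction(rbind(a, b))$f
  weighted <- (8 * fa + 8 * fb) / 16
  expect_false(isTRUE(all.equal(pooled, weighted)))
})

test_that("measurement tolerance is the max pairwise trial difference at 4 dp", {
  expect_equal(measurement_tolerance(c(0.0105, 0.0113))$value, 0.0008)
  expect_equal(measurement_tolerance(c(0.02, 0.02))$value, 0)
  expect_equal(measurement_tolerance(c(0.01, 0.012, 0.011))$value, 0.002)
  expect_error(measurement_tolerance(0.01), "at least 2")
  expect_equal(default_tolerance(), 0.0008)
})
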