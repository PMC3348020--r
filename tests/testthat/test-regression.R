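test_that("pearson_r matches hand-computed values and validates input", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(6, 4, 2)), -1.0)
  # N = 4: r = (4*29 - 10*10) / sqrt((4*30 - 100)(4*30 - 100)) = 16/20
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_r(c(1, 2, 3), c(1, 2)), "length mismatch")
  expect_error(pearson_r(c(1, 2), c(3, 4)), "N >= 3")
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("pearson_r transforms correctly under affine maps of either argument", {
  set.seed(3)
  x <- rnorm(15); y <- rnorm(15)
  r <- pearson_r(x, y)
  expect_equal(pearson_r(2.5 * x + 7, y), r)
  expect_equal(pearson_r(x, 0.3 * y - 2), r)
  expect_equal(pearson_r(-1.5 * x, y), -r)
})

test_that("correlate_all ranks by |r| and reports constant columns as skipped", {
  set.seed(10)
  X <- cbind(a = rnorm(10), b = rnorm(10), c = rnorm(10), flat = rep(2, 10))
  y <- X[, "c"]
  rep <- correlate_all(X, y)
  expect_identical(rep$results$column[1], "c")
  expect_equal(rep$results$r[1], 1.0)
  expect_identical(rep$skipped, "flat")
  expect_true(all(abs(rep$results$r[-1]) < 1))
  expect_true(all(diff(rep$results$abs_r) <= 0))
})

test_that("multiple regression recovers exact linear relationships", {
  x <- 1:10
  fit <- fit_multiple_regression(matrix(x, dimnames = list(NULL, "x")), 2 + 3 * x)
  expect_equal(unname(fit$coefficients), c(2, 3), tolerance = 1e-10)
  expect_equal(fit$R, 1.0, tolerance = 1e-12)
  expect_equal(fit$N, 10L)
  expect_equal(fit$p, 1L)
})

test_that("saturated and collinear designs are refused with informative errors", {
  set.seed(4)
  X <- random_features(6, 5, seed = 4)
  y <- rnorm(6)
  expect_error(fit_multiple_regression(X, y), "insufficient data")
  # override reproduces the saturated regime: p = N - 1 gives R near 1
  fit <- fit_multiple_regression(X, y, allow_saturated = TRUE)
  expect_gt(fit$R, 0.99)

  X2 <- cbind(a = rnorm(12), b = rnorm(12))
  X2 <- cbind(X2, dup = X2[, "a"])
  expect_error(fit_multiple_regression(X2, rnorm(12)), "collinear.*dup")
})

test_that("predict reproduces fitted values and hand-computed dot products", {
  set.seed(5)
  X <- random_features(15, 3, seed = 5)
  y <- 1 + X %*% c(2, -1, 0.5) + rnorm(15, 0, 0.1)
  fit <- fit_multiple_regression(X, drop(y))
  expect_equal(unname(predict(fit, X)), fit$fitted, tolerance = 1e-10)
  zero_row <- matrix(0, 1, 3, dimnames = list(NULL, colnames(X)))
  expect_equal(unname(predict(fit, zero_row)),
               unname(fit$coefficients["(Intercept)"]))
  new_row <- matrix(c(1, 2, 3), 1, 3, dimnames = list(NULL, colnames(X)))
  expect_equal(unname(predict(fit, new_row)),
               unname(fit$coefficients[1] + sum(fit$coefficients[-1] * c(1, 2, 3))))
  expect_error(predict(fit, X[, 1:2]), "lacks model column")
})

test_that("noiseless subsets are identified exactly by the exhaustive search", {
  X <- random_features(20, 10, seed = 6)
  y <- 1 + 2 * X[, 3] - 1.5 * X[, 7]
  sr <- exhaustive_subset_search(X, y, sizes = 2)
  expect_setequal(sr$best$column_ids, c("c3", "c7"))
  expect_equal(sr$best$R, 1.0, tolerance = 1e-10)
})

test_that("search space accounting is exact and the ceiling refuses politely", {
  X <- random_features(20, 8, seed = 8)
  y <- rnorm(20)
  sr <- exhaustive_subset_search(X, y, sizes = 1:3)
  expect_equal(sr$n_fitted, sum(choose(8, 1:3)))
  expect_equal(sr$search_space, sum(choose(8, 1:3)))
  expect_error(exhaustive_subset_search(X, y, sizes = 1:3, max_fits = 10),
               "exceeds the ceiling")
  expect_error(exhaustive_subset_search(X, y, sizes = 1:5), NA)
  expect_error(exhaustive_subset_search(X[1:5, ], y[1:5], sizes = 4),
               "insufficient data")
})

test_that("a size-1 search agrees with the top single-column correlation", {
  X <- random_features(25, 12, seed = 12)
  y <- 0.8 * X[, 5] + rnorm(25, 0, 0.5)
  sr <- exhaustive_subset_search(X, y, sizes = 1)
  top <- correlate_all(X, y)$results[1, ]
  expect_identical(sr$best$column_ids, top$column)
  expect_equal(sr$best$R, top$abs_r, tolerance = 1e-10)
})
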