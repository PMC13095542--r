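# Evaluation metric oracles.

test_that("relative RMSE matches hand-computed cases", {
  expect_equal(relative_rmse(c(1, 2, 3), c(1, 2, 3), 0, 10), 0)
  # constant offset of 10% of the range reports 10%
  y <- runif(20, 0, 10)
  expect_equal(relative_rmse(y, y + 1, 0, 10), 10)
  # hand evaluation on normalised values 0.2/0.8 vs 0.3/0.7
  expect_equal(relative_rmse(c(0.2, 0.8), c(0.3, 0.7), 0, 1), 10)
  expect_error(relative_rmse(1, 1, 5, 5), "range")
})

test_that("RMSE agrees with a brute-force loop on random vectors", {
  set.seed(2)
  for (rep in 1:5) {
    yt <- rnorm(30); yp <- rnorm(30)
    acc <- 0
    for (i in seq_along(yt)) acc <- acc + (yt[i] - yp[i])^2  # loop oracle
    expect_equal(relative_rmse(yt, yp, -3, 3),
                 100 * sqrt(acc / 30) / 6, tolerance = 1e-12)
  }
})

test_that("ED and nMED match hand evaluation and scale correctly", {
  y <- c(0, 1, 2, 1)
  expect_equal(euclidean_distance(y, y), 0)
  expect_equal(nmed(y, y), 0)
  expect_equal(euclidean_distance(y, y + 0.1, x_gt = 1:4), 0.4,
               tolerance = 1e-12)
  expect_equal(nmed(y, y + 0.1), 0.05, tolerance = 1e-12)
  # scaling both curves by c scales ED by c and leaves nMED unchanged
  c_f <- 7.3
  expect_equal(euclidean_distance(c_f * y, c_f * (y + 0.1)),
               c_f * euclidean_distance(y, y + 0.1))
  expect_equal(nmed(c_f * y, c_f * (y + 0.1)), nmed(y, y + 0.1))
  expect_error(nmed(rep(1, 4), c(1, 2, 1, 2)), "zero range")
})

test_that("nMED equals mean absolute error over range on a shared grid", {
  set.seed(3)
  for (rep in 1:5) {
    y <- cumsum(rnorm(50)); yp <- y + rnorm(50, sd = 0.2)
    expect_equal(nmed(y, yp),
                 mean(abs(y - yp)) / diff(range(y)), tolerance = 1e-12)
  }
})

test_that("regression fit matches the normal equations", {
  expect_equal(regression_slope_r2(1:10, 1:10)$slope, 1)
  expect_equal(regression_slope_r2(1:10, 1:10)$r2, 1)
  expect_equal(regression_slope_r2(1:10, 2 * (1:10))$slope, 2)
  # printed triple against an explicit normal-equations oracle
  xt <- c(1, 2, 3); yp <- c(1.1, 1.9, 3.0)
  X <- cbind(1, xt)
  beta <- solve(t(X) %*% X, t(X) %*% yp)
  fit <- regression_slope_r2(xt, yp)
  expect_equal(fit$slope, beta[2], tolerance = 1e-12)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-12)
  expect_error(regression_slope_r2(c(1, 1), c(1, 2)), "degenerate")
})

test_that("test-set evaluation reports only held-out rows", {
  ds <- small_dataset()
  est <- train_estimator(ds, tiny_spec(),
                         training_config(epochs = 5, batch = 16, seed = 2))
  rep <- evaluate_test_set(est, ds, n_resim = 2)
  te <- which(ds$split == "test")
  expect_true(all(rep$nmed$row %in% te))              # leakage audit
  expect_identical(nrow(rep$per_parameter), 8L)
  expect_true(all(is.finite(rep$per_parameter$rmse_pct)))
  # report determinism under identical seeds and dataset
  est2 <- train_estimator(ds, tiny_spec(),
                          training_config(epochs = 5, batch = 16,
                                          seed = 2))
  rep2 <- evaluate_test_set(est2, ds, n_resim = 2)
  expect_equal(rep$per_parameter, rep2$per_parameter, tolerance = 1e-12)
})

test_that("training-size curve is deterministic and well-formed", {
  ds <- small_dataset()
  tc <- training_config(epochs = 4, batch = 16, seed = 1)
  out <- training_size_curve(ds, sizes = c(12), seeds = 1L,
                             spec = tiny_spec(), config = tc)
  expect_identical(nrow(out), 1L)                   # single-size table
  out2 <- training_size_curve(ds, sizes = c(12), seeds = 1L,
                              spec = tiny_spec(), config = tc)
  expect_equal(out$mean_rmse_pct, out2$mean_rmse_pct, tolerance = 1e-12)
})
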