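# Network engine, elastance bridge, training contracts.

test_that("elastance bridge is exact and guards its domain", {
  expect_equal(emax_bridge(100, 45, 5), 2.5)
  expect_equal(emax_bridge(0, 45, 5), 0)
  expect_equal(emax_bridge(200, 45, 5), 2 * emax_bridge(100, 45, 5))
  expect_error(emax_bridge(100, 5, 5), "Ves")
})

test_that("backpropagation matches finite differences", {
  set.seed(42)
  spec <- network_spec(channels = c(2, 4, 8), mlp_hidden = c(8, 8),
                       head = c(16, 8), out_dim = 3)
  m <- build_network(spec, input_len = 16, n_scalar = 4, seed = 7)
  B <- 4
  X <- array(rnorm(B * 2 * 16), c(B, 2, 16))
  S <- matrix(rnorm(B * 4), B, 4)
  Y <- matrix(rnorm(B * 3), B, 3)
  loss <- function(model)
    mean((cardiolpm:::nn_forward(model, X, S) - Y)^2)
  fw <- cardiolpm:::nn_forward(m, X, S, train = TRUE)
  gr <- cardiolpm:::nn_backward(m, fw$cache, 2 * (fw$out - Y) / length(Y))
  eps <- 1e-6
  worst <- 0
  for (part in c("conv", "mlp", "head"))
    for (l in seq_along(m[[part]])) for (p in c("W", "b")) {
      th <- m[[part]][[l]][[p]]
      for (i in sample(length(th), min(length(th), 6))) {
        m2 <- m; m2[[part]][[l]][[p]][i] <- th[i] + eps
        m3 <- m; m3[[part]][[l]][[p]][i] <- th[i] - eps
        num <- (loss(m2) - loss(m3)) / (2 * eps)
        ana <- gr[[part]][[l]][[p]][i]
        worst <- max(worst, abs(num - ana) / max(abs(num), abs(ana), 1e-8))
      }
    }
  expect_lt(worst, 1e-4)
})

test_that("network builder honours the shape contract", {
  # published architecture: 4 conv layers, L = 256, head to 1 or 6
  full <- build_network(network_spec(out_dim = 1), 256, 2, seed = 1)
  out <- cardiolpm:::nn_forward(full, array(rnorm(2 * 256), c(1, 2, 256)),
                                matrix(0, 1, 2))
  expect_identical(dim(out), c(1L, 1L))
  full6 <- build_network(network_spec(out_dim = 6), 256, 3, seed = 1)
  out6 <- cardiolpm:::nn_forward(full6, array(rnorm(2 * 256), c(1, 2, 256)),
                                 matrix(0, 1, 3))
  expect_identical(dim(out6), c(1L, 6L))
  # seeded initialisation is reproducible
  a <- build_network(tiny_spec(), 32, 2, seed = 3)
  b <- build_network(tiny_spec(), 32, 2, seed = 3)
  X <- array(rnorm(2 * 32), c(1, 2, 32)); S <- matrix(0, 1, 2)
  expect_identical(cardiolpm:::nn_forward(a, X, S),
                   cardiolpm:::nn_forward(b, X, S))
  # incompatible length is rejected with the divisibility requirement
  expect_error(build_network(network_spec(out_dim = 1), 100, 2),
               "divisible")
})

test_that("pooling and im2col round-trip as adjoints", {
  # <u, A v> == <A* u, v> for the col2im/im2col pair
  set.seed(5)
  B <- 2; C <- 3; L <- 8
  M <- matrix(rnorm(C * B * L), C, B * L)
  U <- matrix(rnorm(3 * C * B * L), 3 * C, B * L)
  lhs <- sum(U * cardiolpm:::im2col(M, B, L))
  rhs <- sum(M * cardiolpm:::col2im(U, B, L))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("training fits a degenerate constant-target dataset", {
  set.seed(8)
  B <- 48; L <- 16
  X <- array(rnorm(B * 2 * L), c(B, 2, L))
  S <- matrix(rnorm(B * 2), B, 2)
  Y <- matrix(0.37, B, 1)
  m <- build_network(network_spec(c(2, 4), c(8), c(16), 1), L, 2, seed = 2)
  fit <- cardiolpm:::nn_train(m, X, S, Y, X, S, Y,
                              training_config(lr = 0.01, epochs = 200,
                                              batch = 16, patience = 200))
  pred <- cardiolpm:::nn_forward(fit$model, X, S)
  expect_lt(max(abs(pred - 0.37)), 0.05)
  # best-checkpoint contract: returned loss is the minimum logged loss
  expect_equal(fit$val_loss, min(fit$history))
})

test_that("estimator trains, predicts all labels, and bridges exactly", {
  ds <- small_dataset()
  est <- train_estimator(ds, tiny_spec(),
                         training_config(epochs = 8, batch = 16, seed = 1))
  pred <- predict_parameters(est, ds, rows = 1:5)
  expect_identical(colnames(pred),
                   c("Emax_LV", "Emax_RV", colnames(ds$labels)[-(1:2)]))
  expect_true(all(is.finite(pred)))
  # physics-bridge exactness: Emax output obeys the bridge given the
  # network-predicted Pes
  pes <- cardiolpm:::predict_pes(est, ds$q_lv[1:5, , drop = FALSE],
                                 ds$scalars[1:5, "T"],
                                 ds$scalars[1:5, "LV_EDV"],
                                 ds$scalars[1:5, "LV_ESV"], "lv")
  expect_equal(unname(pred[, "Emax_LV"]),
               unname(emax_bridge(pes, ds$scalars[1:5, "LV_ESV"], 5)))
  # teacher forcing bypasses networks A/B entirely
  emax_gt <- ds$labels[1:5, c("Emax_LV", "Emax_RV")]
  pred_tf <- predict_parameters(est, ds, rows = 1:5,
                                teacher_emax = emax_gt)
  expect_equal(pred_tf[, c("Emax_LV", "Emax_RV")], emax_gt)
  # patient assembly passes T and TBV through unchanged
  p <- predict_patient_parameters(est, ds, 3)
  expect_equal(p$T, unname(ds$scalars[3, "T"]))
  expect_equal(p$TBV, unname(ds$scalars[3, "TBV"]))
})

test_that("flat baseline predicts all eight parameters", {
  ds <- small_dataset()
  fb <- flat_baseline(ds, tiny_spec(),
                      training_config(epochs = 6, batch = 16, seed = 1))
  pred <- predict_flat(fb, ds, rows = 1:4)
  expect_identical(colnames(pred), colnames(ds$labels))
  expect_identical(dim(pred), c(4L, 8L))
})

test_that("training rejects non-finite loss with a diagnostic", {
  set.seed(1)
  B <- 16; L <- 8
  X <- array(rnorm(B * 2 * L), c(B, 2, L))
  X[1, 1, 1] <- NaN
  S <- matrix(rnorm(B * 2), B, 2)
  Y <- matrix(rnorm(B), B, 1)
  m <- build_network(network_spec(c(2, 4), c(8), c(8), 1), L, 2, seed = 2)
  expect_error(
    cardiolpm:::nn_train(m, X, S, Y, X, S, Y,
                         training_config(epochs = 5, batch = 16)),
    "diverged")
})
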