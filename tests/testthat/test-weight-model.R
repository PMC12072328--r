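test_that("the 80:20 split uses the floor convention and is reproducible", {
  sp <- split_dataset(278, 0.8, seed = 1)
  expect_length(sp$train, 222)
  expect_length(sp$validation, 56)
  expect_identical(sort(c(sp$train, sp$validation)), 1:278)

  sp2 <- split_dataset(10, 0.5, seed = 2)
  expect_length(sp2$train, 5)
  expect_length(sp2$validation, 5)
  expect_identical(sort(c(sp2$train, sp2$validation)), 1:10)

  expect_identical(split_dataset(50, 0.8, seed = 3),
                   split_dataset(50, 0.8, seed = 3))
  expect_error(split_dataset(1, 0.5), "at least 2")
  expect_error(split_dataset(10, 1.2), "\\(0, 1\\)")
})

test_that("the network fits an exact linear relation to under 1% of SD", {
  withr::with_seed(20, {
    x <- matrix(runif(200 * 21), 200, 21)
    y <- 40 + 25 * x[, 1]
  })
  # full-batch steps with the best-epoch restore off: the example checks
  # the optimizer's final training fit, not generalization
  cfg <- mlp_config(epochs = 300, patience = 300, dropout_rate = 0,
                    batch_size = 200, learning_rate = 0.003,
                    restore_best = FALSE, seed = 4)
  m <- mlp_train(x, y, cfg)
  tr <- m$report$split$train
  rmse <- sqrt(mean((predict(m, x[tr, ]) - y[tr])^2))
  expect_lt(rmse, 0.01 * sd(y))
})

test_that("constant targets are predicted to within 1e-3", {
  withr::with_seed(21, x <- matrix(runif(100 * 21), 100, 21))
  y <- rep(7.5, 100)
  m <- mlp_train(x, y, mlp_config(epochs = 300, patience = 300,
                                  dropout_rate = 0, batch_size = 100,
                                  learning_rate = 0.003,
                                  restore_best = FALSE, seed = 5))
  tr <- m$report$split$train
  expect_true(all(abs(predict(m, x[tr, ]) - 7.5) < 1e-3))
})

test_that("training is deterministic given the seed", {
  withr::with_seed(22, {
    x <- matrix(runif(80 * 21), 80, 21)
    y <- rowSums(x[, 1:3]) * 10
  })
  cfg <- mlp_config(epochs = 15, seed = 6)
  m1 <- mlp_train(x, y, cfg)
  m2 <- mlp_train(x, y, cfg)
  expect_identical(m1$report$val_loss, m2$report$val_loss)
  expect_identical(m1$params, m2$params)
})

test_that("early stopping restores the best-epoch weights", {
  withr::with_seed(23, {
    x <- matrix(runif(60 * 21), 60, 21)
    y <- 20 * x[, 2] + rnorm(60, 0, 2)
  })
  m <- mlp_train(x, y, mlp_config(epochs = 80, patience = 10, seed = 7))
  expect_equal(m$report$best_val_loss, min(m$report$val_loss),
               tolerance = 1e-9)
  # the stored parameters really are the best epoch's: re-evaluating the
  # validation loss reproduces the reported minimum
  sp <- m$report$split
  lva <- mean((predict(m, x[sp$validation, ]) - y[sp$validation])^2)
  expect_equal(lva, m$report$best_val_loss, tolerance = 1e-9)
})

test_that("inference is dropout-free and bit-deterministic", {
  withr::with_seed(24, {
    x <- matrix(runif(50 * 21), 50, 21)
    y <- 10 * x[, 1] + 5
  })
  m <- mlp_train(x, y, mlp_config(epochs = 10, seed = 8))
  p1 <- predict(m, x[1, ])
  p2 <- predict(m, x[1, ])
  expect_identical(p1, p2)
  expect_error(predict(m, x[1, 1:10]), "expected 21 features")
})

test_that("a hand-set tiny network matches the manual forward pass", {
  params <- list(W1 = matrix(c(1, 0, -1, 2), 2, 2), b1 = c(0.5, -0.5),
                 W2 = matrix(c(1, 1, 0, -1), 2, 2), b2 = c(0, 0.25),
                 W3 = matrix(c(2, -1), 2, 1), b3 = 0.1)
  m <- structure(list(params = params,
                      scaling = list(x_center = c(0, 0), x_scale = c(1, 1),
                                     y_center = 0, y_scale = 1),
                      feature_names = NULL,
                      config = mlp_config(hidden_units = c(2, 2))),
                 class = "mlp_model")
  x <- c(0.3, 0.7)
  h1 <- pmax(0, c(0.3 * 1 + 0.7 * 0 + 0.5, 0.3 * -1 + 0.7 * 2 - 0.5))
  h2 <- pmax(0, c(h1[1] + h1[2], h1[1] * 0 + h1[2] * -1 + 0.25))
  manual <- h2[1] * 2 + h2[2] * -1 + 0.1
  expect_equal(predict(m, x), manual, tolerance = 1e-12)

  # zero weights degenerate to the output bias (plus target centering)
  zero <- m
  zero$params <- lapply(params, function(p) p * 0)
  zero$params$b3 <- 3.3
  expect_equal(predict(zero, x), 3.3, tolerance = 1e-12)
})

test_that("checkpoints round-trip through JSON with full precision", {
  withr::with_seed(25, {
    x <- matrix(runif(50 * 21), 50, 21,
                dimnames = list(NULL, paste0("f", 1:21)))
    y <- 10 * x[, 1] + 60
  })
  m <- mlp_train(x, y, mlp_config(epochs = 5, seed = 9))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$feature_names, colnames(x))
  expect_equal(predict(m2, x), predict(m, x), tolerance = 1e-12)
  # schema is verified at predict time
  xbad <- x
  colnames(xbad) <- rev(colnames(x))
  expect_error(predict(m2, xbad), "schema")
})

test_that("training rejects degenerate inputs", {
  x <- matrix(1, 5, 21)
  expect_error(mlp_train(x, rep(1, 5)), "at least 10")
  x2 <- matrix(runif(20 * 21), 20, 21)
  expect_error(mlp_train(x2, rep(1, 19)), "length")
  x2[1, 1] <- NA
  expect_error(mlp_train(x2, rep(1, 20)), "finite")
})

test_that("height estimates round-trip to chart weights through the bands", {
  chart <- growth_chart()
  target_h <- median_height(chart, "male", 48)
  stub <- structure(list(
    params = list(W1 = matrix(0, 21, 2), b1 = c(0, 0),
                  W2 = matrix(0, 2, 2), b2 = c(0, 0),
                  W3 = matrix(0, 2, 1), b3 = 0),
    scaling = list(x_center = rep(0, 21), x_scale = rep(1, 21),
                   y_center = target_h, y_scale = 1),
    feature_names = NULL,
    config = mlp_config(hidden_units = c(2, 2))), class = "mlp_model")
  f <- frame_at()
  est <- estimate_weight(stub, f, "male", 48, "normal", chart)
  expect_equal(est$height_cm, target_h, tolerance = 1e-9)
  expect_equal(est$weight_kg,
               chart$weight_median_kg[chart$sex == "male" &
                                        chart$age_months == 48],
               tolerance = 1e-9)
  est_ow <- estimate_weight(stub, f, "male", 48, "overweight", chart)
  expect_gt(est_ow$weight_kg, est$weight_kg)

  # out-of-range prediction surfaces the raw value
  low <- stub
  low$scaling$y_center <- 20
  expect_error(estimate_weight(low, f, "male", 48, "normal", chart), "20")
})
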