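make_toy <- function(n_per_class = 20, len = 40, sep = 3, seed = 1) {
  ## two classes separated by a constant offset on lead II
  with_seed(seed, {
    n <- 2 * n_per_class
    x <- array(rnorm(12 * len * n), dim = c(12, len, n))
    y <- rep(c("a", "b"), each = n_per_class)
    x[2, , y == "b"] <- x[2, , y == "b"] + sep
    list(x = x * 1000, y = y)   # microvolt-scale amplitudes, as in real input
  })
}

test_that("the early-stopping rule is a pure function of the monitor trace", {
  ## strictly improving: runs to the cap, best = last
  r <- ecgmi:::stopping_epoch(seq(1, 0.1, length.out = 200), 20, 200)
  expect_equal(r$stop_epoch, 200L)
  expect_equal(r$best_epoch, 200L)
  ## frozen from the start: stops after `patience` non-improvements
  r <- ecgmi:::stopping_epoch(rep(1, 200), 20, 200)
  expect_equal(r$stop_epoch, 21L)
  expect_equal(r$best_epoch, 1L)
  ## improvement must be strict
  r <- ecgmi:::stopping_epoch(c(2, 1, 1, 1, 1, 1), 3, 200)
  expect_equal(r$stop_epoch, 5L)
  expect_equal(r$best_epoch, 2L)
  ## late improvement resets the wait counter
  r <- ecgmi:::stopping_epoch(c(3, 2, 2, 1.5, 2, 2, 2, 2), 4, 200)
  expect_equal(r$stop_epoch, 8L)
  expect_equal(r$best_epoch, 4L)
})

test_that("train_config validates its protocol arguments", {
  tc <- train_config()
  expect_equal(tc$learning_rate, 0.001)
  expect_equal(tc$batch_size, 300L)
  expect_equal(tc$max_epochs, 200L)
  expect_equal(tc$patience, 20L)
  expect_equal(tc$monitor, "train_loss")
  expect_error(train_config(patience = 200, max_epochs = 200))
  expect_error(train_config(batch_size = 0))
  expect_error(train_config(monitor = "magic"))
})

test_that("mi_net fits are deterministic under fixed seeds", {
  toy <- make_toy()
  cfg <- model_config(1, 2, 2, input_length = 40)
  tc <- train_config(batch_size = 10, max_epochs = 5, patience = 4)
  f1 <- mi_net(toy$x, toy$y, config = cfg, train = tc, seed = 3)
  f2 <- mi_net(toy$x, toy$y, config = cfg, train = tc, seed = 3)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$history, f2$history)
  f3 <- mi_net(toy$x, toy$y, config = cfg, train = tc, seed = 4)
  expect_false(identical(f1$weights$head$W, f3$weights$head$W))
})

test_that("mi_net learns an easily separable problem", {
  toy <- make_toy(sep = 4)
  cfg <- model_config(1, 2, 2, input_length = 40, dropout_rate = 0)
  tc <- train_config(batch_size = 8, max_epochs = 40, patience = 39)
  fit <- mi_net(toy$x, toy$y, config = cfg, train = tc, seed = 1)
  expect_s3_class(fit, "mi_net")
  expect_gte(fit$history$acc[fit$epochs_run], 0.9)
  ## training loss decreased substantially from its starting point
  expect_lt(min(fit$history$loss), 0.5 * fit$history$loss[1])
  pred <- predict(fit, toy$x, type = "class")
  expect_gte(mean(pred == toy$y), 0.9)
})

test_that("predict returns calibrated shapes for both types", {
  toy <- make_toy(n_per_class = 5)
  fit <- mi_net(toy$x, toy$y, config = model_config(1, 1, 2, input_length = 40),
                train = train_config(batch_size = 5, max_epochs = 2, patience = 1),
                seed = 2)
  p <- predict(fit, toy$x, type = "prob")
  expect_equal(dim(p), c(10L, 2L))
  expect_equal(colnames(p), c("a", "b"))
  expect_equal(rowSums(p), rep(1, 10))
  cl <- predict(fit, toy$x, type = "class")
  expect_true(all(cl %in% c("a", "b")))
  expect_equal(cl, c("a", "b")[max.col(p, ties.method = "first")])
})

test_that("the fit object supports the standard modelling verbs", {
  toy <- make_toy(n_per_class = 5)
  fit <- mi_net(toy$x, toy$y, config = model_config(1, 1, 2, input_length = 40),
                train = train_config(batch_size = 5, max_epochs = 2, patience = 1),
                seed = 2)
  expect_output(print(fit), "N-Net")
  expect_output(print(fit), "trainable parameters")
  expect_output(summary(fit), "Layer plan")
  w <- coef(fit)
  expect_equal(ecgmi:::n_weight_elements(w),
               count_parameters(model_config(1, 1, 2, input_length = 40)))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("mi_net accepts beat_set and ecg_bundle inputs", {
  det <- tiny_detection_bundle()
  tc <- train_config(batch_size = 50, max_epochs = 2, patience = 1)
  fit <- mi_net(det, config = model_config(1, 1, 2), train = tc, seed = 1)
  expect_equal(fit$classes, c("HC", "MI"))
  expect_equal(fit$n_train, 200L)
  p <- predict(fit, det$beats)
  expect_equal(dim(p), c(200L, 2L))
})

test_that("label and configuration mismatches are rejected", {
  toy <- make_toy(n_per_class = 5)
  expect_error(mi_net(toy$x, toy$y[-1],
                      config = model_config(1, 1, 2, input_length = 40)),
               "length")
  expect_error(mi_net(toy$x, toy$y,
                      config = model_config(1, 1, 6, input_length = 40)),
               "classes")
  expect_error(mi_net(array(0, dim = c(12, 40, 0)), character(0),
                      config = model_config(1, 1, 2, input_length = 40),
                      classes = c("a", "b")),
               "empty")
})

test_that("validation monitoring requires validation data and records it", {
  toy <- make_toy(n_per_class = 8)
  cfg <- model_config(1, 1, 2, input_length = 40)
  tc <- train_config(batch_size = 8, max_epochs = 3, patience = 2,
                     monitor = "val_loss")
  expect_error(mi_net(toy$x, toy$y, config = cfg, train = tc), "validation")
  val <- make_toy(n_per_class = 4, seed = 9)
  fit <- mi_net(toy$x, toy$y, config = cfg, train = tc, seed = 1,
                validation = list(x = val$x, y = val$y))
  expect_false(anyNA(fit$history$val_loss))
  expect_false(anyNA(fit$history$val_acc))
})

test_that("the shared order seed pairs runs across configurations", {
  toy <- make_toy()
  tc <- train_config(batch_size = 10, max_epochs = 2, patience = 1)
  f_small <- mi_net(toy$x, toy$y, config = model_config(1, 1, 2, input_length = 40),
                    train = tc, seed = 1, order_seed = 77)
  f_large <- mi_net(toy$x, toy$y, config = model_config(1, 3, 2, input_length = 40),
                    train = tc, seed = 1, order_seed = 77)
  expect_equal(f_small$order_seed, f_large$order_seed)
  ## and Adam state/epoch counters advance identically
  expect_equal(f_small$epochs_run, 2L)
  expect_equal(f_large$epochs_run, 2L)
})
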