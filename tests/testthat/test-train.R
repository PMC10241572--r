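test_that("the two-step learning-rate schedule follows the epoch boundary", {
  cfg <- train_config()
  expect_equal(learning_rate_at(1, cfg), 1e-4)
  expect_equal(learning_rate_at(30, cfg), 1e-4)
  expect_equal(learning_rate_at(31, cfg), 1e-5)
  # exhaustive trace over the full default budget
  rates <- learning_rate_at(1:200, cfg)
  expect_equal(rates, ifelse(1:200 <= 30, 1e-4, 1e-5))
  expect_error(learning_rate_at(0, cfg), "epoch")
  flat <- train_config(base_lr = 1e-3, reduced_lr = 1e-3)
  expect_equal(unique(learning_rate_at(1:50, flat)), 1e-3)
})

test_that("early stopping fires exactly when the window stops improving", {
  expect_false(early_stop_check(c(1.0, 0.9, 0.8), patience = 10))
  expect_true(early_stop_check(c(0.5, rep(0.51, 10)), patience = 10))
  expect_false(early_stop_check(seq(2, 0.1, length.out = 20), patience = 10))
  expect_error(early_stop_check(numeric(0), 5), "non-empty")
  # an improvement inside the window resets the clock
  expect_false(early_stop_check(c(0.5, rep(0.6, 9), 0.4), patience = 10))
  # trace a rigged history epoch by epoch: first stop at the hand-computed epoch
  losses <- c(1.0, 0.8, 0.9, 0.85, 0.95, 0.99)
  stops <- vapply(seq_along(losses), function(e)
    early_stop_check(losses[1:e], patience = 3), TRUE)
  expect_equal(which(stops)[1], 5)            # epochs 3-5 all above the 0.8 minimum
})

test_that("a rising validation loss with patience 1 stops at epoch 2", {
  # labels disagree between train and validation, so fitting the training
  # set strictly worsens the validation loss from the first epoch on
  d <- res <- 18
  x <- matrix(0.5, res * res * 3, 8)
  train <- list(x = x, y = rep(1, 8))
  val <- list(x = x, y = rep(0, 8))
  cfg <- train_config(max_epochs = 50, batch_size = 4, base_lr = 1e-2,
                      reduced_lr = 1e-2, early_stop_patience = 1, seed = 3,
                      resolution = res)
  fit <- train_classifier(reference_cnn(res, seed = 3), train, val, cfg)
  expect_equal(nrow(fit$history), 2L)
  expect_equal(fit$best_epoch, 1L)
})

test_that("training is reproducible under fixed seeds", {
  ds <- tiny_separable_set(n_per_class = 8, seed = 21)
  cfg <- train_config(max_epochs = 3, batch_size = 8, base_lr = 1e-3,
                      reduced_lr = 1e-3, seed = 17, resolution = 18)
  f1 <- train_classifier(reference_cnn(18, seed = 2), ds, ds, cfg)
  f2 <- train_classifier(reference_cnn(18, seed = 2), ds, ds, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$classifier$params, f2$classifier$params)
})

test_that("the reference CNN learns separable data", {
  set.seed(1)
  train <- tiny_separable_set(n_per_class = 24, seed = 5)
  val <- tiny_separable_set(n_per_class = 12, seed = 6)
  cfg <- train_config(max_epochs = 15, batch_size = 8, base_lr = 3e-3,
                      reduced_lr = 3e-3, early_stop_patience = 15, seed = 9,
                      resolution = 18)
  fit <- train_classifier(reference_cnn(18, seed = 4), train, val, cfg)
  h <- fit$history
  expect_lt(min(h$val_loss), h$val_loss[1])
  test <- tiny_separable_set(n_per_class = 12, seed = 7)
  s <- predict(fit, test)
  expect_true(all(s >= 0 & s <= 1))
  expect_gt(auc_mann_whitney(test$y, s), 0.8)
})

test_that("empty training or validation sets are refused", {
  ds <- tiny_separable_set(4, seed = 2)
  none <- list(x = ds$x[, 0], y = numeric(0))
  expect_error(train_classifier(reference_cnn(18), none, ds), "empty training")
  expect_error(train_classifier(reference_cnn(18), ds, none), "empty validation")
})

test_that("configuration invariants are enforced", {
  expect_error(train_config(base_lr = 1e-4, reduced_lr = 1e-3), "reduced_lr")
  expect_error(train_config(early_stop_patience = 0), "patience")
})
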