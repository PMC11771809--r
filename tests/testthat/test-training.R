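test_that("binary cross-entropy reproduces hand-computed values", {
  expect_equal(bce_loss(c(0.9, 0.2), c(1, 0), norm = 1),
               -0.5 * (log(0.9) + log(0.8)), tolerance = 1e-12)
  expect_equal(bce_loss(c(0.9, 0.2), c(1, 0), norm = 1), 0.16425,
               tolerance = 1e-4)
  expect_equal(bce_loss(rep(0.5, 8), rep(c(0, 1), 4), norm = 1), log(2))
  # perfect prediction collapses to (almost) zero under clamping
  expect_lt(bce_loss(c(1, 0, 1), c(1, 0, 1), norm = 1), 1e-6)
  # norm scales linearly
  expect_equal(bce_loss(c(0.7, 0.3), c(1, 0), norm = 3),
               3 * bce_loss(c(0.7, 0.3), c(1, 0), norm = 1))
  expect_error(bce_loss(c(0.5, 0.5), 1), "length")
})

test_that("mean squared error and its homogeneity", {
  expect_equal(mse_loss(c(1, 2), c(0, 2)), 0.5)
  expect_equal(mse_loss(matrix(1, 2, 2), matrix(1, 2, 2)), 0)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(mse_loss(3 * x, 3 * y), 9 * mse_loss(x, y))
})

test_that("total loss is the stated weighted sum and linear in each weight", {
  expect_equal(total_loss(0.3, 0.1, 0.7, loss_weights(1, 2, 0)), 0.5)
  expect_equal(total_loss(1, 1, 1, loss_weights(0, 0, 0)), 0)
  # finite-difference linearity in each weight
  base <- c(alpha = 1, beta = 1, gamma = 1)
  l <- c(0.4, 0.25, 0.6)
  for (wname in names(base)) {
    w1 <- as.list(base); w1[[wname]] <- base[[wname]] + 1
    d <- total_loss(l[1], l[2], l[3], do.call(loss_weights, w1)) -
      total_loss(l[1], l[2], l[3], do.call(loss_weights, as.list(base)))
    expect_equal(d, l[which(names(base) == wname)])
  }
})

test_that("resolution presets encode the optimization protocol", {
  sp <- train_presets("spot")
  expect_equal(sp$optimizer, "sgd")
  expect_equal(sp$lr, 0.01)
  sc <- train_presets("single_cell")
  expect_equal(sc$optimizer, "adam")
  expect_equal(sc$lr, 0.01)
  expect_equal(sc$max_epochs, 1000L)
  expect_equal(sc$plateau_patience, 10L)
  expect_equal(sc$plateau_factor, 0.05)
  expect_error(train_presets("bulk"))
})

test_that("plateau scheduler reaches lr0 * factor^2 after 21 flat epochs", {
  sched <- spatialcci:::make_plateau_scheduler_(0.01, patience = 10,
                                                factor = 0.05)
  for (e in 1:21) sched$observe(1.0)
  expect_equal(sched$lr(), 0.01 * 0.05^2)
  # improvement resets the patience counter
  sched2 <- spatialcci:::make_plateau_scheduler_(0.01, 10, 0.05)
  vals <- c(1, rep(1, 9), 0.9, rep(0.9, 9))   # improvement at epoch 11
  for (v in vals) sched2$observe(v)
  expect_equal(sched2$lr(), 0.01)
})

test_that("a single-epoch run produces a one-row history", {
  fx <- train_fixture(epochs = 1)
  tr <- train_model(fx$m, fx$x_e, fx$x_i, fx$s, fx$cfg)
  expect_equal(nrow(tr$history), 1)
  expect_equal(tr$best_epoch, 1)
  expect_error(train_config(max_epochs = 0), "max_epochs")
})

test_that("training reduces the loss over epochs", {
  fx <- train_fixture(epochs = 50)
  tr <- train_model(fx$m, fx$x_e, fx$x_i, fx$s, fx$cfg)
  expect_lt(tr$history$total[50], tr$history$total[1])
  expect_lt(tr$history$l_reg[50], tr$history$l_reg[1])
})

test_that("the returned checkpoint reproduces the best validation AUC", {
  fx <- train_fixture(epochs = 25)
  tr <- train_model(fx$m, fx$x_e, fx$x_i, fx$s, fx$cfg)
  expect_equal(tr$best_val_auc, max(tr$history$val_auc))
  rep <- evaluate_model(tr, fx$x_e, fx$x_i, fx$s$val_pos, fx$s$val_neg)
  expect_equal(rep$auc_roc, tr$best_val_auc, tolerance = 1e-12)
})

test_that("training is reproducible under fixed seeds", {
  fx <- train_fixture(epochs = 8)
  t1 <- train_model(fx$m, fx$x_e, fx$x_i, fx$s, fx$cfg)
  t2 <- train_model(fx$m, fx$x_e, fx$x_i, fx$s, fx$cfg)
  expect_equal(t1$history, t2$history, tolerance = 1e-6)
  expect_equal(t1$best_val_auc, t2$best_val_auc, tolerance = 1e-6)
})

test_that("ablation-mode training runs without image features", {
  fx <- train_fixture(epochs = 5, use_image = FALSE)
  w <- loss_weights(gamma = 0)
  tr <- train_model(fx$m, fx$x_e, NULL, fx$s, fx$cfg, w)
  expect_true(all(tr$history$l_feature == 0))
  expect_true(is.finite(tr$best_val_auc))
})

test_that("SGD optimization also reduces the loss", {
  fx <- train_fixture(epochs = 30)
  cfg <- train_presets("spot", max_epochs = 30, seed = 0)
  expect_equal(cfg$optimizer, "sgd")
  tr <- train_model(fx$m, fx$x_e, fx$x_i, fx$s, cfg)
  expect_lt(tr$history$total[30], tr$history$total[1])
})
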