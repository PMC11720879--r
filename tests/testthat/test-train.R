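sp <- asNamespace("sparsepat")

test_that("k-fold assignment partitions the samples reproducibly", {
  f <- kfold_split(100, 10, seed = 1)
  expect_length(f, 10)
  expect_true(all(lengths(f) == 10))
  expect_setequal(unlist(f), 1:100)
  expect_identical(f, kfold_split(100, 10, seed = 1))
  expect_false(identical(f, kfold_split(100, 10, seed = 2)))
  expect_error(kfold_split(5, 10), "fewer samples")
  expect_error(train_config(k_folds = 1), "k_folds")
})

test_that("training records a full history and reduces the loss", {
  set.seed(61)
  n <- 6
  targets <- array(runif(128 * 128 * n, 0, 0.2), c(128, 128, n))
  inputs <- pmin(pmax(targets + array(rnorm(128 * 128 * n, 0, 0.1),
                                      c(128, 128, n)), 0), 1)
  m <- build_msdnet(msdnet_config_small(20, seed = 2))
  cfg <- train_config(learning_rate = 1e-3, batch_size = 4, epochs = 2, seed = 3)
  fit <- train_network(m, inputs, targets, cfg,
                       val_inputs = inputs[, , 1:2], val_targets = targets[, , 1:2])
  expect_s3_class(fit, "msdnet_fit")
  # history length = epochs x steps-per-epoch
  expect_length(fit$step_loss, 2 * ceiling(n / 4))
  expect_true(all(fit$step_loss > 0))
  expect_equal(nrow(fit$epochs), 2)
  expect_false(any(is.na(fit$epochs$val_ssim)))
  expect_lt(fit$epochs$train_loss[2], fit$epochs$train_loss[1])
  expect_error(train_network(m, array(0, c(128, 128, 0)),
                             array(0, c(128, 128, 0)), cfg), "empty")
})

test_that("k-fold training tracks the best validation checkpoint", {
  set.seed(62)
  n <- 6
  targets <- array(runif(128 * 128 * n, 0, 0.2), c(128, 128, n))
  inputs <- targets
  builder <- function() build_msdnet(msdnet_config_small(20, seed = 5))
  cv <- kfold_train(list(inputs = inputs, targets = targets), builder,
                    train_config(learning_rate = 1e-3, batch_size = 4,
                                 epochs = 1, k_folds = 3, seed = 6))
  expect_s3_class(cv, "pat_cv")
  expect_length(cv$folds, 3)
  expect_true(cv$best$fold %in% 1:3)
  expect_gt(cv$best$val_ssim, -Inf)
  expect_s3_class(cv$best$model, "msdnet")
  # the restored best model reproduces the recorded validation SSIM family
  expect_true(is.finite(mean(predict(cv$best$model, inputs[, , 1]))))
})
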