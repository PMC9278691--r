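make_pairs <- function(n_pairs, grid, seed, target = NULL) {
  set.seed(seed)
  lapply(seq_len(n_pairs), function(i) {
    x <- matrix(runif(grid^3 * 12), grid^3, 12)
    attr(x, "dims") <- c(grid, grid, grid)
    y <- if (is.null(target)) runif(grid^3) else rep(target, grid^3)
    list(x = x, y = y)
  })
}

test_that("mse loss matches its closed form and a naive summation loop", {
  a <- array(runif(4^3), dim = c(4, 4, 4))
  expect_equal(mse_loss(a, a), 0)
  expect_equal(mse_loss(a, a + 0.5), 0.25)
  b <- array(runif(4^3), dim = c(4, 4, 4))
  acc <- 0
  for (i in seq_along(a)) acc <- acc + (a[i] - b[i])^2
  expect_equal(mse_loss(a, b), acc / length(a), tolerance = 1e-12)
  # invariant under a common voxel permutation
  p <- sample(length(a))
  expect_equal(mse_loss(a[p], b[p]), mse_loss(a, b))
  expect_error(mse_loss(a, array(0, dim = c(4, 4, 2))), "mismatch")
})

test_that("one small Adam step on a fixed batch decreases its loss", {
  pairs <- make_pairs(1, 8, seed = 1)
  net <- build_attention_unet(model_config(n_levels = 3), seed = 2)
  before <- mse_loss(kbpdose:::unet_forward(net, pairs[[1]]$x,
                                            c(8, 8, 8))$out[, 1],
                     pairs[[1]]$y)
  ctl <- train_control(epochs = 1, batch_size = 1, learning_rate = 1e-4,
                       patience = Inf, warmup_steps = 0, seed = 3)
  fit <- train_network(net, pairs, val = NULL, control = ctl)
  after <- mse_loss(kbpdose:::unet_forward(fit, pairs[[1]]$x,
                                           c(8, 8, 8))$out[, 1],
                    pairs[[1]]$y)
  expect_lt(after, before)
})

test_that("early stopping halts after patience+1 epochs of no improvement", {
  # train and validation pairs share the input but carry opposite-sign
  # targets: every step toward the training target moves the prediction
  # away from the validation target, so validation loss worsens from
  # epoch 1 onward
  set.seed(5)
  x <- matrix(runif(16^3 * 12), 16^3, 12)
  attr(x, "dims") <- c(16, 16, 16)
  train <- list(list(x = x, y = rep(0.8, 16^3)))
  val <- list(list(x = x, y = rep(-0.8, 16^3)))
  net <- build_attention_unet(model_config(), seed = 4)
  ctl <- train_control(epochs = 50, batch_size = 1, patience = 3,
                       learning_rate = 1e-4, warmup_steps = 0, seed = 5)
  fit <- train_network(net, train, val, ctl)
  expect_equal(fit$epochs_run, 4)  # patience + 1
  expect_equal(fit$best_epoch, 1)
  expect_true(all(diff(fit$curve$val_loss) > 0))
})

test_that("checkpoint-on-best restores the best-validation weights", {
  set.seed(6)
  x <- matrix(runif(16^3 * 12), 16^3, 12)
  attr(x, "dims") <- c(16, 16, 16)
  train <- list(list(x = x, y = rep(0.8, 16^3)))
  val <- list(list(x = x, y = rep(-0.8, 16^3)))
  net <- build_attention_unet(model_config(), seed = 6)
  fit <- train_network(net, train, val,
                       train_control(epochs = 50, batch_size = 1,
                                     patience = 2, learning_rate = 1e-4,
                                     warmup_steps = 0, seed = 6))
  expect_equal(fit$best_epoch, which.min(fit$curve$val_loss))
  # restored weights reproduce the recorded best validation loss
  reval <- mse_loss(kbpdose:::unet_forward(fit, x, c(16, 16, 16))$out[, 1],
                    val[[1]]$y)
  expect_equal(reval, min(fit$curve$val_loss), tolerance = 1e-6)
})

test_that("training is deterministic given data, config and seed", {
  pairs <- make_pairs(2, 16, seed = 9)
  ctl <- train_control(epochs = 3, batch_size = 2, patience = Inf, seed = 11)
  f1 <- train_network(build_attention_unet(model_config(), seed = 8),
                      pairs, pairs[1], ctl)
  f2 <- train_network(build_attention_unet(model_config(), seed = 8),
                      pairs, pairs[1], ctl)
  expect_identical(f1$curve, f2$curve)
  expect_identical(f1$params$final$W, f2$params$final$W)
})

test_that("training rejects empty cohorts", {
  net <- build_attention_unet(model_config(n_levels = 3), seed = 1)
  expect_error(train_network(net, list(), NULL, train_control()), "empty")
  expect_error(train_network(net, make_pairs(1, 8, 1), list(),
                             train_control()), "empty")
})

test_that("prediction returns Gy on the input grid with clipped negatives", {
  s <- generate_phantom(tiny_phantom_config(32), seed = 3)
  net <- build_attention_unet(model_config(), seed = 3)
  pred <- predict(net, s, prescription = 70, out_size = 32)
  expect_equal(dim(pred), c(32, 32, 32))
  expect_true(all(pred >= 0))
  # rescaling contract: Gy = prescription x normalized, then clipped
  pp <- prepare_pair(s, 32)
  norm_pred <- predict(net, pp$x, normalized = TRUE)
  expect_equal(pred, pmax(norm_pred * 70, 0), tolerance = 1e-9)
  # zero final layer -> identically zero dose
  net0 <- net
  net0$params$final$W[] <- 0
  net0$params$final$b[] <- 0
  expect_true(all(predict(net0, pp$x) == 0))
})
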