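# Neural-network engine: FNN and CNN training contracts.

test_that("FNN training protocol defaults to 200 epochs at batch size 128", {
  cfg <- fnn_config()
  expect_identical(cfg$epochs, 200L)
  expect_identical(cfg$batch_size, 128L)
  expect_equal(cfg$dropout, 0.5)
  expect_equal(cfg$batchnorm_momentum, 0.99)
  expect_identical(cfg$activation, "relu")
  expect_error(fnn_config(dropout = 1), "dropout")
})

memorizable <- function(n = 100, d = 8, seed = 71) {
  set.seed(seed)
  x <- matrix(rnorm(n * d), n, d)
  y <- as.integer(x[, 1] + 0.5 * x[, 2] > 0)
  list(x = x, y = y)
}

test_that("FNN fits a memorizable set: loss falls well below its starting value", {
  m <- memorizable()
  # dropout off: this is a pure capacity check on a memorizable set; small
  # batches give batch-norm running statistics enough steps to converge
  cfg <- fnn_config(hidden_layers = c(16L, 8L), loss = "binary_ce",
                    dropout = 0, epochs = 200L, batch_size = 10L, seed = 3)
  fit <- train_fnn(cfg, m$x, m$y, m$x, m$y)
  expect_identical(nrow(fit$history), 200L)
  expect_lt(fit$history$loss[200], fit$history$loss[1] / 3)
  expect_gt(fit$history$val_f1[200], 0.9)
})

test_that("FNN training is seed-deterministic down to the weights", {
  m <- memorizable()
  cfg <- fnn_config(hidden_layers = c(8L), loss = "binary_ce",
                    epochs = 5L, batch_size = 32L, seed = 11)
  f1 <- train_fnn(cfg, m$x, m$y)
  f2 <- train_fnn(cfg, m$x, m$y)
  expect_identical(f1$net, f2$net)
  cfg2 <- cfg; cfg2$seed <- 12L
  f3 <- train_fnn(cfg2, m$x, m$y)
  expect_false(identical(f1$net, f3$net))
})

test_that("predictions are calibrated scores with threshold semantics", {
  m <- memorizable()
  cfg <- fnn_config(hidden_layers = c(16L), loss = "binary_ce",
                    dropout = 0, epochs = 150L, batch_size = 10L, seed = 5)
  fit <- train_fnn(cfg, m$x, m$y)
  pr <- predict(fit, m$x, type = "prob")
  expect_true(all(pr >= 0 & pr <= 1))
  expect_equal(rowSums(pr), rep(1, nrow(pr)))
  # a well-fit toy model reproduces nearly all its training labels (exact
  # identity is not guaranteed: inference uses batch-norm running stats)
  expect_gte(mean(predict(fit, m$x) == m$y), 0.95)
  # threshold 0 labels everything positive
  expect_true(all(predict(fit, m$x, threshold = 0) == 1L))

  # categorical head: softmax rows sum to 1
  y3 <- (m$y + as.integer(m$x[, 3] > 1)) %% 3L
  cfg3 <- fnn_config(hidden_layers = c(16L), loss = "categorical_ce",
                     epochs = 10L, batch_size = 25L, seed = 6)
  fit3 <- train_fnn(cfg3, m$x, y3)
  pr3 <- predict(fit3, m$x, type = "prob")
  expect_identical(ncol(pr3), 3L)
  expect_equal(rowSums(pr3), rep(1, nrow(pr3)))
})

test_that("FNN rejects degenerate inputs", {
  m <- memorizable()
  expect_error(train_fnn(fnn_config(), m$x, rep(0L, nrow(m$x))),
               "single class")
  expect_error(train_fnn(fnn_config(loss = "binary_ce"), m$x,
                         (seq_len(nrow(m$x)) %% 3L)),
               "2 classes")
})

test_that("training curves export as long-format CSV", {
  m <- memorizable()
  fit <- train_fnn(fnn_config(hidden_layers = 8L, loss = "binary_ce",
                              epochs = 3L, seed = 1),
                   m$x, m$y, m$x, m$y)
  path <- tempfile(fileext = ".csv")
  write_training_curves(fit, path)
  curves <- read.csv(path)
  expect_setequal(unique(curves$split), c("train", "validation"))
  expect_identical(nrow(curves), 9L)   # 3 epochs x 3 series
})

# --- CNN -------------------------------------------------------------------

tiny_onehot <- function(n = 40, len = 100, seed = 81) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  seqs <- vapply(seq_len(n), function(i) {
    gc <- if (y[i] == 1) 0.7 else 0.3
    paste(sample(c("A", "T", "G", "C"), len, TRUE,
                 prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
          collapse = "")
  }, character(1))
  list(X = one_hot(seqs), y = y)
}

test_that("CNN architecture defaults follow the three-stage design", {
  cfg <- cnn_config()
  expect_identical(cfg$conv_filters, c(64L, 32L, 32L))
  expect_equal(cfg$spatial_dropout, 0.2)
  expect_equal(cfg$head_dropout, 0.2)
  expect_identical(cfg$subsample_per_class, 15000L)
})

test_that("balanced subsample draws exactly per_class from each class", {
  labels <- rep(c(0, 1), times = c(300, 40))
  idx <- balanced_subsample(labels, 30, seed = 2)
  expect_identical(as.integer(table(labels[idx])), c(30L, 30L))
  expect_identical(balanced_subsample(labels, 30, seed = 2), idx)
  expect_error(balanced_subsample(labels, 50, seed = 2), "cannot supply")
})

test_that("CNN trains on one-hot tensors and learns a composition signal", {
  d <- tiny_onehot()
  cfg <- cnn_config(conv_filters = c(8L, 4L, 4L), kernel_sizes = c(5L, 3L, 3L),
                    head_hidden = 8L, epochs = 25L, batch_size = 10L,
                    batchnorm_momentum = 0.9,   # few steps at this tiny scale
                    seed = 9, subsample_per_class = 20L)
  fit <- train_cnn(cfg, d$X, d$y, d$X, d$y)
  expect_identical(fit$kind, "cnn")
  expect_lt(fit$history$loss[25], fit$history$loss[1])
  expect_gt(fit$history$val_f1[25], 0.7)
  # predict path: raw sequences are one-hot encoded and padded to fit
  p <- predict(fit, d$X[, , 1:5], type = "prob")
  expect_identical(dim(p), c(5L, 2L))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("CNN rejects feature maps narrower than the first kernel", {
  d <- tiny_onehot(n = 12, len = 3)
  cfg <- cnn_config(conv_filters = c(4L, 2L, 2L), epochs = 1L,
                    subsample_per_class = 6L)
  expect_error(train_cnn(cfg, d$X, d$y), "smaller than the first kernel")
})

test_that("CNN training is seed-deterministic", {
  d <- tiny_onehot(n = 20)
  cfg <- cnn_config(conv_filters = c(4L, 2L, 2L), head_hidden = 4L,
                    epochs = 2L, batch_size = 10L, seed = 13,
                    subsample_per_class = 10L)
  f1 <- train_cnn(cfg, d$X, d$y)
  f2 <- train_cnn(cfg, d$X, d$y)
  expect_identical(f1$net, f2$net)
})
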