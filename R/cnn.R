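#' Convolutional network configuration
#'
#' A TERL-style architecture over one-hot DNA: three convolutional stages
#' with 64, 32 and 32 filters (kernel widths 5, 3, 3 across positions; the
#' first stage consumes all 5 alphabet rows as input channels), each stage
#' followed by ReLU, batch normalization, spatial dropout 0.2 and average
#' pooling; then a dense head with dropout 0.2 and a sigmoid output for the
#' two-label problem. Training at full scale first draws a balanced
#' subsample (the reference protocol uses 15,000 records per class).
#'
#' @param conv_filters Filter counts for the three stages.
#' @param kernel_sizes Kernel widths along the position axis, one per
#'   stage.
#' @param spatial_dropout Per-channel dropout fraction after each stage.
#' @param pool_size Average-pooling window (and stride).
#' @param head_hidden Dense-head hidden widths.
#' @param head_dropout Dense-head dropout fraction.
#' @param batchnorm_momentum Running-statistics momentum of every
#'   batch-normalization stage.
#' @param loss `"binary_ce"` (the two-label problem) or
#'   `"categorical_ce"`.
#' @param epochs,batch_size,learning_rate,seed As in [fnn_config()].
#' @param subsample_per_class Balanced subsample size per class drawn
#'   before training (`Inf` to use all records).
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(conv_filters = c(64L, 32L, 32L),
                       kernel_sizes = c(5L, 3L, 3L),
                       spatial_dropout = 0.2, pool_size = 2L,
                       head_hidden = c(64L), head_dropout = 0.2,
                       batchnorm_momentum = 0.99,
                       loss = c("binary_ce", "categorical_ce"),
                       epochs = 200L, batch_size = 128L,
                       learning_rate = 1e-3, seed = 1L,
                       subsample_per_class = 15000L) {
  loss <- match.arg(loss)
  stopifnot(length(conv_filters) == 3L,
            length(kernel_sizes) == length(conv_filters),
            spatial_dropout >= 0, spatial_dropout < 1,
            head_dropout >= 0, head_dropout < 1)
  structure(list(conv_filters = as.integer(conv_filters),
                 kernel_sizes = as.integer(kernel_sizes),
                 spatial_dropout = spatial_dropout,
                 pool_size = as.integer(pool_size),
                 head_hidden = as.integer(head_hidden),
                 head_dropout = head_dropout,
                 batchnorm_momentum = batchnorm_momentum, loss = loss,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 subsample_per_class = subsample_per_class),
            class = "cnn_config")
}

#' Balanced subsample of record indices
#'
#' Draws exactly `per_class` indices from each class (without replacement),
#' seed-deterministic.
#'
#' @param labels Label vector.
#' @param per_class Records to draw per class.
#' @param seed Integer seed.
#' @return Integer index vector.
#' @export
balanced_subsample <- function(labels, per_class, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  idx <- unlist(lapply(split(seq_along(labels), labels), function(g) {
    if (length(g) < per_class)
      stop("class with ", length(g), " records cannot supply ", per_class)
    sample(g, per_class)
  }), use.names = FALSE)
  sort(idx)
}

# convert a 5 x m x n one-hot tensor into the engine's per-sample list of
# m x 5 matrices, padding/truncating to width `m_target` if given
tensor_to_samples <- function(X, m_target = NULL) {
  stopifnot(length(dim(X)) == 3L)
  m <- dim(X)[2L]
  out <- lapply(seq_len(dim(X)[3L]), function(i) t(X[, , i]))
  if (!is.null(m_target) && m_target != m) {
    out <- lapply(out, function(M) {
      if (nrow(M) >= m_target) M[seq_len(m_target), , drop = FALSE]
      else rbind(M, matrix(0, m_target - nrow(M), ncol(M)))
    })
  }
  out
}

build_cnn_net <- function(m, n_out, config) {
  if (m < config$kernel_sizes[1L])
    stop("sequence width m = ", m, " is smaller than the first kernel (",
         config$kernel_sizes[1L], ")")
  net <- list()
  c_in <- 5L
  len <- m
  for (s in seq_along(config$conv_filters)) {
    kw <- config$kernel_sizes[s]
    if (len < kw) stop("feature map shrank below kernel width at stage ", s)
    net <- c(net, list(nn_conv(c_in, config$conv_filters[s], kw),
                       nn_act("relu"),
                       nn_bn(config$conv_filters[s],
                             momentum = config$batchnorm_momentum),
                       nn_spatialdrop(config$spatial_dropout),
                       nn_pool(config$pool_size)))
    len <- (len - kw + 1L) %/% config$pool_size
    c_in <- config$conv_filters[s]
    if (len < 1L) stop("feature map vanished at stage ", s)
  }
  net <- c(net, list(nn_flatten()))
  d <- len * c_in
  for (w in config$head_hidden) {
    net <- c(net, list(nn_dense(d, w), nn_act("relu")))
    if (config$head_dropout > 0)
      net <- c(net, list(nn_dropout(config$head_dropout)))
    d <- w
  }
  c(net, list(nn_dense(d, n_out)))
}

#' Train the convolutional network
#'
#' Draws a balanced subsample (per `config$subsample_per_class`), builds
#' the three-stage convolutional network for the training tensor's width,
#' and trains with Adam, recording per-epoch curves as [train_fnn()] does.
#'
#' @param config A [cnn_config()].
#' @param x_train A `5 x m x n` one-hot array (see [one_hot()]).
#' @param y_train Label vector of length n.
#' @param x_val,y_val Optional validation tensor and labels.
#' @param verbose Print a progress line every 5 epochs.
#' @return A `trained_model` of kind `"cnn"`.
#' @export
train_cnn <- function(config, x_train, y_train,
                      x_val = NULL, y_val = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "cnn_config"), length(dim(x_train)) == 3L,
            dim(x_train)[3L] == length(y_train))
  per <- min(config$subsample_per_class, min(table(y_train)))
  keep <- balanced_subsample(y_train, per, seed = config$seed)
  x_train <- x_train[, , keep, drop = FALSE]
  y_train <- y_train[keep]
  classes <- sort(unique(y_train))
  n_out <- if (config$loss == "binary_ce") 1L else length(classes)
  m <- dim(x_train)[2L]

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  net <- build_cnn_net(m, n_out, config)
  state <- adam_init(net)
  loss_fn <- if (config$loss == "binary_ce") loss_binary_ce
             else loss_categorical_ce
  samples <- tensor_to_samples(x_train)
  y_mat <- encode_targets(y_train, classes, config$loss)
  val_samples <- if (!is.null(x_val)) tensor_to_samples(x_val, m) else NULL
  n <- length(samples)
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     val_loss = numeric(0), val_f1 = numeric(0))
  t_step <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_n <- 0L
    for (bs in seq(1L, n, by = config$batch_size)) {
      idx <- ord[bs:min(bs + config$batch_size - 1L, n)]
      fw <- net_forward(net, samples[idx], training = TRUE)
      net <- fw$net
      l <- loss_fn(fw$out, y_mat[idx, , drop = FALSE])
      grads <- net_backward(net, fw$caches, l$dz)
      t_step <- t_step + 1L
      up <- adam_step(net, grads, state, config$learning_rate, t_step)
      net <- up$net; state <- up$state
      ep_loss <- ep_loss + l$loss * length(idx); ep_n <- ep_n + length(idx)
    }
    val_loss <- NA_real_; val_f1 <- NA_real_
    if (!is.null(val_samples)) {
      ev <- nn_evaluate(net, val_samples, y_val, classes, config$loss,
                        loss_fn)
      val_loss <- ev$loss; val_f1 <- ev$f1
    }
    hist <- rbind(hist, data.frame(epoch = epoch, loss = ep_loss / ep_n,
                                   val_loss = val_loss, val_f1 = val_f1))
    if (verbose && epoch %% 5L == 0L)
      message(sprintf("epoch %d  loss %.4f  val_f1 %.4f", epoch,
                      ep_loss / ep_n, val_f1))
  }
  structure(list(kind = "cnn", net = net, config = config,
                 classes = classes,
                 preprocessing = list(onehot_width = m),
                 history = hist, seed = config$seed),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> kind=%s  classes=%s  epochs=%d\n",
              x$kind, paste(x$classes, collapse = ","),
              nrow(x$history)))
  invisible(x)
}
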