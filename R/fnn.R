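#' Fully connected network configuration
#'
#' Defaults follow the reference training protocol: 200 epochs at batch
#' size 128, dropout 0.5 and batch-normalization momentum 0.99 in the
#' hidden layers, ReLU activations, Adam at 1e-3. The loss selects the
#' output head: `"categorical_ce"` (softmax over the classes) or
#' `"binary_ce"` (single sigmoid unit).
#'
#' @param hidden_layers Integer vector of hidden widths.
#' @param activation `"relu"`, `"sigmoid"` or `"tanh"`.
#' @param dropout Hidden-layer dropout fraction in `[0, 1)`.
#' @param batchnorm_momentum Running-statistics momentum in `[0, 1)`.
#' @param loss `"categorical_ce"` or `"binary_ce"`.
#' @param epochs Training epochs (>= 1).
#' @param batch_size Minibatch size.
#' @param learning_rate Adam learning rate.
#' @param weight_decay L2 penalty on the dense weights (0 disables).
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @return An object of class `fnn_config`.
#' @export
fnn_config <- function(hidden_layers = c(256L, 128L, 64L),
                       activation = c("relu", "sigmoid", "tanh"),
                       dropout = 0.5, batchnorm_momentum = 0.99,
                       loss = c("categorical_ce", "binary_ce"),
                       epochs = 200L, batch_size = 128L,
                       learning_rate = 1e-3, weight_decay = 0,
                       seed = 1L) {
  activation <- match.arg(activation)
  loss <- match.arg(loss)
  stopifnot(dropout >= 0, dropout < 1, epochs >= 1, batch_size >= 1,
            all(hidden_layers >= 1))
  structure(list(hidden_layers = as.integer(hidden_layers),
                 activation = activation, dropout = dropout,
                 batchnorm_momentum = batchnorm_momentum, loss = loss,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "fnn_config")
}

build_fnn_net <- function(d_in, n_out, config) {
  net <- list()
  d <- d_in
  for (w in config$hidden_layers) {
    net <- c(net, list(nn_dense(d, w),
                       nn_bn(w, momentum = config$batchnorm_momentum),
                       nn_act(config$activation)))
    if (config$dropout > 0)
      net <- c(net, list(nn_dropout(config$dropout)))
    d <- w
  }
  c(net, list(nn_dense(d, n_out)))
}

# labels -> training targets; classes is the sorted label universe
encode_targets <- function(labels, classes, loss) {
  idx <- match(labels, classes)
  if (anyNA(idx)) stop("labels outside the training class set")
  if (loss == "binary_ce") {
    if (length(classes) != 2L)
      stop("binary cross entropy requires exactly 2 classes")
    matrix(as.numeric(idx == 2L), ncol = 1L)
  } else {
    y <- matrix(0, length(idx), length(classes))
    y[cbind(seq_along(idx), idx)] <- 1
    y
  }
}

#' Train a fully connected network
#'
#' Trains for exactly `config$epochs` epochs at `config$batch_size`,
#' recording per-epoch training loss, validation loss and validation F1
#' (weighted F1 for the multiclass head, positive-class F1 for the binary
#' head). Deterministic given the config seed.
#'
#' @param config An [fnn_config()].
#' @param x_train,x_val Numeric feature matrices (e.g. PCA-reduced k-mer
#'   spectra).
#' @param y_train,y_val Label vectors.
#' @param preprocessing Optional list (e.g. `kmer_config`, `scaler`, `pca`)
#'   bound to the model so that [predict.trained_model()] can start from
#'   raw sequences.
#' @param verbose Print a progress line every 25 epochs.
#' @return An object of class `trained_model` with the fitted network,
#'   class universe, training history and bound preprocessing.
#' @export
train_fnn <- function(config, x_train, y_train,
                      x_val = NULL, y_val = NULL,
                      preprocessing = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "fnn_config"), is.matrix(x_train),
            nrow(x_train) == length(y_train))
  classes <- sort(unique(y_train))
  if (length(classes) < 2L) stop("training data contains a single class")
  n_out <- if (config$loss == "binary_ce") 1L else length(classes)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  net <- build_fnn_net(ncol(x_train), n_out, config)
  state <- adam_init(net)
  loss_fn <- if (config$loss == "binary_ce") loss_binary_ce
             else loss_categorical_ce
  y_mat <- encode_targets(y_train, classes, config$loss)
  n <- nrow(x_train)
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     val_loss = numeric(0), val_f1 = numeric(0))
  t_step <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batch_starts <- seq(1L, n, by = config$batch_size)
    ep_loss <- 0; ep_n <- 0L
    for (bs in batch_starts) {
      idx <- ord[bs:min(bs + config$batch_size - 1L, n)]
      fw <- net_forward(net, x_train[idx, , drop = FALSE], training = TRUE)
      net <- fw$net
      l <- loss_fn(fw$out, y_mat[idx, , drop = FALSE])
      grads <- net_backward(net, fw$caches, l$dz)
      if (config$weight_decay > 0)
        grads <- add_weight_decay(net, grads, config$weight_decay)
      t_step <- t_step + 1L
      up <- adam_step(net, grads, state, config$learning_rate, t_step)
      net <- up$net; state <- up$state
      ep_loss <- ep_loss + l$loss * length(idx); ep_n <- ep_n + length(idx)
    }
    val_loss <- NA_real_; val_f1 <- NA_real_
    if (!is.null(x_val)) {
      ev <- nn_evaluate(net, x_val, y_val, classes, config$loss, loss_fn)
      val_loss <- ev$loss; val_f1 <- ev$f1
    }
    hist <- rbind(hist, data.frame(epoch = epoch, loss = ep_loss / ep_n,
                                   val_loss = val_loss, val_f1 = val_f1))
    if (verbose && epoch %% 25L == 0L)
      message(sprintf("epoch %d  loss %.4f  val_f1 %.4f", epoch,
                      ep_loss / ep_n, val_f1))
  }
  structure(list(kind = "fnn", net = net, config = config,
                 classes = classes, preprocessing = preprocessing,
                 history = hist, seed = config$seed),
            class = "trained_model")
}

nn_evaluate <- function(net, x, y, classes, loss, loss_fn) {
  fw <- net_forward(net, x, training = FALSE)
  y_mat <- encode_targets(y, classes, loss)
  l <- loss_fn(fw$out, y_mat)
  if (loss == "binary_ce") {
    pred <- classes[1L + as.integer(l$probs[, 1L] >= 0.5)]
    cm <- confusion_matrix(y, pred, levels = classes)
    f1 <- binary_metrics(tn = cm[1, 1], fp = cm[1, 2],
                         fn = cm[2, 1], tp = cm[2, 2])$f1
  } else {
    pred <- classes[max.col(l$probs, ties.method = "first")]
    f1 <- multiclass_metrics(confusion_matrix(y, pred, levels = classes))$f1
  }
  list(loss = l$loss, f1 = f1)
}

#' Predict with a trained model
#'
#' Applies the model's bound preprocessing (k-mer featurization, scaler,
#' PCA — for FNN/classical models; one-hot encoding for the CNN) and runs
#' the network. Raw sequences, raw feature matrices or already-reduced
#' matrices are accepted; preprocessing stages are applied as needed based
#' on input width.
#'
#' @param object A `trained_model`.
#' @param newdata A [Biostrings::DNAStringSet], character vector of
#'   sequences, or numeric feature matrix.
#' @param type `"class"` (default), `"prob"`, or `"both"`.
#' @param threshold Binary decision threshold on the positive-class score
#'   (default 0.5; a label is positive when score >= threshold).
#' @param ... Unused.
#' @return Labels, a score matrix, or a list with both.
#' @export
predict.trained_model <- function(object, newdata,
                                  type = c("class", "prob", "both"),
                                  threshold = 0.5, ...) {
  type <- match.arg(type)
  if (is.null(object$net) && is.null(object$fit))
    stop("model has not been trained")
  x <- prepare_features(object, newdata)
  if (object$kind == "cnn") {
    fw <- net_forward(object$net, x, training = FALSE)
  } else {
    fw <- net_forward(object$net, x, training = FALSE)
  }
  z <- fw$out
  if (object$config$loss == "binary_ce") {
    score <- 1 / (1 + exp(-z[, 1L]))
    probs <- cbind(1 - score, score)
    colnames(probs) <- as.character(object$classes)
    labels <- object$classes[1L + as.integer(score >= threshold)]
  } else {
    probs <- softmax_probs(z)
    colnames(probs) <- as.character(object$classes)
    labels <- object$classes[max.col(probs, ties.method = "first")]
  }
  switch(type, class = labels, prob = probs,
         both = list(class = labels, prob = probs))
}

# featurize/reduce `newdata` according to the model's bound preprocessing
prepare_features <- function(model, newdata) {
  pp <- model$preprocessing
  if (model$kind == "cnn") {
    if (is.matrix(newdata) || is.array(newdata) && length(dim(newdata)) == 3L) {
      X <- if (length(dim(newdata)) == 3L) newdata else stop("CNN expects sequences or a 5 x m x n array")
    } else {
      X <- one_hot(newdata)
    }
    m_train <- pp$onehot_width
    return(tensor_to_samples(X, m_train))
  }
  if (inherits(newdata, "DNAStringSet") || is.character(newdata) ||
      inherits(newdata, "DNAString")) {
    if (inherits(newdata, "DNAString"))
      newdata <- Biostrings::DNAStringSet(newdata)
    x <- kmer_featurize(newdata, pp$kmer_config %||% kmer_config())
  } else {
    x <- as.matrix(newdata)
  }
  # preprocessing chain: optional raw-feature scaler, PCA, then the
  # component-score scaler; each stage applies only when the width matches
  # (so already-reduced matrices pass through untouched)
  if (!is.null(pp$pre_scaler) && ncol(x) == pp$pre_scaler$d)
    x <- apply_scaler(pp$pre_scaler, x)
  if (!is.null(pp$pca) && ncol(x) == pp$pca$d)
    x <- apply_pca(pp$pca, x)
  if (!is.null(pp$scaler) && ncol(x) == pp$scaler$d)
    x <- apply_scaler(pp$scaler, x)
  x
}

#' Export a model's training curves
#'
#' Writes the per-epoch series (epoch, split, metric, value) as CSV.
#'
#' @param model A `trained_model`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_training_curves <- function(model, path) {
  h <- model$history
  long <- rbind(
    data.frame(epoch = h$epoch, split = "train", metric = "loss",
               value = h$loss),
    data.frame(epoch = h$epoch, split = "validation", metric = "loss",
               value = h$val_loss),
    data.frame(epoch = h$epoch, split = "validation", metric = "f1",
               value = h$val_f1)
  )
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
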