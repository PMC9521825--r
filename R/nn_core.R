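# Minimal neural-network engine: dense and 1-D convolutional layers over
# one-hot DNA, batch normalization, (spatial) dropout, ReLU/sigmoid/tanh,
# softmax/sigmoid cross-entropy heads, Adam. Written in base matrix ops;
# minibatch data flow is either an n x d matrix (dense path) or a list of
# per-sample m x C matrices (convolutional path, C = channels).

nn_dense <- function(d_in, d_out) {
  list(type = "dense",
       params = list(W = matrix(stats::rnorm(d_in * d_out, sd = sqrt(2 / d_in)),
                                d_in, d_out),
                     b = rep(0, d_out)))
}

nn_bn <- function(d, momentum = 0.99, eps = 1e-3) {
  list(type = "bn",
       params = list(gamma = rep(1, d), beta = rep(0, d)),
       state = list(rmean = rep(0, d), rvar = rep(1, d)),
       conf = list(momentum = momentum, eps = eps))
}

nn_act <- function(fun) list(type = "act", conf = list(fun = fun))
nn_dropout <- function(p) list(type = "dropout", conf = list(p = p))
nn_conv <- function(c_in, c_out, kw) {
  fan_in <- c_in * kw
  list(type = "conv",
       params = list(W = matrix(stats::rnorm(fan_in * c_out,
                                             sd = sqrt(2 / fan_in)),
                                fan_in, c_out),
                     b = rep(0, c_out)),
       conf = list(kw = kw, c_in = c_in))
}
nn_pool <- function(size) list(type = "pool", conf = list(size = size))
nn_spatialdrop <- function(p) list(type = "spatialdrop", conf = list(p = p))
nn_flatten <- function() list(type = "flatten")

im2col <- function(X, kw) {
  m <- nrow(X); cin <- ncol(X)
  out_len <- m - kw + 1L
  col <- matrix(0, out_len, kw * cin)
  for (j in seq_len(kw) - 1L)
    col[, j * cin + seq_len(cin)] <- X[(1L + j):(out_len + j), , drop = FALSE]
  col
}

col2im <- function(dcol, m, cin, kw) {
  out_len <- m - kw + 1L
  dX <- matrix(0, m, cin)
  for (j in seq_len(kw) - 1L)
    dX[(1L + j):(out_len + j), ] <- dX[(1L + j):(out_len + j), ] +
      dcol[, j * cin + seq_len(cin), drop = FALSE]
  dX
}

# batchnorm over columns of a matrix (dense: features; conv: channels with
# samples/positions stacked as rows)
bn_forward_mat <- function(layer, x, training) {
  eps <- layer$conf$eps
  if (training) {
    mu <- colMeans(x)
    xc <- sweep(x, 2L, mu, "-")
    v <- colMeans(xc^2)
    inv_sd <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2L, inv_sd, "*")
    mom <- layer$conf$momentum
    layer$state$rmean <- mom * layer$state$rmean + (1 - mom) * mu
    layer$state$rvar <- mom * layer$state$rvar + (1 - mom) * v
    cache <- list(xhat = xhat, xc = xc, inv_sd = inv_sd)
  } else {
    xhat <- sweep(sweep(x, 2L, layer$state$rmean, "-"), 2L,
                  1 / sqrt(layer$state$rvar + eps), "*")
    cache <- NULL
  }
  out <- sweep(sweep(xhat, 2L, layer$params$gamma, "*"), 2L,
               layer$params$beta, "+")
  list(out = out, cache = cache, layer = layer)
}

bn_backward_mat <- function(layer, cache, dy) {
  n <- nrow(dy)
  xhat <- cache$xhat; inv_sd <- cache$inv_sd
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, layer$params$gamma, "*")
  # dx = inv_sd/n * (n*dxhat - colSums(dxhat) - xhat * colSums(dxhat*xhat))
  t1 <- n * dxhat
  t2 <- matrix(colSums(dxhat), n, ncol(dy), byrow = TRUE)
  t3 <- xhat * matrix(colSums(dxhat * xhat), n, ncol(dy), byrow = TRUE)
  dx <- sweep(t1 - t2 - t3, 2L, inv_sd / n, "*")
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

layer_forward <- function(layer, x, training) {
  switch(layer$type,
    dense = {
      out <- x %*% layer$params$W
      out <- sweep(out, 2L, layer$params$b, "+")
      list(out = out, cache = list(x = x), layer = layer)
    },
    bn = {
      if (is.list(x) && !is.data.frame(x) && !is.matrix(x)) {
        rows <- vapply(x, nrow, integer(1))
        stacked <- do.call(rbind, x)
        r <- bn_forward_mat(layer, stacked, training)
        out <- unstack_rows(r$out, rows)
        list(out = out, cache = c(r["cache"], list(rows = rows)),
             layer = r$layer)
      } else {
        bn_forward_mat(layer, x, training)
      }
    },
    act = {
      out <- switch(layer$conf$fun,
                    relu = if (is.matrix(x)) pmax(x, 0) else lapply(x, pmax, 0),
                    sigmoid = map_any(x, function(z) 1 / (1 + exp(-z))),
                    tanh = map_any(x, tanh))
      list(out = out, cache = list(out = out, x = x), layer = layer)
    },
    dropout = {
      if (!training) return(list(out = x, cache = NULL, layer = layer))
      p <- layer$conf$p
      mask <- matrix(stats::runif(length(x)) >= p, nrow(x), ncol(x)) / (1 - p)
      list(out = x * mask, cache = list(mask = mask), layer = layer)
    },
    conv = {
      kw <- layer$conf$kw
      cols <- lapply(x, im2col, kw = kw)
      out <- lapply(cols, function(cl)
        sweep(cl %*% layer$params$W, 2L, layer$params$b, "+"))
      list(out = out, cache = list(cols = cols,
                                   in_rows = vapply(x, nrow, integer(1))),
           layer = layer)
    },
    pool = {
      sz <- layer$conf$size
      out <- lapply(x, function(X) {
        keep <- (nrow(X) %/% sz) * sz
        if (keep == 0L) stop("pooling window larger than feature map")
        X <- X[seq_len(keep), , drop = FALSE]
        # average consecutive blocks of `sz` rows
        idx <- rep(seq_len(keep %/% sz), each = sz)
        rowsum(X, idx) / sz
      })
      list(out = out, cache = list(in_rows = vapply(x, nrow, integer(1))),
           layer = layer)
    },
    spatialdrop = {
      if (!training) return(list(out = x, cache = NULL, layer = layer))
      p <- layer$conf$p
      masks <- lapply(x, function(X)
        (stats::runif(ncol(X)) >= p) / (1 - p))
      out <- Map(function(X, m) sweep(X, 2L, m, "*"), x, masks)
      list(out = out, cache = list(masks = masks), layer = layer)
    },
    flatten = {
      dims <- lapply(x, dim)
      out <- t(vapply(x, as.vector, numeric(length(x[[1L]]))))
      list(out = out, cache = list(dims = dims), layer = layer)
    },
    stop("unknown layer type: ", layer$type))
}

map_any <- function(x, f) if (is.matrix(x)) f(x) else lapply(x, f)

unstack_rows <- function(mat, rows) {
  ends <- cumsum(rows)
  starts <- ends - rows + 1L
  Map(function(s, e) mat[s:e, , drop = FALSE], starts, ends)
}

layer_backward <- function(layer, cache, dy) {
  switch(layer$type,
    dense = {
      list(dx = dy %*% t(layer$params$W),
           grads = list(W = t(cache$x) %*% dy, b = colSums(dy)))
    },
    bn = {
      if (!is.null(cache$rows)) {
        r <- bn_backward_mat(layer, cache$cache, do.call(rbind, dy))
        list(dx = unstack_rows(r$dx, cache$rows), grads = r$grads)
      } else {
        bn_backward_mat(layer, cache, dy)
      }
    },
    act = {
      dx <- switch(layer$conf$fun,
        relu = if (is.matrix(dy)) dy * (cache$x > 0)
               else Map(function(d, x) d * (x > 0), dy, cache$x),
        sigmoid = if (is.matrix(dy)) dy * cache$out * (1 - cache$out)
                  else Map(function(d, o) d * o * (1 - o), dy, cache$out),
        tanh = if (is.matrix(dy)) dy * (1 - cache$out^2)
               else Map(function(d, o) d * (1 - o^2), dy, cache$out))
      list(dx = dx, grads = NULL)
    },
    dropout = {
      if (is.null(cache)) list(dx = dy, grads = NULL)
      else list(dx = dy * cache$mask, grads = NULL)
    },
    conv = {
      kw <- layer$conf$kw; cin <- layer$conf$c_in
      W <- layer$params$W
      dW <- matrix(0, nrow(W), ncol(W)); db <- rep(0, ncol(W))
      dx <- vector("list", length(dy))
      for (i in seq_along(dy)) {
        dW <- dW + t(cache$cols[[i]]) %*% dy[[i]]
        db <- db + colSums(dy[[i]])
        dx[[i]] <- col2im(dy[[i]] %*% t(W), cache$in_rows[i], cin, kw)
      }
      list(dx = dx, grads = list(W = dW, b = db))
    },
    pool = {
      sz <- layer$conf$size
      dx <- Map(function(d, m) {
        keep <- (m %/% sz) * sz
        dX <- matrix(0, m, ncol(d))
        dX[seq_len(keep), ] <- d[rep(seq_len(nrow(d)), each = sz), ] / sz
        dX
      }, dy, cache$in_rows)
      list(dx = dx, grads = NULL)
    },
    spatialdrop = {
      if (is.null(cache)) list(dx = dy, grads = NULL)
      else list(dx = Map(function(d, m) sweep(d, 2L, m, "*"), dy,
                         cache$masks),
           grads = NULL)
    },
    flatten = {
      dx <- lapply(seq_len(nrow(dy)), function(i) {
        matrix(dy[i, ], cache$dims[[i]][1L], cache$dims[[i]][2L])
      })
      list(dx = dx, grads = NULL)
    })
}

net_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net))
  for (i in seq_along(net)) {
    r <- layer_forward(net[[i]], x, training)
    x <- r$out
    caches[i] <- list(r$cache)  # cache may be NULL; preserve the slot
    net[[i]] <- r$layer
  }
  list(out = x, caches = caches, net = net)
}

net_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net))
  for (i in rev(seq_along(net))) {
    r <- layer_backward(net[[i]], caches[[i]], dout)
    dout <- r$dx
    grads[i] <- list(r$grads)   # keep NULL slots (plain [[<- would drop them)
  }
  grads
}

# --- loss heads ------------------------------------------------------------

softmax_probs <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# categorical cross entropy on logits; y is a one-hot matrix
loss_categorical_ce <- function(z, y) {
  p <- softmax_probs(z)
  list(loss = -mean(rowSums(y * log(p + 1e-12))),
       dz = (p - y) / nrow(z), probs = p)
}

# binary cross entropy on a single logit column; y in {0,1}
loss_binary_ce <- function(z, y) {
  p <- 1 / (1 + exp(-z))
  list(loss = -mean(y * log(p + 1e-12) + (1 - y) * log(1 - p + 1e-12)),
       dz = (p - y) / nrow(z), probs = p)
}

# L2 penalty on dense/conv weight matrices (not biases or batchnorm params)
add_weight_decay <- function(net, grads, wd) {
  for (i in seq_along(net)) {
    if (net[[i]]$type %in% c("dense", "conv") && !is.null(grads[[i]]))
      grads[[i]]$W <- grads[[i]]$W + wd * net[[i]]$params$W
  }
  grads
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(net) {
  lapply(net, function(l) {
    if (is.null(l$params)) return(NULL)
    lapply(l$params, function(p) list(m = p * 0, v = p * 0))
  })
}

adam_step <- function(net, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(net)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[nm]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[nm]]^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      net[[i]]$params[[nm]] <- net[[i]]$params[[nm]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(net = net, state = state)
}
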