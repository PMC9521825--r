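#' @title Classical-ML hyperparameter grids
#' @description
#' The reference parameter catalogue for the eight classical algorithms:
#' KNN (n_neighbors 1-100 step 1), SVC (C 10-100, multiplicative step 10,
#' gamma fixed at 1e-6), LR (C 0.1-1 step 0.1), LDA (tol 1e-4 to 1e-3 step
#' 1e-4), NB (var_smoothing 1e-1 to 1e-19, factor 1e-2), MLP (hidden width
#' 50-500 step 50, lbfgs-style solver, alpha 0.5), DT (max_depth 1-10 step
#' 1) and RF (n_estimators 10-100 step 10). [grid_search()] selects the
#' candidate maximizing validation F1, ties going to the earliest
#' (smallest) candidate.
#' @name grid
NULL

grid_algorithms <- c("KNN", "SVC", "LR", "LDA", "NB", "MLP", "DT", "RF")

#' Enumerate the candidate grid for one algorithm
#'
#' @param algorithm One of `"KNN"`, `"SVC"`, `"LR"`, `"LDA"`, `"NB"`,
#'   `"MLP"`, `"DT"`, `"RF"`.
#' @return A data.frame with columns `algorithm`, `parameter`, `value`,
#'   in deterministic catalogue order.
#' @export
enumerate_grid <- function(algorithm) {
  algorithm <- toupper(algorithm)
  if (!algorithm %in% grid_algorithms)
    stop("unknown algorithm: ", algorithm)
  g <- switch(algorithm,
    KNN = list(parameter = "n_neighbors", value = 1:100),
    SVC = list(parameter = "C", value = c(10, 100)),
    LR  = list(parameter = "C", value = seq(0.1, 1, by = 0.1)),
    LDA = list(parameter = "tol", value = seq(1e-4, 1e-3, by = 1e-4)),
    NB  = list(parameter = "var_smoothing", value = 10^seq(-1, -19, by = -2)),
    MLP = list(parameter = "hidden_layer_sizes", value = seq(50, 500, by = 50)),
    DT  = list(parameter = "max_depth", value = 1:10),
    RF  = list(parameter = "n_estimators", value = seq(10, 100, by = 10)))
  data.frame(algorithm = algorithm, parameter = g$parameter,
             value = g$value, stringsAsFactors = FALSE)
}

# fit + predict one candidate; returns predicted labels on x_val.
# y is a factor throughout.
fit_predict_candidate <- function(algorithm, value, x_train, y_train, x_val) {
  switch(algorithm,
    KNN = as.character(class::knn(x_train, x_val, cl = y_train, k = value)),
    SVC = {
      fit <- e1071::svm(x_train, y_train, type = "C-classification",
                        kernel = "radial", gamma = 1e-6, cost = value,
                        scale = FALSE)
      as.character(predict(fit, x_val))
    },
    LR = {
      fam <- if (nlevels(y_train) > 2L) "multinomial" else "binomial"
      # map the inverse-regularization strength C to ridge lambda = 1/(n*C)
      fit <- glmnet::glmnet(x_train, y_train, family = fam, alpha = 0,
                            lambda = 1 / (nrow(x_train) * value))
      as.character(predict(fit, x_val, type = "class")[, 1L])
    },
    LDA = {
      fit <- MASS::lda(x_train, grouping = y_train, tol = value)
      as.character(predict(fit, x_val)$class)
    },
    NB = {
      fit <- gaussian_nb(x_train, y_train, var_smoothing = value)
      as.character(predict(fit, x_val))
    },
    MLP = {
      # single hidden layer of `value` units; BFGS optimizer, decay = alpha
      y_ind <- nnet::class.ind(y_train)
      fit <- nnet::nnet(x_train, y_ind, size = value, softmax = TRUE,
                        decay = 0.5, maxit = 200, trace = FALSE,
                        MaxNWts = 1e7)
      colnames(y_ind)[max.col(predict(fit, x_val), ties.method = "first")]
    },
    DT = {
      df <- data.frame(y = y_train, x_train)
      fit <- rpart::rpart(y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(maxdepth = value,
                                                         cp = 0,
                                                         minsplit = 2))
      as.character(predict(fit, data.frame(x_val), type = "class"))
    },
    RF = {
      fit <- randomForest::randomForest(x_train, y_train, ntree = value)
      as.character(predict(fit, x_val))
    })
}

#' Gaussian naive Bayes with variance smoothing
#'
#' Per-class Gaussian likelihoods on each feature; `var_smoothing` times
#' the largest feature variance is added to every per-class variance for
#' numerical stability (the Table-1 NB parameter).
#'
#' @param x Numeric training matrix.
#' @param y Factor of class labels.
#' @param var_smoothing Smoothing fraction.
#' @return An object of class `gaussian_nb`.
#' @export
gaussian_nb <- function(x, y, var_smoothing = 1e-9) {
  y <- as.factor(y)
  classes <- levels(y)
  mu <- t(vapply(classes, function(cl)
    colMeans(x[y == cl, , drop = FALSE]), numeric(ncol(x))))
  va <- t(vapply(classes, function(cl)
    apply(x[y == cl, , drop = FALSE], 2L, stats::var), numeric(ncol(x))))
  va[!is.finite(va)] <- 0
  glob <- apply(x, 2L, stats::var)
  va <- va + var_smoothing * max(glob, na.rm = TRUE)
  prior <- as.numeric(table(y)[classes]) / length(y)
  structure(list(classes = classes, mu = mu, var = va, prior = prior),
            class = "gaussian_nb")
}

#' @export
predict.gaussian_nb <- function(object, newdata, ...) {
  ll <- vapply(seq_along(object$classes), function(ci) {
    mu <- object$mu[ci, ]; va <- object$var[ci, ]
    rowSums(-0.5 * (sweep(newdata, 2L, mu, "-")^2 /
                      matrix(va, nrow(newdata), ncol(newdata), byrow = TRUE)) -
              0.5 * matrix(log(2 * pi * va), nrow(newdata), ncol(newdata),
                           byrow = TRUE)) + log(object$prior[ci])
  }, numeric(nrow(newdata)))
  ll <- matrix(ll, nrow = nrow(newdata))
  factor(object$classes[max.col(ll, ties.method = "first")],
         levels = object$classes)
}

#' Grid search over one algorithm's Table-1 candidates
#'
#' Fits each candidate on the training partition and scores it on the
#' validation partition by F1 (positive-class F1 for two classes, weighted
#' F1 otherwise); selects the maximum, ties resolved toward the earliest
#' (smallest) candidate.
#'
#' @param algorithm Algorithm name (see [enumerate_grid()]).
#' @param x_train,y_train Training features (already scaled/PCA-reduced)
#'   and labels.
#' @param x_val,y_val Validation features and labels.
#' @return List with `best` (one-row data.frame: algorithm, parameter,
#'   value, f1) and `scores` (per-candidate data.frame).
#' @export
grid_search <- function(algorithm, x_train, y_train, x_val, y_val) {
  y_train <- as.factor(y_train)
  if (nlevels(droplevels(y_train)) < 2L)
    stop("training data contains a single class; grid search is undefined")
  grid <- enumerate_grid(algorithm)
  classes <- levels(y_train)
  f1s <- vapply(grid$value, function(v) {
    pred <- fit_predict_candidate(grid$algorithm[1L], v, x_train, y_train,
                                  x_val)
    cm <- confusion_matrix(as.character(y_val), pred, levels = classes)
    if (length(classes) == 2L)
      binary_metrics(tn = cm[1, 1], fp = cm[1, 2],
                     fn = cm[2, 1], tp = cm[2, 2])$f1
    else
      multiclass_metrics(cm)$f1
  }, numeric(1))
  scores <- cbind(grid, f1 = f1s)
  best <- scores[which.max(scores$f1), , drop = FALSE]
  rownames(best) <- NULL
  list(best = best, scores = scores)
}
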