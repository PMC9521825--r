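#' Train a curation model end-to-end
#'
#' The full training workflow: stratified split -> k-mer featurization ->
#' PCA to the target explained variance (fit on the training partition) ->
#' standardization of the component scores (fit on the training partition)
#' -> model training -> test-partition evaluation. PCA is fitted on the
#' per-k-normalized frequencies directly; standardizing all 5460 features
#' first would give every rare k-mer's sampling noise unit variance and
#' drown the composition signal at moderate sample sizes, so the scaler is
#' applied to the retained component scores instead (`scale_first = TRUE`
#' restores the scale-then-reduce order). For the FNN the preprocessing chain is bound
#' to the returned model, so it can score raw FASTA sequences directly.
#' Classical algorithms run their Table-1 grid search on the validation
#' partition and report the best candidate's test performance.
#'
#' @param ds A `labeled_dataset` with non-missing labels.
#' @param binary Collapse classes 1-4 into one positive class (the
#'   two-label problem; default) or keep all five classes.
#' @param model `"fnn"` or a classical algorithm name
#'   (see [enumerate_grid()]).
#' @param kmer_cfg A [kmer_config()].
#' @param split A [split_spec()].
#' @param pca_variance Target explained variance for PCA (`NULL` to skip).
#' @param scale_first Standardize all raw features before PCA instead of
#'   standardizing the component scores after it.
#' @param fnn An [fnn_config()]; its `loss` is forced to match `binary`.
#' @param verbose Passed to [train_fnn()].
#' @return List with `model` (`trained_model` for the FNN, the grid-search
#'   result otherwise), `report` (test-partition metrics), `confusion`,
#'   `roc` (binary only), `split` indices and `labels` as trained on.
#' @export
train_curation_model <- function(ds, binary = TRUE, model = "fnn",
                                 kmer_cfg = kmer_config(),
                                 split = split_spec(),
                                 pca_variance = 0.96, scale_first = FALSE,
                                 fnn = fnn_config(), verbose = FALSE) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (anyNA(ds$labels)) stop("dataset labels contain NA")
  labels <- if (binary) binarize(ds$labels) else ds$labels
  parts <- split_dataset(labels, split)

  X <- kmer_featurize(ds$seqs, kmer_cfg)
  Xs <- X
  pca <- NULL
  pre_scaler <- NULL
  if (scale_first) {
    pre_scaler <- fit_scaler(Xs[parts$train, , drop = FALSE])
    Xs <- apply_scaler(pre_scaler, Xs)
  }
  if (!is.null(pca_variance)) {
    pca <- fit_pca(Xs[parts$train, , drop = FALSE], pca_variance)
    Xs <- apply_pca(pca, Xs)
  }
  scaler <- NULL
  if (!scale_first) {
    scaler <- fit_scaler(Xs[parts$train, , drop = FALSE])
    Xs <- apply_scaler(scaler, Xs)
  }

  if (identical(model, "fnn")) {
    fnn$loss <- if (binary) "binary_ce" else "categorical_ce"
    fit <- train_fnn(fnn,
                     Xs[parts$train, , drop = FALSE], labels[parts$train],
                     Xs[parts$validation, , drop = FALSE],
                     labels[parts$validation],
                     preprocessing = list(kmer_config = kmer_cfg,
                                          pre_scaler = pre_scaler,
                                          pca = pca, scaler = scaler),
                     verbose = verbose)
    pred <- predict(fit, X[parts$test, , drop = FALSE], type = "both")
    test_pred <- pred$class
    scores <- if (binary) pred$prob[, "1"] else NULL
  } else {
    gs <- grid_search(model,
                      Xs[parts$train, , drop = FALSE],
                      labels[parts$train],
                      Xs[parts$validation, , drop = FALSE],
                      labels[parts$validation])
    test_pred <- fit_predict_candidate(
      toupper(model), gs$best$value,
      Xs[parts$train, , drop = FALSE], as.factor(labels[parts$train]),
      Xs[parts$test, , drop = FALSE])
    test_pred <- as.integer(test_pred)
    fit <- gs
    scores <- NULL
  }

  truth <- labels[parts$test]
  cls <- sort(unique(labels))
  cm <- confusion_matrix(truth, test_pred, levels = cls)
  if (binary) {
    report <- binary_metrics(tn = cm[1, 1], fp = cm[1, 2],
                             fn = cm[2, 1], tp = cm[2, 2])
    roc <- if (!is.null(scores) && length(unique(truth)) == 2L)
      roc_prc(scores, truth) else NULL
  } else {
    report <- multiclass_metrics(cm)
    roc <- NULL
  }
  list(model = fit, report = report, confusion = cm, roc = roc,
       split = parts, labels = labels, binary = binary)
}

#' Curate a sequence library with a trained model
#'
#' Scores every input sequence and splits the library into kept (predicted
#' intact) and removed (predicted contaminated) sets. Sequences shorter
#' than the k-mer upper bound are still scored (their spectra are
#' degenerate) and flagged.
#'
#' @param model A `trained_model` (binary head) from
#'   [train_curation_model()] / [train_fnn()].
#' @param seqs A named [Biostrings::DNAStringSet].
#' @param threshold Positive-class decision threshold (default 0.5).
#' @return List with `kept`, `removed` (both `DNAStringSet`) and `scores`
#'   (data.frame: seq_id, score, decision, flag).
#' @export
curate_library <- function(model, seqs, threshold = 0.5) {
  stopifnot(inherits(model, "trained_model"))
  if (length(seqs) == 0L) {
    empty <- Biostrings::DNAStringSet()
    return(list(kept = empty, removed = empty,
                scores = data.frame(seq_id = character(0),
                                    score = numeric(0),
                                    decision = character(0),
                                    flag = character(0))))
  }
  k_max <- (model$preprocessing$kmer_config %||% kmer_config())$k_max
  pred <- predict(model, seqs, type = "both", threshold = threshold)
  score <- if (ncol(pred$prob) == 2L) pred$prob[, 2L]
           else 1 - pred$prob[, 1L]
  contaminated <- pred$class != model$classes[1L]
  flag <- ifelse(Biostrings::width(seqs) < k_max, "short", "ok")
  scores <- data.frame(seq_id = names(seqs), score = score,
                       decision = ifelse(contaminated, "removed", "kept"),
                       flag = flag, stringsAsFactors = FALSE)
  list(kept = seqs[!contaminated], removed = seqs[contaminated],
       scores = scores)
}
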