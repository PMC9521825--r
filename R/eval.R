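#' @title Splitting, metrics and curves
#' @description
#' Stratified 80/10/10 train/validation/test splitting, binary and
#' multiclass confusion-matrix metrics (precision, recall, F1, accuracy,
#' specificity, FPR), and ROC / precision-recall curves with trapezoidal
#' AUC and step-wise auPRC.
#' @name eval
NULL

#' Train/validation/test split specification
#'
#' @param train,validation,test Fractions summing to 1 (defaults 0.8, 0.1,
#'   0.1).
#' @param seed Integer seed.
#' @param stratified Preserve class proportions within each partition
#'   (default `TRUE`).
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train = 0.8, validation = 0.1, test = 0.1,
                       seed = 1L, stratified = TRUE) {
  if (abs(train + validation + test - 1) > 1e-8)
    stop("split fractions must sum to 1")
  stopifnot(train > 0, validation >= 0, test >= 0)
  structure(list(fractions = c(train = train, validation = validation,
                               test = test),
                 seed = as.integer(seed), stratified = stratified),
            class = "split_spec")
}

# allocate n items to 3 bins by largest-remainder rounding of fractions
allocate_counts <- function(n, fractions) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Split record indices into train/validation/test
#'
#' Disjoint, exhaustive and seed-deterministic. In stratified mode each
#' class is allocated separately (largest-remainder rounding), so partition
#' class proportions match the dataset within one record per class.
#'
#' @param labels Vector of class labels (any atomic type); its length sets
#'   the dataset size.
#' @param spec A [split_spec()].
#' @return List with integer index vectors `train`, `validation`, `test`.
#' @export
split_dataset <- function(labels, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  n <- length(labels)
  if (n < 10L) stop("dataset must have at least 10 records")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  parts <- list(train = integer(0), validation = integer(0),
                test = integer(0))
  groups <- if (spec$stratified) split(seq_len(n), labels)
            else list(all = seq_len(n))
  for (g in groups) {
    g <- sample(g)
    cnt <- allocate_counts(length(g), spec$fractions)
    parts$train <- c(parts$train, g[seq_len(cnt[1])])
    parts$validation <- c(parts$validation,
                          g[seq_len(cnt[2]) + cnt[1]])
    parts$test <- c(parts$test, g[seq_len(cnt[3]) + cnt[1] + cnt[2]])
  }
  lapply(parts, sort)
}

#' Metrics from binary confusion counts
#'
#' Standard definitions: precision tp/(tp+fp), recall tp/(tp+fn),
#' F1 = 2PR/(P+R), accuracy (tp+tn)/n, specificity tn/(tn+fp),
#' FPR fp/(fp+tn). Undefined ratios (0/0) are reported as 0 and flagged.
#'
#' @param tn,fp,fn,tp Non-negative counts; alternatively pass a single
#'   named vector/list as `tn`.
#' @return An object of class `evaluation_report`.
#' @export
binary_metrics <- function(tn, fp = NULL, fn = NULL, tp = NULL) {
  if (is.null(fp) && (is.list(tn) || length(tn) == 4L)) {
    cc <- as.list(tn)
    tn <- cc$tn; fp <- cc$fp; fn <- cc$fn; tp <- cc$tp
  }
  counts <- c(tn = tn, fp = fp, fn = fn, tp = tp)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  if (sum(counts) == 0) stop("confusion counts must not all be zero")
  undefined <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); 0 } else num / den
  }
  precision <- ratio(tp, tp + fp, "precision")
  recall <- ratio(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) { undefined <- c(undefined, "f1"); 0 }
        else 2 * precision * recall / (precision + recall)
  structure(list(
    counts = counts,
    precision = precision, recall = recall, f1 = f1,
    accuracy = (tp + tn) / sum(counts),
    specificity = ratio(tn, tn + fp, "specificity"),
    fpr = ratio(fp, fp + tn, "fpr"),
    undefined = undefined
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf("  counts: tn=%d fp=%d fn=%d tp=%d\n",
              x$counts["tn"], x$counts["fp"], x$counts["fn"],
              x$counts["tp"]))
  cat(sprintf("  precision=%.4f recall=%.4f F1=%.4f accuracy=%.4f\n",
              x$precision, x$recall, x$f1, x$accuracy))
  cat(sprintf("  specificity=%.4f FPR=%.4f\n", x$specificity, x$fpr))
  if (length(x$undefined))
    cat("  undefined (0/0, reported as 0):",
        paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Confusion matrix from predicted and true labels
#'
#' @param truth,predicted Vectors of equal length.
#' @param levels Optional label universe (row/column order).
#' @return A square matrix, rows = truth, columns = predicted.
#' @export
confusion_matrix <- function(truth, predicted, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(c(truth, predicted)))
  truth <- factor(truth, levels = levels)
  predicted <- factor(predicted, levels = levels)
  as.matrix(table(truth, predicted))
}

#' Metrics from a multiclass confusion matrix
#'
#' Per-class one-vs-rest precision/recall/F1 plus macro and weighted
#' averages (weights = per-class truth counts). Classes that are never
#' predicted get F1 = 0 and are flagged.
#'
#' @param mat Square confusion matrix, rows = truth, columns = predicted.
#' @param averaging `"weighted"` (default, befitting imbalanced data) or
#'   `"macro"` selects the headline `f1` field; both are always reported.
#' @return List with `per_class` data.frame, `macro_f1`, `weighted_f1`,
#'   `f1`, `accuracy`, `never_predicted`.
#' @export
multiclass_metrics <- function(mat, averaging = c("weighted", "macro")) {
  averaging <- match.arg(averaging)
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("confusion matrix must be square")
  n <- sum(mat)
  tp <- diag(mat)
  fp <- colSums(mat) - tp
  fn <- rowSums(mat) - tp
  prec <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  rec <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  support <- rowSums(mat)
  per_class <- data.frame(class = rownames(mat) %||% seq_len(nrow(mat)),
                          precision = prec, recall = rec, f1 = f1,
                          support = support, row.names = NULL)
  macro <- mean(f1)
  weighted <- sum(f1 * support) / max(n, 1)
  list(per_class = per_class,
       macro_f1 = macro, weighted_f1 = weighted,
       f1 = if (averaging == "weighted") weighted else macro,
       accuracy = sum(tp) / max(n, 1),
       never_predicted = per_class$class[colSums(mat) == 0 & support > 0],
       matrix = mat)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' ROC and precision-recall curves
#'
#' Threshold sweep over the unique scores: ROC points (FPR, TPR) with
#' trapezoidal AUC, and PR points with step-wise interpolated auPRC
#' (sum over recall increments of the precision at each threshold).
#'
#' @param scores Numeric scores in `[0, 1]` (higher = more positive).
#' @param truth Binary truth (0/1 or logical).
#' @return List with `roc` (data.frame threshold/fpr/tpr), `prc`
#'   (data.frame threshold/recall/precision), `auc`, `auprc`.
#' @export
roc_prc <- function(scores, truth) {
  truth <- as.integer(truth)
  stopifnot(length(scores) == length(truth), all(truth %in% 0:1))
  P <- sum(truth == 1L); N <- sum(truth == 0L)
  if (P == 0L || N == 0L)
    stop("AUC undefined: truth contains a single class")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  # cumulative counts at each distinct threshold
  keep <- c(diff(s) != 0, TRUE)
  tp <- cumsum(y)[keep]
  fp <- cumsum(1 - y)[keep]
  thr <- s[keep]
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  prec <- tp / (tp + fp)
  rec <- tp / P
  auprc <- sum(diff(c(0, rec)) * prec)
  list(roc = data.frame(threshold = c(Inf, thr), fpr = fpr, tpr = tpr),
       prc = data.frame(threshold = thr, recall = rec, precision = prec),
       auc = auc, auprc = auprc)
}

#' Paper-style truncated display of a metric
#'
#' Truncates (not rounds) to `digits` decimals, the convention the
#' reference tables appear to use (e.g. recall 0.9167 shown as 0.916,
#' F1 0.9368 shown as 93.6%).
#'
#' @param x Value in `[0, 1]`.
#' @param digits Decimals to keep.
#' @param percent Display as percentage.
#' @return Character scalar.
#' @export
format_metric <- function(x, digits = 3L, percent = FALSE) {
  if (percent) {
    sprintf(paste0("%.", max(digits - 2L, 0L), "f%%"),
            trunc(x * 10^digits) / 10^(digits - 2L))
  } else {
    sprintf(paste0("%.", digits, "f"), trunc(x * 10^digits) / 10^digits)
  }
}

#' Export an evaluation report as JSON
#'
#' @param report An `evaluation_report` or [multiclass_metrics()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}
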