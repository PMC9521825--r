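# Splitting, confusion metrics, ROC/PRC.

test_that("80/10/10 split is disjoint, exhaustive, stratified and seed-stable", {
  labels <- rep(c(0, 1), times = c(600, 400))
  sp <- split_spec(seed = 5)
  parts <- split_dataset(labels, sp)
  expect_identical(sort(unname(unlist(parts))), 1:1000)
  expect_length(parts$train, 800L)
  expect_length(parts$validation, 100L)
  expect_length(parts$test, 100L)
  # stratification: 60:40 within one record per class
  for (p in parts) {
    tab <- table(labels[p])
    expect_lte(abs(tab["0"] / length(p) - 0.6), 1.5 / length(p))
  }
  expect_identical(split_dataset(labels, sp), parts)
  expect_false(identical(split_dataset(labels, split_spec(seed = 6)), parts))

  # odd sizes still disjoint/exhaustive
  labs2 <- rep(c("a", "b", "c"), times = c(7, 11, 5))
  p2 <- split_dataset(labs2, split_spec(seed = 2))
  expect_identical(sort(unname(unlist(p2))), seq_along(labs2))

  expect_error(split_spec(0.7, 0.1, 0.1), "sum to 1")
  expect_error(split_dataset(1:5), "at least 10")
})

test_that("binary metrics reproduce the library-curation worked example", {
  # confusion counts from a published curation run on a rice LTR-RT library
  r <- binary_metrics(tn = 2302, fp = 132, fn = 272, tp = 2994)
  expect_equal(r$precision, 2994 / 3126)
  expect_equal(r$recall, 2994 / 3266)
  expect_equal(r$f1, 2 * (2994/3126) * (2994/3266) / (2994/3126 + 2994/3266))
  expect_identical(format_metric(r$f1, percent = TRUE), "93.6%")
  expect_identical(format_metric(r$recall), "0.916")
  expect_equal(r$accuracy, (2994 + 2302) / 5700, tolerance = 1e-12)
  expect_identical(format_metric(r$accuracy), "0.929")
})

test_that("degenerate confusion counts are handled with flags, not NaN", {
  r <- binary_metrics(tn = 0, fp = 0, fn = 0, tp = 10)
  expect_equal(c(r$precision, r$recall, r$f1, r$accuracy), rep(1, 4))
  r0 <- binary_metrics(tn = 10, fp = 0, fn = 0, tp = 0)
  expect_equal(r0$precision, 0)
  expect_true("precision" %in% r0$undefined)
  expect_error(binary_metrics(tn = -1, fp = 0, fn = 0, tp = 1),
               "non-negative")
  expect_error(binary_metrics(tn = 0, fp = 0, fn = 0, tp = 0))
})

test_that("metric identities hold over random confusion counts", {
  set.seed(47)
  for (i in 1:1000) {
    cc <- sample(0:500, 4, replace = TRUE)
    if (sum(cc) == 0) next
    r <- binary_metrics(tn = cc[1], fp = cc[2], fn = cc[3], tp = cc[4])
    expect_equal(r$accuracy, (cc[4] + cc[1]) / sum(cc))
    if (r$precision + r$recall > 0)
      expect_equal(r$f1,
                   2 * r$precision * r$recall / (r$precision + r$recall))
    expect_true(all(unlist(r[c("precision", "recall", "f1", "accuracy",
                               "specificity", "fpr")]) >= 0))
    expect_true(all(unlist(r[c("precision", "recall", "f1", "accuracy",
                               "specificity", "fpr")]) <= 1))
  }
})

test_that("multiclass metrics: identity matrix, absent predictions, binary agreement", {
  m <- multiclass_metrics(diag(5) * 10)
  expect_equal(m$macro_f1, 1)
  expect_equal(m$weighted_f1, 1)

  mat <- rbind(c(10, 0, 0), c(2, 8, 0), c(5, 0, 0))  # class 3 never predicted
  m2 <- multiclass_metrics(mat)
  expect_equal(m2$per_class$f1[3], 0)
  expect_length(m2$never_predicted, 1L)

  # balanced symmetric 2-class case: weighted F1 equals binary F1
  mat2 <- rbind(c(45, 5), c(5, 45))
  m3 <- multiclass_metrics(mat2)
  b <- binary_metrics(tn = 45, fp = 5, fn = 5, tp = 45)
  expect_equal(m3$weighted_f1, b$f1)

  expect_error(multiclass_metrics(matrix(1, 2, 3)), "square")
})

test_that("ROC/PRC: perfect separation, reversal symmetry, degenerate truth", {
  scores <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  truth <- c(1, 1, 1, 0, 0, 0)
  r <- roc_prc(scores, truth)
  expect_equal(r$auc, 1)
  expect_equal(r$auprc, 1)

  set.seed(51)
  s <- runif(100); y <- rbinom(100, 1, 0.4)
  a <- roc_prc(s, y)$auc
  b <- roc_prc(1 - s, y)$auc
  expect_equal(a + b, 1, tolerance = 1e-12)

  expect_error(roc_prc(runif(5), rep(1, 5)), "single class")
})

test_that("trapezoidal AUC equals the brute-force Mann-Whitney statistic", {
  # oracle: mean over all (positive, negative) pairs of
  # I(s_pos > s_neg) + 0.5 * I(s_pos == s_neg)
  mw_auc <- function(scores, truth) {
    sp <- scores[truth == 1]; sn <- scores[truth == 0]
    mean(outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(53)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), sample(c(1, 2, 6), 1))   # induce ties sometimes
    expect_equal(roc_prc(s, y)$auc, mw_auc(s, y), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent implementation", {
  set.seed(57)
  s <- runif(300); y <- rbinom(300, 1, 0.5)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_prc(s, y)$auc, ref, tolerance = 1e-10)
})

test_that("AUC of truth-independent scores approaches 0.5", {
  set.seed(59)
  s <- runif(10000); y <- rbinom(10000, 1, 0.5)
  expect_equal(roc_prc(s, y)$auc, 0.5, tolerance = 0.02)
})

test_that("paper-style truncation display truncates rather than rounds", {
  expect_identical(format_metric(0.9167), "0.916")
  expect_identical(format_metric(0.9368, percent = TRUE), "93.6%")
  expect_identical(format_metric(0.9999), "0.999")
})
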