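#' @title Sequence featurization
#' @description
#' Two representations feed the classifiers: concatenated k-mer frequency
#' spectra for k = 1..6 (4 + 16 + ... + 4096 = 5460 dimensions), optionally
#' standardized and PCA-reduced to 96% explained variance; and 5-row one-hot
#' matrices (rows A, C, G, T, N) stacked into a 5 x m x n tensor, m being
#' the longest sequence in the set.
#' @name features
NULL

#' k-mer featurization configuration
#'
#' @param k_min,k_max Inclusive k range (defaults 1 and 6).
#' @param normalize `"frequency"` (each k-block divided by its valid window
#'   count; 0/0 yields 0) or `"count"` (raw counts).
#' @return An object of class `kmer_config`.
#' @export
kmer_config <- function(k_min = 1L, k_max = 6L,
                        normalize = c("frequency", "count")) {
  normalize <- match.arg(normalize)
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  stopifnot(k_min >= 1L, k_min <= k_max)
  structure(list(k_min = k_min, k_max = k_max, normalize = normalize),
            class = "kmer_config")
}

#' Feature dimension of a k-mer configuration
#'
#' `sum(4^k)` over the configured k range; 5460 for the default k = 1..6.
#'
#' @param config A [kmer_config()].
#' @return Integer dimension.
#' @export
kmer_dim <- function(config = kmer_config()) {
  as.integer(sum(4^(config$k_min:config$k_max)))
}

#' k-mer spectrum matrix for a sequence set
#'
#' For each k, k-mers over \{A,C,G,T\} are counted by sliding window;
#' windows containing any other letter (e.g. N) are skipped. In frequency
#' mode each k-block row is divided by its number of counted windows.
#' Columns are ordered lexicographically within each k, k ascending.
#'
#' @param seqs A [Biostrings::DNAStringSet] (or character vector).
#' @param config A [kmer_config()].
#' @return A numeric matrix, one row per sequence, with k-mer column names.
#' @export
kmer_featurize <- function(seqs, config = kmer_config()) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(toupper(seqs))
  blocks <- lapply(config$k_min:config$k_max, function(k) {
    M <- Biostrings::oligonucleotideFrequency(seqs, width = k)
    if (config$normalize == "frequency") {
      tot <- rowSums(M)
      M <- M / ifelse(tot == 0, 1, tot)
    }
    M
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- names(seqs)
  out
}

#' k-mer spectrum vector for a single sequence
#'
#' @param seq Character string or [Biostrings::DNAString].
#' @inheritParams kmer_featurize
#' @return A named numeric vector of length [kmer_dim()].
#' @export
kmer_vector <- function(seq, config = kmer_config()) {
  s <- Biostrings::DNAStringSet(as_single_dna(seq))
  kmer_featurize(s, config)[1L, ]
}

onehot_rows <- c("A", "C", "G", "T", "N")

#' One-hot encode a sequence set
#'
#' Each sequence becomes a 5-row binary matrix (row order A, C, G, T, N) of
#' width `m`, the longest sequence length; shorter sequences are
#' right-padded with all-zero columns. Letters outside \{A,C,G,T,N\} (after
#' uppercasing) map to N with a warning.
#'
#' @param seqs A [Biostrings::DNAStringSet] or character vector.
#' @return A numeric array of dimension `5 x m x n` with dimnames on the
#'   first margin; class `onehot_tensor`.
#' @export
one_hot <- function(seqs) {
  chr <- if (is.character(seqs)) toupper(seqs) else toupper(as.character(seqs))
  if (length(chr) == 0L) stop("need at least one sequence")
  n <- length(chr)
  m <- max(nchar(chr))
  X <- array(0, dim = c(5L, m, n),
             dimnames = list(onehot_rows, NULL, names(seqs)))
  warned <- FALSE
  for (i in seq_len(n)) {
    ch <- strsplit(chr[i], "", fixed = TRUE)[[1L]]
    idx <- match(ch, onehot_rows)
    if (anyNA(idx)) {
      if (!warned) {
        warning("letters outside {A,C,G,T,N} mapped to N")
        warned <- TRUE
      }
      idx[is.na(idx)] <- 5L
    }
    if (length(idx))
      X[cbind(idx, seq_along(idx), i)] <- 1
  }
  class(X) <- c("onehot_tensor", class(X))
  X
}

#' Decode a one-hot tensor back to sequences
#'
#' Argmax over non-zero columns; all-zero (padding) columns are dropped.
#'
#' @param X An array produced by [one_hot()].
#' @return Character vector of sequences.
#' @export
decode_one_hot <- function(X) {
  vapply(seq_len(dim(X)[3L]), function(i) {
    M <- X[, , i, drop = FALSE][, , 1L]
    keep <- colSums(M) > 0
    paste(onehot_rows[apply(M[, keep, drop = FALSE], 2L, which.max)],
          collapse = "")
  }, character(1))
}

#' Per-feature standardization
#'
#' `fit_scaler` learns per-column means and standard deviations on the
#' training partition only; `apply_scaler` standardizes new data with them.
#' Zero-variance columns pass through unchanged.
#'
#' @param X Numeric matrix (rows = records).
#' @return `fit_scaler`: an object of class `feature_scaler`;
#'   `apply_scaler`: the transformed matrix.
#' @export
fit_scaler <- function(X) {
  stopifnot(is.matrix(X), nrow(X) >= 1L)
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  if (nrow(X) == 1L) sd <- rep(0, ncol(X))
  zero <- !is.finite(sd) | sd == 0
  mu[zero] <- 0
  sd[zero] <- 1
  structure(list(center = mu, scale = sd, d = ncol(X)),
            class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param scaler A fitted `feature_scaler`.
#' @export
apply_scaler <- function(scaler, X) {
  if (!inherits(scaler, "feature_scaler"))
    stop("scaler has not been fitted (expected a 'feature_scaler')")
  stopifnot(ncol(X) == scaler$d)
  sweep(sweep(X, 2L, scaler$center, "-"), 2L, scaler$scale, "/")
}

#' PCA reduction to a target explained variance
#'
#' `fit_pca` (training partition only) retains the smallest number of
#' leading principal components whose cumulative explained-variance ratio
#' reaches the target (default 96%); `apply_pca` projects new data.
#'
#' @param X Numeric matrix, at least 2 rows.
#' @param target_variance Fraction in (0, 1].
#' @return `fit_pca`: an object of class `pca_model` with `center`,
#'   `rotation`, `n_components`, `explained_ratio` (per retained component)
#'   and `retained_variance`; `apply_pca`: the projected matrix.
#' @export
fit_pca <- function(X, target_variance = 0.96) {
  if (!(target_variance > 0 && target_variance <= 1))
    stop("target_variance must be in (0, 1]")
  stopifnot(is.matrix(X), nrow(X) >= 2L)
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  var <- pr$sdev^2
  ratio <- var / sum(var)
  cum <- cumsum(ratio)
  ncomp <- which(cum >= target_variance - 1e-12)[1L]
  if (is.na(ncomp)) ncomp <- length(ratio)
  structure(list(center = pr$center,
                 rotation = pr$rotation[, seq_len(ncomp), drop = FALSE],
                 n_components = ncomp,
                 explained_ratio = ratio[seq_len(ncomp)],
                 retained_variance = cum[ncomp],
                 target_variance = target_variance,
                 d = ncol(X)),
            class = "pca_model")
}

#' @rdname fit_pca
#' @param model A fitted `pca_model`.
#' @export
apply_pca <- function(model, X) {
  if (!inherits(model, "pca_model"))
    stop("PCA model has not been fitted (expected a 'pca_model')")
  stopifnot(ncol(X) == model$d)
  sweep(X, 2L, model$center, "-") %*% model$rotation
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d -> %d components (%.2f%% variance retained)\n",
              x$d, x$n_components, 100 * x$retained_variance))
  invisible(x)
}
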