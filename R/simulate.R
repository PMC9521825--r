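#' @title Synthetic LTR retrotransposon simulator
#' @description
#' Generators for labelled synthetic LTR-RT sequences with ground truth that
#' the rule-based curation filters can recover exactly:
#' class 0 intact elements, class 1 cross-superfamily nested insertions,
#' class 2 cross-lineage nested insertions, class 3 length anomalies, and
#' class 4 Class II (TIR transposon) insertions.
#'
#' The `simulate_*` functions draw from the R session RNG; seed the stream
#' (or use [generate_dataset()], which seeds it for you) for reproducibility.
#' @name simulate
NULL

# i.i.d. random DNA with a given GC fraction
rand_dna <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# DNA from a first-order Markov composition profile (inverse-CDF stepping
# over precomputed cumulative rows)
markov_dna <- function(n, trans) {
  if (n <= 0L) return("")
  cum <- t(apply(trans, 1L, cumsum))
  bases <- c("A", "C", "G", "T")
  out <- integer(n)
  u <- stats::runif(n)
  # start from the profile's average composition
  out[1L] <- findInterval(u[1L], cumsum(colMeans(trans))) + 1L
  for (i in seq_len(n - 1L))
    out[i + 1L] <- findInterval(u[i + 1L], cum[out[i], ]) + 1L
  out[out > 4L] <- 4L
  paste(bases[out], collapse = "")
}

lineage_dna <- function(n, spec) markov_dna(n, spec$trans)

#' Composition profile of the Class II (TIR transposon) cargo
#'
#' A fixed first-order Markov profile for the DNA-transposon interior
#' (transposase-like coding sequence): AT-biased with CpG depletion,
#' rescaled to a target GC. Real Class II families carry oligonucleotide
#' signatures as distinctive as LTR-RT lineages do; this fixed profile
#' plays that role for every simulated Class II insertion.
#'
#' @param gc Target GC fraction of the cargo.
#' @return A 4x4 stochastic matrix (A, C, G, T order).
#' @export
default_class2_profile <- function(gc = 0.40) {
  bias <- rbind(c(1.6, 0.7, 1.1, 0.8),
                c(1.2, 1.3, 0.4, 1.3),   # C->G depleted (CpG avoidance)
                c(1.0, 1.4, 1.2, 0.6),
                c(0.7, 0.9, 1.3, 1.3))
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  t(apply(bias, 1L, function(b) { w <- b * p; w / sum(w) }))
}

# minimum internal-region length needed to hold the 5 domain motifs with at
# least 1 bp of spacer on each side of each motif
min_internal_len <- function(spec) {
  sum(nchar(spec$domain_motifs)) + 6L
}

# Build the internal region: spacers interleaved with the ordered domain
# motifs, total length exactly `len`.
build_internal <- function(spec, len) {
  motifs <- spec$domain_motifs
  slack <- len - sum(nchar(motifs))
  stopifnot(slack >= 6L)
  # split slack into 6 spacers, each >= 1 bp (composition via 5 distinct cuts)
  cuts <- sort(sample.int(slack - 1L, 5L))
  sizes <- as.integer(diff(c(0L, cuts, slack)))
  stopifnot(sum(sizes) == slack, all(sizes >= 1L))
  parts <- character(11L)
  parts[seq(1, 11, by = 2)] <- vapply(sizes, lineage_dna, character(1),
                                      spec = spec)
  parts[seq(2, 10, by = 2)] <- motifs
  paste(parts, collapse = "")
}

#' Simulate one intact LTR retrotransposon
#'
#' The element is `LTR + internal + LTR` with the two LTRs identical, the
#' five lineage domain motifs present exactly once each in the superfamily's
#' domain order, and a total length drawn uniformly from the lineage's
#' length interval.
#'
#' @param spec A [lineage_spec()].
#' @param total_len Optional fixed total length (bp); default drawn uniformly
#'   from `spec$total_len_range`.
#' @return A list with `seq` (character), `lineage`, `superfamily`,
#'   `ltr_len`, `label = 0L`.
#' @export
simulate_intact <- function(spec, total_len = NULL) {
  stopifnot(inherits(spec, "lineage_spec"))
  if (is.null(total_len)) {
    total_len <- sample(spec$total_len_range[1]:spec$total_len_range[2], 1L)
  }
  total_len <- as.integer(total_len)
  # LTR short enough that the internal region can hold all motifs
  ltr_max <- min(spec$ltr_len_range[2],
                 (total_len - min_internal_len(spec)) %/% 2L)
  stopifnot(ltr_max >= spec$ltr_len_range[1])
  ltr_len <- sample(spec$ltr_len_range[1]:ltr_max, 1L)
  ltr <- lineage_dna(ltr_len, spec)
  internal <- build_internal(spec, total_len - 2L * ltr_len)
  list(seq = paste0(ltr, internal, ltr),
       lineage = spec$name, superfamily = spec$superfamily,
       ltr_len = ltr_len, label = 0L,
       note = sprintf("intact lineage=%s", spec$name))
}

# insert `insert` at a uniform-random breakpoint strictly inside the host's
# internal region; returns list(seq, pos)
insert_internal <- function(host, insert) {
  n <- nchar(host$seq)
  lo <- host$ltr_len + 1L
  hi <- n - host$ltr_len - 1L
  stopifnot(hi >= lo)
  pos <- sample(lo:hi, 1L)   # insertion after base `pos`
  list(seq = paste0(substr(host$seq, 1L, pos), insert,
                    substr(host$seq, pos + 1L, n)),
       pos = pos)
}

#' Simulate a nested LTR-RT insertion
#'
#' A full intact donor element is inserted at a uniform-random breakpoint
#' strictly inside the host's internal region (never inside an LTR). Ground
#' truth is class 1 when host and donor superfamilies differ, class 2 when
#' they share a superfamily but differ in lineage.
#'
#' @param host,donor [lineage_spec()] objects; must differ.
#' @return A list with `seq`, `label` (1 or 2), host/donor metadata and the
#'   insertion breakpoint.
#' @export
simulate_nested <- function(host, donor) {
  stopifnot(inherits(host, "lineage_spec"), inherits(donor, "lineage_spec"))
  if (identical(host$name, donor$name))
    stop("host and donor lineage must differ")
  h <- simulate_intact(host)
  d <- simulate_intact(donor)
  ins <- insert_internal(h, d$seq)
  label <- if (!identical(host$superfamily, donor$superfamily)) 1L else 2L
  list(seq = ins$seq, lineage = host$name, superfamily = host$superfamily,
       ltr_len = h$ltr_len, label = label,
       donor = donor$name, breakpoint = ins$pos,
       note = sprintf("nested host=%s donor=%s pos=%d",
                      host$name, donor$name, ins$pos))
}

#' Simulate a length-anomalous element
#'
#' An otherwise intact single-lineage element padded (inside the internal
#' region, with motif-free background of the lineage's own composition) so
#' that its total length exceeds the lineage maximum by more than the length
#' filter's tolerance. Ground truth is class 3.
#'
#' @param spec A [lineage_spec()].
#' @param tolerance Length-filter tolerance fraction (default 0.20); the
#'   emitted length exceeds `max(total_len_range) * (1 + tolerance)`.
#' @return A list with `seq`, `label = 3L` and metadata.
#' @export
simulate_length_anomaly <- function(spec, tolerance = 0.20) {
  base <- simulate_intact(spec)
  mx <- spec$total_len_range[2]
  target_min <- floor(mx * (1 + tolerance)) + 1L
  target_max <- ceiling(mx * (1 + tolerance + 0.15))
  target <- sample(target_min:target_max, 1L)
  pad_len <- target - nchar(base$seq)
  # pad with the lineage's own composition: a length anomaly is (by
  # construction) compositionally indistinguishable from an intact element
  ins <- insert_internal(base, lineage_dna(pad_len, spec))
  list(seq = ins$seq, lineage = spec$name, superfamily = spec$superfamily,
       ltr_len = base$ltr_len, label = 3L, breakpoint = ins$pos,
       note = sprintf("length_anomaly lineage=%s pad=%d", spec$name, pad_len))
}

#' Simulate a Class II (TIR transposon) insertion
#'
#' A TIR-flanked segment (`motif + spacer + reverse-complement motif`) is
#' inserted into the internal region of an intact element. The base element
#' is drawn short enough that the final length stays within the lineage
#' length interval, so only the Class II filter fires. Ground truth is
#' class 4.
#'
#' @param spec A [lineage_spec()].
#' @param tir_motifs List with `left`/`right` motif strings
#'   (default [default_tir_motifs()]).
#' @param spacer_range Integer pair: cargo length range between the TIRs
#'   (autonomous DNA-transposon interiors, transposase-scale).
#' @param gc Target GC of the cargo profile
#'   (see [default_class2_profile()]).
#' @return A list with `seq`, `label = 4L` and metadata, including the
#'   inserted segment's coordinates (`insert_start`, `insert_end`, 1-based
#'   inclusive) so the insertion can be spliced back out.
#' @export
simulate_class2_insertion <- function(spec, tir_motifs = default_tir_motifs(),
                                      spacer_range = c(1500L, 3000L),
                                      gc = 0.40) {
  insert_max <- nchar(tir_motifs$left) + nchar(tir_motifs$right) +
    spacer_range[2]
  hi <- spec$total_len_range[2] - insert_max
  stopifnot(hi >= spec$total_len_range[1])
  base <- simulate_intact(spec, total_len = sample(spec$total_len_range[1]:hi, 1L))
  spacer <- markov_dna(sample(spacer_range[1]:spacer_range[2], 1L),
                       default_class2_profile(gc))
  segment <- paste0(tir_motifs$left, spacer, tir_motifs$right)
  ins <- insert_internal(base, segment)
  list(seq = ins$seq, lineage = spec$name, superfamily = spec$superfamily,
       ltr_len = base$ltr_len, label = 4L,
       insert_start = ins$pos + 1L, insert_end = ins$pos + nchar(segment),
       note = sprintf("class2 lineage=%s pos=%d len=%d",
                      spec$name, ins$pos, nchar(segment)))
}

#' Simulation configuration
#'
#' @param n_per_class Integer vector of length 5: number of records for
#'   classes 0..4.
#' @param seed Integer seed.
#' @param gc_content Background GC for Class II cargo segments.
#' @param class2_motifs TIR motif pair (see [default_tir_motifs()]).
#' @param length_tolerance Length-filter tolerance fraction in (0, 1).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_per_class = c(50L, 30L, 5L, 8L, 2L), seed = 1L,
                       gc_content = 0.40,
                       class2_motifs = default_tir_motifs(),
                       length_tolerance = 0.20) {
  n_per_class <- as.integer(n_per_class)
  stopifnot(length(n_per_class) == 5L, all(n_per_class >= 0L),
            length_tolerance > 0, length_tolerance < 1)
  structure(list(n_per_class = n_per_class, seed = as.integer(seed),
                 gc_content = gc_content, class2_motifs = class2_motifs,
                 length_tolerance = length_tolerance),
            class = "sim_config")
}

#' Class counts matching the reference dataset's imbalance
#'
#' Splits `n_total` across the five classes in the proportions of the
#' reference curation dataset (56442 : 33874 : 4734 : 8568 : 2039 for
#' classes 0..4), by largest-remainder rounding.
#'
#' @param n_total Total number of records.
#' @return Integer vector of length 5.
#' @export
imbalanced_counts <- function(n_total) {
  ref <- c(56442, 33874, 4734, 8568, 2039)
  p <- ref / sum(ref)
  raw <- p * n_total
  base <- floor(raw)
  rem <- n_total - sum(base)
  extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
  base[extra] <- base[extra] + 1
  as.integer(base)
}

#' Generate a labelled synthetic dataset
#'
#' Draws `n_per_class[c]` records for each class c in 0..4 from the given
#' lineage library, shuffles deterministically, and returns sequences,
#' labels and per-record provenance. Class 1 requires lineages from both
#' superfamilies; class 2 requires at least two lineages within one
#' superfamily.
#'
#' @param config A [sim_config()].
#' @param library A non-empty list of [lineage_spec()] objects.
#' @return An object of class `labeled_dataset`: list with `seqs`
#'   (named [Biostrings::DNAStringSet]), `labels` (integer vector) and
#'   `provenance` (data.frame).
#' @export
generate_dataset <- function(config, library) {
  stopifnot(inherits(config, "sim_config"))
  if (length(library) == 0) stop("lineage library must be non-empty")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  sfs <- vapply(library, `[[`, character(1), "superfamily")
  n <- config$n_per_class
  if (n[2] > 0 && length(unique(sfs)) < 2)
    stop("class 1 records require lineages from both superfamilies")
  if (n[3] > 0 && max(table(sfs)) < 2)
    stop("class 2 records require >= 2 lineages within a superfamily")

  pick <- function(cond) {
    cand <- library[cond]
    cand[[sample.int(length(cand), 1L)]]
  }
  recs <- vector("list", sum(n))
  i <- 0L
  for (cls in 0:4) {
    for (j in seq_len(n[cls + 1L])) {
      i <- i + 1L
      recs[[i]] <- switch(as.character(cls),
        "0" = simulate_intact(pick(TRUE)),
        "1" = {
          host <- pick(TRUE)
          donor <- pick(sfs != host$superfamily)
          simulate_nested(host, donor)
        },
        "2" = {
          # a superfamily with >= 2 lineages
          sf_ok <- names(which(table(sfs) >= 2))
          host <- pick(sfs %in% sf_ok)
          donor <- pick(sfs == host$superfamily &
                          vapply(library, `[[`, character(1), "name") != host$name)
          simulate_nested(host, donor)
        },
        "3" = simulate_length_anomaly(pick(TRUE), config$length_tolerance),
        "4" = simulate_class2_insertion(pick(TRUE),
                                        tir_motifs = config$class2_motifs,
                                        gc = config$gc_content))
    }
  }
  ord <- sample.int(length(recs))
  recs <- recs[ord]
  ids <- sprintf("LTRRT_%05d", seq_along(recs))
  seqs <- Biostrings::DNAStringSet(vapply(recs, `[[`, character(1), "seq"))
  names(seqs) <- ids
  labels <- vapply(recs, `[[`, integer(1), "label")
  prov <- data.frame(
    seq_id = ids,
    label = labels,
    lineage = vapply(recs, `[[`, character(1), "lineage"),
    note = vapply(recs, `[[`, character(1), "note"),
    stringsAsFactors = FALSE
  )
  structure(list(seqs = seqs, labels = labels, provenance = prov,
                 seed = config$seed),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d records; class counts: %s\n",
              length(x$seqs),
              paste(sprintf("%d=%d", 0:4, tabulate(x$labels + 1L, 5L)),
                    collapse = " ")))
  invisible(x)
}

#' Write a labelled dataset to FASTA + label TSV
#'
#' FASTA is wrapped at 60 columns; the TSV has columns
#' `seq_id<TAB>label` (no header).
#'
#' @param ds A `labeled_dataset`.
#' @param fasta,tsv Output paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_dataset <- function(ds, fasta, tsv) {
  stopifnot(inherits(ds, "labeled_dataset"))
  Biostrings::writeXStringSet(ds$seqs, fasta, width = 60L)
  utils::write.table(data.frame(names(ds$seqs), ds$labels),
                     tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(fasta = fasta, tsv = tsv))
}

#' Read sequences and (optionally) labels from disk
#'
#' @param fasta Path to a multi-FASTA of LTR-RT sequences (uppercased on
#'   read).
#' @param tsv Optional path to a 2-column `seq_id<TAB>label` TSV.
#' @return A `labeled_dataset` (labels `NA` when no TSV given).
#' @export
read_dataset <- function(fasta, tsv = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  labels <- rep(NA_integer_, length(seqs))
  if (!is.null(tsv)) {
    tab <- utils::read.table(tsv, sep = "\t", header = FALSE,
                             col.names = c("seq_id", "label"),
                             stringsAsFactors = FALSE)
    m <- match(names(seqs), tab$seq_id)
    if (anyNA(m)) {
      missing <- names(seqs)[is.na(m)][seq_len(min(5, sum(is.na(m))))]
      stop("label file is missing ids present in FASTA: ",
           paste(missing, collapse = ", "))
    }
    labels <- as.integer(tab$label[m])
  }
  structure(list(seqs = seqs, labels = labels,
                 provenance = data.frame(seq_id = names(seqs),
                                         label = labels,
                                         stringsAsFactors = FALSE)),
            class = "labeled_dataset")
}
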