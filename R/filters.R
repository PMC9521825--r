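#' @title Rule-based curation filters
#' @description
#' The conventional-bioinformatics arm of the curator: scan a sequence for
#' lineage domain markers and TIR pairs, then apply the four curation
#' filters — cross-superfamily nesting (1), cross-lineage nesting (2),
#' length anomaly beyond a 20% tolerance (3) and Class II insertion (4) —
#' to assign a class label, with 0 meaning intact. Labels 1-4 collapse to a
#' single "contaminated" class under [binarize()].
#' @name filters
NULL

#' Annotate domain and TIR hits in one sequence
#'
#' Reports every exact occurrence of every domain marker motif in the
#' lineage library (forward strand by default) and every TIR pair
#' (`motif ... revcomp(motif)` within `tir_span` bp). Coordinates are
#' 0-based half-open.
#'
#' @param seq A character string, [Biostrings::DNAString], or length-1
#'   [Biostrings::DNAStringSet].
#' @param library List of [lineage_spec()] objects.
#' @param class2_motifs TIR motif pair (list with `left`, `right`), or
#'   `NULL` to skip Class II detection.
#' @param tir_span Maximum distance (bp) from the start of the left TIR to
#'   the end of the right TIR for the two to be paired.
#' @param both_strands Also scan the reverse strand for domain motifs
#'   (default `FALSE`: the simulator emits forward-strand domains).
#' @param seq_id Identifier recorded in the annotation.
#' @return An object of class `element_annotation`: list with `seq_id`,
#'   `length`, `hits` (data.frame: domain, lineage, superfamily, start, end,
#'   strand) sorted by start, and `class2_hits` (data.frame: start, end).
#' @export
annotate_domains <- function(seq, library, class2_motifs = default_tir_motifs(),
                             tir_span = 4000L, both_strands = FALSE,
                             seq_id = "seq") {
  s <- as_single_dna(seq)
  if (length(s) == 0L)    # DNAString length = number of letters
    stop("sequence must be non-empty")
  ss <- Biostrings::DNAStringSet(s)
  names(ss) <- seq_id
  annotate_domain_set(ss, library, class2_motifs, tir_span, both_strands)[[1L]]
}

as_single_dna <- function(seq) {
  if (is.character(seq)) Biostrings::DNAString(toupper(seq))
  else if (inherits(seq, "DNAStringSet")) seq[[1L]]
  else if (inherits(seq, "DNAString")) seq
  else stop("unsupported sequence type")
}

#' Annotate a whole sequence set
#'
#' Vectorised form of [annotate_domains()]; one `element_annotation` per
#' input sequence.
#'
#' @inheritParams annotate_domains
#' @param seqs A named [Biostrings::DNAStringSet].
#' @return A list of `element_annotation` objects, named by sequence id.
#' @export
annotate_domain_set <- function(seqs, library,
                                class2_motifs = default_tir_motifs(),
                                tir_span = 4000L, both_strands = FALSE) {
  stopifnot(inherits(seqs, "DNAStringSet"))
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq_%d", seq_along(seqs))
  n <- length(seqs)
  hit_tabs <- rep(list(NULL), n)

  scan_motif <- function(motif, domain, lineage, superfamily, strand) {
    hits <- Biostrings::vmatchPattern(motif, seqs, fixed = TRUE)
    for (i in seq_len(n)) {
      r <- hits[[i]]
      if (length(r) == 0L) next
      df <- data.frame(domain = domain, lineage = lineage,
                       superfamily = superfamily,
                       start = IRanges::start(r) - 1L,
                       end = IRanges::end(r),
                       strand = strand, stringsAsFactors = FALSE)
      hit_tabs[[i]] <<- rbind(hit_tabs[[i]], df)
    }
  }
  for (spec in library) {
    for (d in names(spec$domain_motifs)) {
      scan_motif(spec$domain_motifs[[d]], d, spec$name, spec$superfamily, "+")
      if (both_strands)
        scan_motif(revcomp_chr(spec$domain_motifs[[d]]), d, spec$name,
                   spec$superfamily, "-")
    }
  }

  # TIR pairs: each left-motif occurrence paired with the nearest
  # right-motif (revcomp) occurrence starting after it, within tir_span
  empty_c2 <- data.frame(start = integer(0), end = integer(0))
  c2_tabs <- rep(list(empty_c2), n)
  if (!is.null(class2_motifs)) {
    lhits <- Biostrings::vmatchPattern(class2_motifs$left, seqs, fixed = TRUE)
    rhits <- Biostrings::vmatchPattern(class2_motifs$right, seqs, fixed = TRUE)
    for (i in seq_len(n)) {
      ls <- IRanges::start(lhits[[i]]); re <- IRanges::end(rhits[[i]])
      if (length(ls) == 0L || length(re) == 0L) next
      pairs <- NULL
      for (st in ls) {
        cand <- re[re > st + nchar(class2_motifs$left) &
                     re - st + 1L <= tir_span]
        if (length(cand))
          pairs <- rbind(pairs, c(st - 1L, min(cand)))
      }
      if (!is.null(pairs))
        c2_tabs[[i]] <- data.frame(start = pairs[, 1], end = pairs[, 2])
    }
  }

  empty_hits <- data.frame(domain = character(0), lineage = character(0),
                           superfamily = character(0), start = integer(0),
                           end = integer(0), strand = character(0),
                           stringsAsFactors = FALSE)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    h <- hit_tabs[[i]]
    h <- if (is.null(h)) empty_hits else h[order(h$start), , drop = FALSE]
    rownames(h) <- NULL
    out[[i]] <- structure(
      list(seq_id = names(seqs)[i], length = Biostrings::width(seqs)[i],
           hits = h, class2_hits = c2_tabs[[i]]),
      class = "element_annotation")
  }
  names(out) <- names(seqs)
  out
}

#' @export
print.element_annotation <- function(x, ...) {
  cat(sprintf("<element_annotation> %s (%d bp): %d domain hits, %d TIR pairs\n",
              x$seq_id, x$length, nrow(x$hits), nrow(x$class2_hits)))
  invisible(x)
}

#' Assign a curation label from an annotation
#'
#' First-match-wins cascade over the four filters, in the order
#' cross-superfamily (1) -> cross-lineage (2) -> Class II (4) -> length (3),
#' so structural contamination outranks the length symptom it causes:
#' \itemize{
#'   \item label 1 if the domain hits span two or more superfamilies;
#'   \item else label 2 if they span two or more lineages;
#'   \item else label 4 if any TIR pair was found;
#'   \item else label 3 if the element length falls outside the hit
#'     lineage's interval widened by `tolerance` (symmetric by default;
#'     `one_sided = TRUE` tests only the upper bound);
#'   \item else label 0 (intact).
#' }
#' Elements with zero domain hits are reported as unclassifiable
#' (`value = NA`, `status = "unclassifiable"`), never silently labelled.
#'
#' @param ann An `element_annotation`.
#' @param library The lineage library (source of length intervals).
#' @param tolerance Length tolerance fraction (default 0.20).
#' @param one_sided If `TRUE`, only a length increase beyond
#'   `max * (1 + tolerance)` triggers label 3.
#' @return An object of class `curation_label`: list with `value`
#'   (integer 0..4 or `NA`), `binary` (0/1 or `NA`) and `status`.
#' @export
assign_label <- function(ann, library, tolerance = 0.20, one_sided = FALSE) {
  stopifnot(inherits(ann, "element_annotation"),
            tolerance > 0, tolerance < 1)
  h <- ann$hits
  if (nrow(h) == 0L)
    return(structure(list(value = NA_integer_, binary = NA_integer_,
                          status = "unclassifiable"),
                     class = "curation_label"))
  value <- if (length(unique(h$superfamily)) >= 2L) 1L
    else if (length(unique(h$lineage)) >= 2L) 2L
    else if (nrow(ann$class2_hits) > 0L) 4L
    else {
      spec <- library[[h$lineage[1L]]]
      if (is.null(spec))
        stop("lineage ", h$lineage[1L], " not present in library")
      rng <- spec$total_len_range
      lo <- if (one_sided) -Inf else rng[1L] * (1 - tolerance)
      hi <- rng[2L] * (1 + tolerance)
      if (ann$length < lo || ann$length > hi) 3L else 0L
    }
  structure(list(value = value, binary = binarize(value),
                 status = "classified"),
            class = "curation_label")
}

#' @export
print.curation_label <- function(x, ...) {
  cat(sprintf("<curation_label> value=%s binary=%s (%s)\n",
              x$value, x$binary, x$status))
  invisible(x)
}

#' Binarize a curation label
#'
#' Intact (0) maps to 0; every contamination class (1-4) maps to 1.
#'
#' @param label A `curation_label`, or an integer vector of class values.
#' @return Integer 0/1 (NA preserved).
#' @export
binarize <- function(label) {
  v <- if (inherits(label, "curation_label")) label$value else label
  stopifnot(all(v %in% c(0:4, NA)))
  ifelse(is.na(v), NA_integer_, as.integer(v != 0L))
}

#' Label a sequence set with the rule-based filters
#'
#' Runs [annotate_domain_set()] then [assign_label()] over a set of
#' sequences.
#'
#' @inheritParams annotate_domain_set
#' @inheritParams assign_label
#' @return A data.frame with columns `seq_id`, `label`, `binary`, `status`.
#' @export
label_sequences <- function(seqs, library,
                            class2_motifs = default_tir_motifs(),
                            tolerance = 0.20, tir_span = 4000L,
                            one_sided = FALSE, both_strands = FALSE) {
  anns <- annotate_domain_set(seqs, library, class2_motifs, tir_span,
                              both_strands)
  labs <- lapply(anns, assign_label, library = library,
                 tolerance = tolerance, one_sided = one_sided)
  data.frame(
    seq_id = vapply(anns, `[[`, character(1), "seq_id"),
    label = vapply(labs, `[[`, integer(1), "value"),
    binary = vapply(labs, `[[`, integer(1), "binary"),
    status = vapply(labs, `[[`, character(1), "status"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Export an annotation report
#'
#' Writes one row per domain hit (`seq_id`, `domain`, `lineage`,
#' `superfamily`, `start`, `end`, `strand`; 0-based half-open coordinates).
#'
#' @param anns List of `element_annotation` objects.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_annotation_report <- function(anns, path) {
  rows <- lapply(anns, function(a) {
    if (nrow(a$hits) == 0L) return(NULL)
    cbind(seq_id = a$seq_id, a$hits)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(seq_id = character(0), domain = character(0),
                      lineage = character(0), superfamily = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
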