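#' Lineage specification for synthetic LTR retrotransposons
#'
#' A `lineage_spec` describes one LTR-RT lineage: its superfamily, the length
#' interval of its LTRs, the total-element length interval used by the length
#' filter, an ordered set of protein-domain marker motifs, and a lineage-level
#' base composition (GC fraction). Domain order follows plant LTR-RT
#' convention: Copia elements carry GAG-AP-INT-RT-RH, Gypsy elements
#' GAG-AP-RT-RH-INT.
#'
#' @param name Lineage identifier, e.g. `"RLC_A"`.
#' @param superfamily `"COPIA"` or `"GYPSY"`.
#' @param ltr_len_range Integer pair: min/max LTR length (bp).
#' @param total_len_range Integer pair: min/max total element length (bp);
#'   this is the interval the length filter tests against.
#' @param domain_motifs Named character vector of marker motifs, names in
#'   the superfamily's domain order.
#' @param gc Target lineage body GC fraction in (0, 1).
#' @param trans Optional 4x4 first-order Markov transition matrix
#'   (rows/cols in A, C, G, T order, rows summing to 1) describing the
#'   lineage's oligonucleotide composition; defaults to the i.i.d. chain at
#'   the given GC. Distinct per-lineage transition profiles are what give
#'   real lineages their characteristic k-mer signatures.
#' @return An object of class `lineage_spec`.
#' @export
lineage_spec <- function(name, superfamily, ltr_len_range, total_len_range,
                         domain_motifs, gc = 0.5, trans = NULL) {
  superfamily <- match.arg(toupper(superfamily), c("GYPSY", "COPIA"))
  ltr_len_range <- as.integer(ltr_len_range)
  total_len_range <- as.integer(total_len_range)
  stopifnot(
    length(ltr_len_range) == 2L, ltr_len_range[1] <= ltr_len_range[2],
    length(total_len_range) == 2L, total_len_range[1] <= total_len_range[2],
    gc > 0, gc < 1
  )
  if (total_len_range[1] < 2L * ltr_len_range[1])
    stop("total_len_range min must be >= 2 * ltr_len_range min")
  expected <- domain_order(superfamily)
  if (!identical(names(domain_motifs), expected))
    stop("domain_motifs must be named ", paste(expected, collapse = "-"),
         " for superfamily ", superfamily)
  if (anyDuplicated(domain_motifs))
    stop("domain motifs within a lineage must be distinct")
  if (is.null(trans)) {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    trans <- matrix(p, 4L, 4L, byrow = TRUE)
  }
  trans <- as.matrix(trans)
  dimnames(trans) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  if (!all(dim(trans) == c(4L, 4L)) || any(trans < 0) ||
      any(abs(rowSums(trans) - 1) > 1e-6))
    stop("trans must be a 4x4 stochastic matrix")
  structure(
    list(name = name, superfamily = superfamily,
         ltr_len_range = ltr_len_range, total_len_range = total_len_range,
         domain_motifs = domain_motifs, gc = gc, trans = trans),
    class = "lineage_spec"
  )
}

#' @export
print.lineage_spec <- function(x, ...) {
  cat(sprintf("<lineage_spec> %s (%s)  LTR %d-%d bp  total %d-%d bp  GC %.2f\n",
              x$name, x$superfamily,
              x$ltr_len_range[1], x$ltr_len_range[2],
              x$total_len_range[1], x$total_len_range[2], x$gc))
  invisible(x)
}

# Internal domain order per superfamily (Copia: INT before RT; Gypsy: RT-RH
# before INT).
domain_order <- function(superfamily) {
  switch(superfamily,
         COPIA = c("GAG", "AP", "INT", "RT", "RH"),
         GYPSY = c("GAG", "AP", "RT", "RH", "INT"),
         stop("unknown superfamily: ", superfamily))
}

#' Generate a library of synthetic lineage specifications
#'
#' Creates `2 * n_lineages_per_superfamily` lineage specs (half Gypsy, half
#' Copia) with distinct marker motifs and staggered length intervals and base
#' compositions. Motifs are random fixed strings (default 24 bp), resampled
#' until no motif is a substring of any other across the whole library
#' (including the default TIR motif used for Class II insertions), so that
#' the rule-based filters can recover ground truth exactly.
#'
#' @param n_lineages_per_superfamily Number of lineages per superfamily
#'   (>= 1).
#' @param seed Integer seed; the library is deterministic given the seed.
#' @param motif_len Length of each domain marker motif (bp).
#' @return A named list of [lineage_spec()] objects.
#' @export
make_lineage_library <- function(n_lineages_per_superfamily, seed = 1L,
                                 motif_len = 24L) {
  if (!is.numeric(n_lineages_per_superfamily) ||
      n_lineages_per_superfamily < 1)
    stop("n_lineages_per_superfamily must be >= 1")
  n <- as.integer(n_lineages_per_superfamily)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  n_motifs <- 2L * n * 5L
  motifs <- sample_disjoint_motifs(n_motifs, motif_len,
                                   reserved = unlist(default_tir_motifs()))
  specs <- vector("list", 2L * n)
  # each lineage gets its own Markov composition profile drawn around a
  # common base composition, giving lineages distinct k-mer signatures in
  # general position (real LTR-RT lineages differ in oligonucleotide usage
  # far more than in gross GC); length intervals are staggered so the
  # length filter is lineage-specific
  gcs <- rep(0.5, 2L * n)
  idx <- 0L
  for (sf in c("COPIA", "GYPSY")) {
    for (i in seq_len(n)) {
      idx <- idx + 1L
      nm <- sprintf("%s_%s", if (sf == "COPIA") "RLC" else "RLG", LETTERS[i])
      total_min <- 4000L + 500L * ((idx - 1L) %% 4L)
      total_max <- total_min + 4000L
      dm <- motifs[(idx - 1L) * 5L + 1:5]
      names(dm) <- domain_order(sf)
      specs[[idx]] <- lineage_spec(
        name = nm, superfamily = sf,
        ltr_len_range = c(200L, 450L),
        total_len_range = c(total_min, total_max),
        domain_motifs = dm,
        gc = gcs[idx],
        trans = sample_markov_profile(gcs[idx], concentration = 8)
      )
    }
  }
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

# Draw a random first-order Markov transition profile centred on the base
# distribution implied by a GC target: each row is a Dirichlet draw with
# mean equal to that distribution. Lower concentration = more distinctive
# lineage signatures.
sample_markov_profile <- function(gc, concentration = 8) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  t(vapply(1:4, function(i) {
    g <- stats::rgamma(4L, shape = p * concentration)
    g / sum(g)
  }, numeric(4)))
}

# Sample `n` random DNA motifs of length `len` such that no motif (nor any
# reserved string) is a substring of another; resample offenders.
sample_disjoint_motifs <- function(n, len, reserved = character()) {
  ok <- function(cand, pool) {
    all(vapply(pool, function(p)
      !grepl(cand, p, fixed = TRUE) && !grepl(p, cand, fixed = TRUE),
      logical(1)))
  }
  pool <- reserved
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      cand <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                    collapse = "")
      if (ok(cand, pool)) break
    }
    out[i] <- cand
    pool <- c(pool, cand)
  }
  out
}

#' Default TIR motif pair marking Class II (DNA transposon) insertions
#'
#' A terminal-inverted-repeat motif and its reverse complement; a Class II
#' insertion is simulated (and detected) as `motif ... revcomp(motif)`.
#' @return List with elements `left` and `right`.
#' @export
default_tir_motifs <- function() {
  left <- "TACGGTTGCAAGCCATGCAT"
  list(left = left, right = revcomp_chr(left))
}

# reverse complement of a plain character string
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Write / read a lineage library as YAML
#'
#' @param library A list of [lineage_spec()] objects.
#' @param path Output / input YAML file path.
#' @return `write_lineage_library` returns `path` invisibly;
#'   `read_lineage_library` returns the list of specs.
#' @export
write_lineage_library <- function(library, path) {
  stopifnot(length(library) > 0)
  x <- lapply(library, function(s) {
    list(name = s$name, superfamily = s$superfamily,
         ltr_len_range = as.integer(s$ltr_len_range),
         total_len_range = as.integer(s$total_len_range),
         domain_motifs = as.list(s$domain_motifs),
         gc = s$gc,
         trans = lapply(seq_len(4), function(i) unname(s$trans[i, ])))
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_lineage_library
#' @export
read_lineage_library <- function(path) {
  x <- yaml::read_yaml(path)
  specs <- lapply(x, function(s) {
    lineage_spec(s$name, s$superfamily,
                 unlist(s$ltr_len_range), unlist(s$total_len_range),
                 unlist(s$domain_motifs), s$gc,
                 trans = do.call(rbind, s$trans))
  })
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

# save/restore the global RNG state so seeded helpers do not perturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
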