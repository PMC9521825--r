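# Synthetic LTR-RT generator: library invariants, per-class constructions,
# determinism, and ground-truth recoverability.

test_that("lineage library satisfies its structural invariants", {
  lib <- make_lineage_library(1, seed = 7)
  expect_length(lib, 2L)
  expect_setequal(vapply(lib, `[[`, character(1), "superfamily"),
                  c("GYPSY", "COPIA"))
  expect_true(all(vapply(lib, function(s) length(s$domain_motifs) == 5L,
                         logical(1))))
  motifs <- unlist(lapply(lib, `[[`, "domain_motifs"), use.names = FALSE)
  expect_length(unique(motifs), 10L)

  # brute-force all-pairs substring scan, including the TIR motifs
  all_m <- c(motifs, unlist(default_tir_motifs()))
  for (i in seq_along(all_m)) for (j in seq_along(all_m)) {
    if (i == j) next
    expect_false(grepl(all_m[i], all_m[j], fixed = TRUE),
                 info = sprintf("motif %d inside motif %d", i, j))
  }

  # domain order: Copia GAG-AP-INT-RT-RH, Gypsy GAG-AP-RT-RH-INT
  cop <- lib[[which(vapply(lib, `[[`, character(1), "superfamily") == "COPIA")]]
  gyp <- lib[[which(vapply(lib, `[[`, character(1), "superfamily") == "GYPSY")]]
  expect_identical(names(cop$domain_motifs), c("GAG", "AP", "INT", "RT", "RH"))
  expect_identical(names(gyp$domain_motifs), c("GAG", "AP", "RT", "RH", "INT"))
  expect_true(all(vapply(lib, function(s)
    s$total_len_range[1] >= 2L * s$ltr_len_range[1], logical(1))))
})

test_that("library generation is deterministic and rejects bad n", {
  expect_identical(make_lineage_library(3, seed = 7),
                   make_lineage_library(3, seed = 7))
  expect_false(identical(make_lineage_library(3, seed = 7),
                         make_lineage_library(3, seed = 8)))
  expect_error(make_lineage_library(0), "must be >= 1")
})

test_that("intact elements have identical LTRs, in-range length, 5 ordered motifs", {
  lib <- tiny_library()
  set.seed(11)
  for (spec in lib[c(1, 3)]) {
    el <- simulate_intact(spec)
    n <- nchar(el$seq)
    expect_gte(n, spec$total_len_range[1])
    expect_lte(n, spec$total_len_range[2])
    expect_identical(substr(el$seq, 1, el$ltr_len),
                     substr(el$seq, n - el$ltr_len + 1L, n))
    ann <- annotate_domains(el$seq, lib)
    expect_identical(nrow(ann$hits), 5L)
    expect_identical(unique(ann$hits$lineage), spec$name)
    # hits sorted by start implies the spec's domain order was emitted
    expect_identical(ann$hits$domain, names(spec$domain_motifs))
    expect_identical(nrow(ann$class2_hits), 0L)
  }
})

test_that("nesting conserves bases and ground-truth labels follow superfamily", {
  lib <- tiny_library()
  sfs <- vapply(lib, `[[`, character(1), "superfamily")
  cop <- lib[sfs == "COPIA"]; gyp <- lib[sfs == "GYPSY"]
  set.seed(13)
  cross <- simulate_nested(cop[[1]], gyp[[1]])
  expect_identical(cross$label, 1L)
  within <- simulate_nested(gyp[[1]], gyp[[2]])
  expect_identical(within$label, 2L)
  expect_error(simulate_nested(cop[[1]], cop[[1]]), "must differ")

  # |nested| = |host| + |donor|: regenerate parts under a fixed stream
  set.seed(99)
  h <- simulate_intact(cop[[1]]); d <- simulate_intact(gyp[[1]])
  set.seed(99)
  nested <- simulate_nested(cop[[1]], gyp[[1]])
  expect_identical(nchar(nested$seq), nchar(h$seq) + nchar(d$seq))
  # insertion lies strictly inside the host internal region
  expect_gt(nested$breakpoint, h$ltr_len)
  expect_lt(nested$breakpoint, nchar(h$seq) - h$ltr_len)
})

test_that("length anomalies exceed the tolerance bound but keep domain content", {
  lib <- tiny_library()
  spec <- lib[[1]]
  set.seed(17)
  for (i in 1:3) {
    el <- simulate_length_anomaly(spec, tolerance = 0.20)
    expect_gt(nchar(el$seq), spec$total_len_range[2] * 1.2)
    ann <- annotate_domains(el$seq, lib)
    expect_identical(nrow(ann$hits), 5L)
    expect_identical(unique(ann$hits$lineage), spec$name)
  }
})

test_that("Class II insertions carry a TIR pair and splice back to intact", {
  lib <- tiny_library()
  spec <- lib[[2]]
  tir <- default_tir_motifs()
  set.seed(19)
  el <- simulate_class2_insertion(spec)
  expect_true(grepl(tir$left, el$seq, fixed = TRUE))
  expect_true(grepl(tir$right, el$seq, fixed = TRUE))
  lab <- assign_label(annotate_domains(el$seq, lib), lib)
  expect_identical(lab$value, 4L)
  # length stays inside the tolerance window so only filter 4 fires
  expect_lte(nchar(el$seq), spec$total_len_range[2] * 1.2)

  # removing the inserted segment restores an intact (label 0) element
  spliced <- paste0(substr(el$seq, 1, el$insert_start - 1L),
                    substr(el$seq, el$insert_end + 1L, nchar(el$seq)))
  lab0 <- assign_label(annotate_domains(spliced, lib), lib)
  expect_identical(lab0$value, 0L)
})

test_that("generate_dataset honours counts, shuffles deterministically, writes FASTA", {
  lib <- tiny_library()
  cfg <- sim_config(n_per_class = c(10L, 10L, 10L, 10L, 10L), seed = 5)
  ds <- generate_dataset(cfg, lib)
  expect_length(ds$seqs, 50L)
  expect_identical(tabulate(ds$labels + 1L, 5L), rep(10L, 5L))
  expect_identical(names(ds$seqs), ds$provenance$seq_id)

  ds2 <- generate_dataset(cfg, lib)
  expect_identical(as.character(ds$seqs), as.character(ds2$seqs))

  f1 <- tempfile(fileext = ".fasta"); t1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".fasta"); t2 <- tempfile(fileext = ".tsv")
  write_dataset(ds, f1, t1); write_dataset(ds2, f2, t2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  back <- read_dataset(f1, t1)
  expect_identical(as.character(back$seqs), as.character(ds$seqs))
  expect_identical(back$labels, ds$labels)

  expect_error(generate_dataset(cfg, list()), "non-empty")
  expect_error(
    generate_dataset(sim_config(n_per_class = c(1L, 1L, 0L, 0L, 0L)),
                     mini_library()[1]),
    "both superfamilies")
})

test_that("reference imbalance proportions are reproduced by imbalanced_counts", {
  n <- imbalanced_counts(1000L)
  expect_identical(sum(n), 1000L)
  ref <- c(56442, 33874, 4734, 8568, 2039)
  expect_equal(n / 1000, ref / sum(ref), tolerance = 2e-3)
})

test_that("different seeds give different sequences", {
  lib <- tiny_library()
  a <- generate_dataset(sim_config(n_per_class = c(5L, 0L, 0L, 0L, 0L),
                                   seed = 1), lib)
  b <- generate_dataset(sim_config(n_per_class = c(5L, 0L, 0L, 0L, 0L),
                                   seed = 2), lib)
  expect_false(identical(as.character(a$seqs), as.character(b$seqs)))
})
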