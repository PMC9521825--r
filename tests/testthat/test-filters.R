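# Rule-based curation: domain scan, filter cascade, binarization.

test_that("annotate_domains reports motif and TIR occurrences with 0-based half-open coords", {
  lib <- tiny_library()
  spec <- lib[[1]]
  # hand-placed motif at a known offset
  pre <- strrep("A", 50)
  seq <- paste0(pre, spec$domain_motifs[["GAG"]], strrep("A", 30))
  ann <- annotate_domains(seq, lib)
  expect_identical(nrow(ann$hits), 1L)
  expect_identical(ann$hits$start, 50L)
  expect_identical(ann$hits$end, 50L + nchar(spec$domain_motifs[["GAG"]]))
  expect_identical(ann$hits$lineage, spec$name)

  # homopolymer: no hits at all
  ann0 <- annotate_domains(strrep("A", 200), lib)
  expect_identical(nrow(ann0$hits), 0L)

  # TIR pair detection
  tir <- default_tir_motifs()
  seq2 <- paste0(strrep("C", 40), tir$left, strrep("A", 100), tir$right,
                 strrep("C", 40))
  ann2 <- annotate_domains(seq2, lib)
  expect_identical(nrow(ann2$class2_hits), 1L)
  expect_identical(ann2$class2_hits$start, 40L)

  expect_error(annotate_domains("", lib), "non-empty")
})

test_that("filter cascade assigns labels in order 1 -> 2 -> 4 -> 3 -> 0", {
  lib <- tiny_library()
  rlc <- names(lib)[1]; rlg <- grep("RLG", names(lib), value = TRUE)

  # two superfamilies present -> 1, even with a TIR pair present
  ann1 <- fake_annotation(6000L,
                          rbind(fake_hit("RT", rlg[1], "GYPSY", 100L),
                                fake_hit("INT", rlc, "COPIA", 500L)),
                          class2 = data.frame(start = 10L, end = 300L))
  expect_identical(assign_label(ann1, lib)$value, 1L)

  # one superfamily, two lineages -> 2
  ann2 <- fake_annotation(6000L,
                          rbind(fake_hit("RT", rlg[1], "GYPSY", 100L),
                                fake_hit("RT", rlg[2], "GYPSY", 500L)))
  expect_identical(assign_label(ann2, lib)$value, 2L)

  # single lineage + TIR pair -> 4 even when the length is also anomalous
  ann4 <- fake_annotation(20000L,
                          fake_hit("RT", rlc, "COPIA", 100L),
                          class2 = data.frame(start = 10L, end = 300L))
  expect_identical(assign_label(ann4, lib)$value, 4L)

  # zero hits -> unclassifiable, not label 0
  ann_none <- fake_annotation(500L, NULL)
  lab <- assign_label(ann_none, lib)
  expect_identical(lab$status, "unclassifiable")
  expect_true(is.na(lab$value))
})

test_that("length filter boundary sits exactly at max * (1 + tolerance)", {
  lib <- tiny_library()
  spec <- lib[[1]]   # total_len_range 4000-8000
  expect_identical(spec$total_len_range, c(4000L, 8000L))
  at_bound <- fake_annotation(9600L, fake_hit("RT", spec$name, spec$superfamily))
  over <- fake_annotation(9601L, fake_hit("RT", spec$name, spec$superfamily))
  expect_identical(assign_label(at_bound, lib, tolerance = 0.20)$value, 0L)
  expect_identical(assign_label(over, lib, tolerance = 0.20)$value, 3L)

  # symmetric by default: a large deficit also fires
  short <- fake_annotation(3000L, fake_hit("RT", spec$name, spec$superfamily))
  expect_identical(assign_label(short, lib, tolerance = 0.20)$value, 3L)
  # one-sided mode ignores the deficit
  expect_identical(assign_label(short, lib, tolerance = 0.20,
                                one_sided = TRUE)$value, 0L)
})

test_that("raising the tolerance never converts intact into length-anomalous", {
  lib <- tiny_library()
  spec <- lib[[1]]
  set.seed(23)
  lens <- sample(3000:12000, 40)
  for (len in lens) {
    ann <- fake_annotation(len, fake_hit("RT", spec$name, spec$superfamily))
    tols <- c(0.05, 0.1, 0.2, 0.4, 0.6)
    labs <- vapply(tols, function(tl)
      assign_label(ann, lib, tolerance = tl)$value, integer(1))
    # monotone: once intact at some tolerance, intact at all larger ones
    if (any(labs == 0L)) {
      first0 <- which(labs == 0L)[1]
      expect_true(all(labs[first0:length(labs)] == 0L))
    }
  }
})

test_that("binarize maps 0 to 0 and every contamination class to 1", {
  expect_identical(binarize(0L), 0L)
  expect_identical(binarize(3L), 1L)
  expect_identical(binarize(c(0L, 1L, 2L, 3L, 4L)),
                   c(0L, 1L, 1L, 1L, 1L))
  expect_true(is.na(binarize(NA_integer_)))
  expect_error(binarize(7L))
})

test_that("assigned labels equal simulator ground truth on a mixed dataset", {
  lib <- tiny_library()
  ds <- tiny_dataset()
  labs <- label_sequences(ds$seqs, lib)
  expect_identical(labs$label, ds$labels)
  expect_identical(labs$binary, binarize(ds$labels))
  expect_true(all(labs$status == "classified"))
})

test_that("annotation report round-trips through TSV", {
  lib <- tiny_library()
  ds <- tiny_dataset()
  anns <- annotate_domain_set(ds$seqs[1:5], lib)
  path <- tempfile(fileext = ".tsv")
  write_annotation_report(anns, path)
  tab <- read.delim(path)
  expect_true(all(c("seq_id", "domain", "lineage", "start", "end")
                  %in% names(tab)))
  expect_identical(nrow(tab),
                   sum(vapply(anns, function(a) nrow(a$hits), integer(1))))
})
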