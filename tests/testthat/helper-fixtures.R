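# Shared fixtures, built in code. Cached per test-session environment so
# repeated calls across test files are cheap.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, build) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, build(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

tiny_library <- function() {
  fixture("lib2", function() make_lineage_library(2, seed = 7))
}

# one lineage per superfamily (minimal valid library)
mini_library <- function() {
  fixture("lib1", function() make_lineage_library(1, seed = 7))
}

# 55-record balanced-ish dataset over the tiny library
tiny_dataset <- function() {
  fixture("ds55", function()
    generate_dataset(sim_config(n_per_class = c(15L, 10L, 10L, 10L, 10L),
                                seed = 3), tiny_library()))
}

# hand-built annotation for filter cascade tests
fake_annotation <- function(length, hits, class2 = NULL, seq_id = "x") {
  empty <- data.frame(domain = character(0), lineage = character(0),
                      superfamily = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  h <- if (is.null(hits) || nrow(hits) == 0) empty
       else hits[order(hits$start), , drop = FALSE]
  c2 <- if (is.null(class2)) data.frame(start = integer(0), end = integer(0))
        else class2
  structure(list(seq_id = seq_id, length = length, hits = h,
                 class2_hits = c2),
            class = "element_annotation")
}

fake_hit <- function(domain, lineage, superfamily, start = 100L) {
  data.frame(domain = domain, lineage = lineage, superfamily = superfamily,
             start = start, end = start + 24L, strand = "+",
             stringsAsFactors = FALSE)
}
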