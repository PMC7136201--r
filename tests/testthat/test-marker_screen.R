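test_that("score cutoffs are model-specific and boundary-inclusive", {
  reg <- marker_registry(c(PolB = 30, VLTF3 = 25, MCP = 30, A32 = 30,
                           SFII = 30))
  hits <- make_hmm_hits(c("p1", "p2", "p3", "p4"),
                        c("PolB", "PolB", "VLTF3", "PolB"),
                        c(25, 30, 25, 80))
  kept <- filter_marker_hits(hits, reg)
  expect_setequal(kept$protein_id, c("p2", "p3", "p4"))  # 25 < 30 dropped,
  # boundary kept, both PolB proteins over cutoff retained
  expect_error(filter_marker_hits(make_hmm_hits("p", "NOPE", 99), reg),
               "unknown marker")
  expect_error(marker_registry(c(PolB = 30)), "setequal")
})

test_that("split-gene merging joins non-overlapping fragments only", {
  two <- make_hmm_hits(c("P1", "P2"), "PolB", c(100, 90),
                       hmm_from = c(1L, 320L), hmm_to = c(300L, 600L))
  copies <- merge_split_hits(two)
  expect_length(copies, 1L)
  expect_equal(copies[[1]]$proteins, c("P1", "P2"))  # concatenation order

  overlapping <- make_hmm_hits(c("P1", "P2"), "PolB", c(100, 90),
                               hmm_from = c(1L, 250L),
                               hmm_to = c(300L, 600L))
  expect_length(merge_split_hits(overlapping), 2L)

  single <- make_hmm_hits("P1", "PolB", 100, hmm_from = 1L, hmm_to = 600L)
  expect_length(merge_split_hits(single), 1L)
  expect_length(merge_split_hits(single[0, ]), 0L)

  # boundary: overlap of exactly max_overlap residues still merges
  edge <- make_hmm_hits(c("P1", "P2"), "PolB", c(100, 90),
                        hmm_from = c(1L, 291L), hmm_to = c(300L, 600L))
  expect_length(merge_split_hits(edge, max_overlap = 10L), 1L)
  expect_length(merge_split_hits(edge, max_overlap = 9L), 2L)
})

test_that("merging never increases the copy count over naive counting", {
  withr::with_seed(42L, {
    for (i in 1:50) {
      n <- sample(1:6, 1)
      from <- sample(1:500, n)
      hits <- make_hmm_hits(paste0("p", seq_len(n)), "MCP",
                            runif(n, 40, 120), hmm_from = as.integer(from),
                            hmm_to = as.integer(from +
                                                  sample(50:300, n,
                                                         replace = TRUE)))
      expect_lte(length(merge_split_hits(hits)), n)
    }
  })
})

test_that("the bin screen requires 4 markers and more than 100 Kbp", {
  reg <- marker_registry()
  mk_profile <- function(markers) {
    hits <- make_hmm_hits(paste0("p", seq_along(markers)), markers,
                          rep(60, length(markers)))
    marker_profile(hits, reg, "g1")
  }
  bin_big <- make_bin(contig_lengths = c(c1 = 80000L, c2 = 70000L))
  bin_small <- make_bin(contig_lengths = c(c1 = 50000L, c2 = 40000L))

  four <- mk_profile(c("PolB", "MCP", "A32", "VLTF3"))
  expect_true(screen_bin(bin_big, four)$pass)

  five <- mk_profile(c("PolB", "MCP", "A32", "VLTF3", "SFII"))
  dec <- screen_bin(bin_small, five)
  expect_false(dec$pass)
  expect_match(dec$reasons, "length")

  three <- mk_profile(c("PolB", "MCP", "A32"))
  dec3 <- screen_bin(bin_big, three)
  expect_false(dec3$pass)
  expect_match(dec3$reasons, "markers < 4")
})

test_that("supermatrix concatenation pads missing genomes and partitions", {
  aln <- list(
    PolB = c(g1 = "MKVAAKKVAA", g2 = "MKVAAKKVAA", g3 = "MKV--KKVAA"),
    VLTF3 = c(g1 = strrep("A", 20), g3 = strrep("C", 20)))
  sm <- build_supermatrix(aln)
  expect_equal(unique(nchar(sm$alignment)), 30L)
  expect_equal(substr(sm$alignment[["g2"]], 11, 30), strrep("-", 20))
  expect_equal(sm$partitions$marker, c("PolB", "VLTF3"))
  expect_equal(sm$partitions$start, c(1L, 11L))
  expect_equal(sm$partitions$end, c(10L, 30L))
  expect_error(
    build_supermatrix(list(PolB = c(g1 = "AA", g1 = "CC"))),
    "duplicate")
})

test_that("gap trimming matches -gt semantics and is idempotent", {
  aln <- c(r1 = "A-AC", r2 = "A--C", r3 = "A--C")
  out <- trim_alignment(aln, gt = 0.5)
  expect_equal(unname(out), c("AC", "AC", "AC"))  # all-gap-ish col dropped,
  # gap-free retained

  # 10 rows, exactly 1 non-gap in a column, gt = 0.1: boundary inclusive
  rows <- c("AX", paste0("A", strrep("-", 1))[rep(1, 9)])
  aln10 <- stats::setNames(c("AX", rep("A-", 9)), paste0("r", 1:10))
  out10 <- trim_alignment(aln10, gt = 0.1)
  expect_equal(nchar(out10[[1]]), 2L)  # X counts as residue, column kept
  expect_equal(nchar(trim_alignment(aln10, gt = 0.11)[[1]]), 1L)

  withr::with_seed(8L, {
    for (i in 1:20) {
      w <- sample(5:30, 1)
      al <- vapply(1:6, function(j) {
        paste(sample(c("A", "K", "-"), w, replace = TRUE,
                     prob = c(.3, .3, .4)), collapse = "")
      }, character(1))
      names(al) <- paste0("s", 1:6)
      if (all(vapply(strsplit(al, ""), function(x) all(x == "-"),
                     logical(1)))) next
      t1 <- trim_alignment(al, 0.3)
      expect_identical(trim_alignment(t1, 0.3), t1)
    }
  })
})
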