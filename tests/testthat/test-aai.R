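rand_prot <- function(n, len, prefix) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")
  stats::setNames(
    vapply(seq_len(n), function(i) paste(sample(aa, len, replace = TRUE),
                                         collapse = ""), character(1)),
    paste0(prefix, seq_len(n)))
}

test_that("identical proteomes give AAI 100 and AF 100 by alignment", {
  withr::with_seed(4L, {
    a <- rand_prot(4, 60, "a")
    b <- stats::setNames(a, paste0("b", 1:4))
    r <- aai_pair(a, b, "A", "B")
    expect_equal(r$n_rbh, 4L)
    expect_equal(r$aai_pct, 100)
    expect_equal(r$af_pct, 100)
    expect_equal(r$masked_aai, 100)
  })
})

test_that("RBH pairs require mutual best hits", {
  # hand-built 3-protein toy with one asymmetric best hit
  ab <- data.frame(query = c("a1", "a2", "a3"),
                   subject = c("b1", "b2", "b1"),
                   pident = c(90, 80, 40), bitscore = c(300, 250, 100),
                   stringsAsFactors = FALSE)
  ba <- data.frame(query = c("b1", "b2", "b3"),
                   subject = c("a1", "a2", "a2"),
                   pident = c(88, 82, 30), bitscore = c(290, 240, 90),
                   stringsAsFactors = FALSE)
  rbh <- reciprocal_best_hits(ab, ba)
  # brute-force check of the definition over all candidate pairs
  best_ab <- stats::setNames(ab$subject, ab$query)
  best_ba <- stats::setNames(ba$subject, ba$query)
  expected <- list()
  for (q in names(best_ab)) {
    s <- best_ab[[q]]
    if (!is.na(best_ba[s]) && best_ba[[s]] == q) {
      expected[[length(expected) + 1L]] <- c(q, s)
    }
  }
  expect_equal(nrow(rbh), length(expected))
  expect_setequal(rbh$protein_a, vapply(expected, `[`, character(1), 1L))
  expect_false("a3" %in% rbh$protein_a)
  expect_equal(rbh$pct_identity[rbh$protein_a == "a1"], (90 + 88) / 2)

  empty <- ab[0, ]
  expect_equal(nrow(reciprocal_best_hits(empty, ba)), 0L)
})

test_that("AAI assembles means, AF and the masking rule", {
  rbh <- data.frame(protein_a = c("a1", "a2"), protein_b = c("b1", "b2"),
                    pct_identity = c(60, 40), stringsAsFactors = FALSE)
  r <- compute_aai(rbh, 40, 20, "A", "B")
  expect_equal(r$aai_pct, 50)
  expect_equal(r$af_pct, 100 * 2 / 20)
  expect_equal(r$masked_aai, 50)

  # AF below 10 masks the AAI to 0
  r2 <- compute_aai(rbh, 40, 40, "A", "B")
  expect_equal(r2$af_pct, 5)
  expect_equal(r2$masked_aai, 0)
  expect_equal(r2$aai_pct, 50)

  r0 <- compute_aai(rbh[0, ], 10, 10)
  expect_equal(r0$n_rbh, 0L)
  expect_true(is.na(r0$aai_pct))
  expect_equal(r0$masked_aai, 0)
})

test_that("removing a protein never increases the RBH count", {
  withr::with_seed(17L, {
    a <- rand_prot(5, 50, "a")
    b <- stats::setNames(mutate_proteome(a, 70), paste0("b", 1:5))
    full <- aai_pair(a, b)$n_rbh
    for (drop in 1:3) {
      expect_lte(aai_pair(a[-drop], b)$n_rbh, full)
    }
  })
})

test_that("the AAI matrix is symmetric with a 100 diagonal", {
  res <- rbind(
    compute_aai(data.frame(protein_a = "x", protein_b = "y",
                           pct_identity = 80), 10, 10, "g1", "g2"),
    compute_aai(data.frame(protein_a = "x", protein_b = "y",
                           pct_identity = 30), 10, 10, "g1", "g3"),
    compute_aai(data.frame(protein_a = "x", protein_b = "y",
                           pct_identity = 55), 10, 10, "g2", "g3"))
  m <- aai_matrix(res)
  expect_true(isSymmetric(m))
  expect_equal(unname(diag(m)), rep(100, 3))
  expect_equal(m["g1", "g2"], 80)

  tr <- ape::read.tree(text = "((g3:1,g1:1):1,g2:2):0;")
  m2 <- aai_matrix(res, tree = tr)
  expect_equal(rownames(m2), c("g3", "g1", "g2"))

  expect_error(aai_matrix(res[1:2, ]), "missing AAI pairs")
})

test_that("planted two-family structure shows in the masked matrix", {
  d <- bundle_dir()
  truth <- read_truth(d)
  rows <- list()
  for (p in truth$aai) {
    fwd <- parse_tabular_hits(
      file.path(d, "aai", paste0(p$genome_a, "__vs__", p$genome_b,
                                 ".tsv")))
    rev <- parse_tabular_hits(
      file.path(d, "aai", paste0(p$genome_b, "__vs__", p$genome_a,
                                 ".tsv")))
    r <- compute_aai(reciprocal_best_hits(fwd, rev), p$n_proteins,
                     p$n_proteins, p$genome_a, p$genome_b)
    expect_equal(r$aai_pct, p$realized_identity, tolerance = 1e-4)
    expect_equal(r$af_pct, 100)
    rows[[length(rows) + 1L]] <- r
  }
  res <- do.call(rbind, rows)
  expect_equal(res$aai_pct[res$genome_a == "aai80_src"], 80,
               tolerance = 0.02)
  expect_equal(res$aai_pct[res$genome_a == "aai50_src"], 50,
               tolerance = 0.04)
})
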