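test_that("the frequency spectrum counts genomes and singletons", {
  mat <- matrix(c(1L, 0L, 0L,   # OG1 in 1 genome
                  0L, 2L, 0L,   # OG2 in 1 genome
                  1L, 1L, 0L),  # OG3 in 2 genomes
                nrow = 3,
                dimnames = list(paste0("g", 1:3), paste0("OG", 1:3)))
  fs <- frequency_spectrum(mat, annotations = c(OG1 = "capsid"))
  expect_equal(unname(fs$genome_counts), c(1L, 1L, 2L))
  expect_equal(fs$summary$n_singletons, 2L)
  expect_equal(fs$summary$singleton_pct, 67L)
  expect_equal(fs$summary$n_annotated, 1L)
  expect_equal(fs$summary$annotated_pct, 33L)

  all_shared <- matrix(1L, 2, 2, dimnames = list(c("a", "b"),
                                                 c("o1", "o2")))
  expect_equal(frequency_spectrum(all_shared)$summary$n_singletons, 0L)
})

test_that("the power-law exponent matches the closed form", {
  expect_equal(power_law_alpha(c(1, 2, 4)), 1 + 3 / (log(2) + log(4)))
  expect_error(power_law_alpha(c(1, 1, 1)), "undefined")
  # scale invariance when xmin scales with the counts
  x <- c(1, 3, 9, 27)
  expect_equal(power_law_alpha(x, 1), power_law_alpha(10 * x, 10))
})

test_that("the bipartite network keeps OGs above the genome threshold", {
  genomes <- paste0("g", 1:8)
  mat <- matrix(0L, 8, 3, dimnames = list(genomes, paste0("OG", 1:3)))
  mat[1:5, 1] <- 1L   # exactly 5 genomes: excluded at min_genomes = 5
  mat[1:6, 2] <- 1L   # 6 genomes: included with degree 6
  mat[1, 3] <- 1L
  g <- bipartite_network(mat, min_genomes = 5L,
                         genome_sizes = stats::setNames(1:8 * 1e5,
                                                        genomes))
  expect_true("OG2" %in% igraph::V(g)$name)
  expect_false("OG1" %in% igraph::V(g)$name)
  expect_equal(unname(igraph::degree(g, "OG2")), 6)
  expect_equal(igraph::V(g)$genome_size[igraph::V(g)$name == "g2"], 2e5)

  expect_warning(empty <- bipartite_network(mat[, 3, drop = FALSE]),
                 "empty")
  expect_equal(igraph::vcount(empty), 0L)

  # exports are parseable text
  d <- withr::local_tempdir()
  write_edge_list(g, file.path(d, "edges.tsv"))
  write_graphml(g, file.path(d, "net.graphml"))
  edges <- read.table(file.path(d, "edges.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(edges), igraph::ecount(g))
  expect_match(readLines(file.path(d, "net.graphml"), n = 2L)[1], "xml")
})

test_that("enrichment reproduces the exact U on separable data", {
  genomes <- paste0("g", 1:48)
  clades <- stats::setNames(c(rep("c1", 8), rep("bg", 40)), genomes)
  mat <- matrix(0L, 48, 2, dimnames = list(genomes, c("OG_A", "OG_B")))
  mat[1:8, "OG_A"] <- 1L          # planted: all clade members, no others
  mat[c(1:4, 9:14), "OG_B"] <- 1L # shared background family
  ann <- c(OG_A = "planted", OG_B = "shared")
  res <- og_enrichment(mat, clades, ann, min_clade_size = 5L,
                       min_og_genomes = 6L)
  row_a <- res[res$og_id == "OG_A" & res$clade_id == "c1", ]
  expect_equal(row_a$u_statistic, 320)   # 8 x 40, complete separation
  expect_lt(row_a$p_value, 1e-6)
  expect_true(row_a$significant)
  expect_equal(row_a$direction, "enriched")

  # identical counts everywhere: no signal
  mat2 <- mat
  mat2[, "OG_A"] <- 1L
  res2 <- og_enrichment(mat2, clades, ann)
  expect_equal(res2$p_value[res2$og_id == "OG_A" & res2$clade_id == "c1"],
               1)
  expect_false(any(res2$significant[res2$og_id == "OG_A"]))

  # OGs at or below the genome threshold are not tested
  mat3 <- mat
  mat3[, "OG_B"] <- 0L
  mat3[1:5, "OG_B"] <- 1L
  res3 <- og_enrichment(mat3, clades, ann)
  expect_false("OG_B" %in% res3$og_id)

  # unannotated OGs are not tested
  res4 <- og_enrichment(mat, clades, c(OG_A = "planted"))
  expect_false("OG_B" %in% res4$og_id)

  # binary membership mode collapses copy numbers
  mat5 <- mat
  mat5[1:8, "OG_A"] <- 3L
  res5 <- og_enrichment(mat5, clades, ann, membership = "binary")
  expect_equal(res5$u_statistic[res5$og_id == "OG_A" &
                                  res5$clade_id == "c1"], 320)
})

test_that("BH-adjusted q-values dominate p-values monotonically", {
  withr::with_seed(7L, {
    genomes <- paste0("g", 1:30)
    clades <- stats::setNames(rep(c("c1", "c2", "c3"), each = 10), genomes)
    mat <- matrix(rbinom(30 * 40, 2L, 0.4), 30,
                  dimnames = list(genomes, sprintf("OG%02d", 1:40)))
    ann <- stats::setNames(paste0("f", 1:40), colnames(mat))
    res <- og_enrichment(mat, clades, ann)
    expect_true(all(res$q_value >= res$p_value - 1e-12))
    ord <- order(res$p_value)
    expect_true(all(diff(res$q_value[ord]) >= -1e-12))
    expect_equal(res$q_value, stats::p.adjust(res$p_value, "BH"))
  })
})
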