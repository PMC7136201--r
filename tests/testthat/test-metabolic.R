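test_that("packaged pathway definitions load with ordered steps", {
  defs <- read_pathway_defs()
  expect_setequal(names(defs), c("glycolysis", "tca", "gluconeogenesis",
                                 "glyoxylate"))
  expect_length(defs$glycolysis, 10L)
  expect_equal(names(defs$glycolysis)[1:3], c("HK", "PGI", "PFK"))
  expect_setequal(defs$tca$SD, c("SD-A", "SD-B", "SD-C"))
  expect_length(defs$glyoxylate, 2L)
})

test_that("pathway completeness counts distinct steps once", {
  defs <- read_pathway_defs()
  seven <- c("PGI", "PFK", "ALD", "TPI", "G3P", "PGK", "PGM")
  r <- pathway_completeness(seven, defs$glycolysis, "glycolysis", "g1")
  expect_equal(r$completeness_pct, 70)

  expect_equal(pathway_completeness(character(0), defs$glycolysis)
               $completeness_pct, 0)

  # 3 copies of ENO still count as one step
  r3 <- pathway_completeness(rep("ENO", 3), defs$glycolysis)
  expect_equal(r3$completeness_pct, 10)

  # any SD subunit satisfies the SD step
  expect_equal(pathway_completeness("SD-B", defs$tca)$completeness_pct,
               100 / 8)

  expect_warning(pathway_completeness(c("ENO", "NOT_AN_ENZYME"),
                                      defs$glycolysis), "ignored")

  ann <- data.frame(genome_id = c("g1", "g1", "g2"),
                    enzyme_id = c("ENO", "CS", "ICL"),
                    stringsAsFactors = FALSE)
  pp <- pathway_profiles(ann, defs)
  expect_equal(nrow(pp), 8L)  # 2 genomes x 4 pathways
  expect_equal(pp$completeness_pct[pp$genome_id == "g2" &
                                     pp$pathway_id == "glyoxylate"], 50)
})

test_that("fusion calls require both domains with bounded overlap", {
  dom <- data.frame(protein_id = c("p1", "p1"),
                    domain_id = c("G3P", "PGK"),
                    start = c(1L, 340L), end = c(330L, 730L),
                    stringsAsFactors = FALSE)
  call <- detect_fusion(dom, "G3P", "PGK")
  expect_equal(nrow(call), 1L)
  expect_equal(call$first_domain, "G3P")
  expect_equal(call$second_domain, "PGK")

  split <- data.frame(protein_id = c("p1", "p2"),
                      domain_id = c("G3P", "PGK"),
                      start = c(1L, 1L), end = c(330L, 400L),
                      stringsAsFactors = FALSE)
  expect_equal(nrow(detect_fusion(split, "G3P", "PGK")), 0L)

  overlapping <- data.frame(protein_id = c("p1", "p1"),
                            domain_id = c("G3P", "PGK"),
                            start = c(1L, 100L), end = c(330L, 400L),
                            stringsAsFactors = FALSE)
  expect_equal(nrow(detect_fusion(overlapping, "G3P", "PGK")), 0L)

  # reversed order along the protein is reported as such
  rev <- data.frame(protein_id = "p9", domain_id = c("G3P", "PGK"),
                    start = c(400L, 1L), end = c(700L, 380L),
                    stringsAsFactors = FALSE)
  r <- detect_fusion(rev, "G3P", "PGK")
  expect_equal(r$first_domain, "PGK")
})

test_that("co-localization clusters follow the gap rule", {
  gt <- function(idx, cid = "c1") {
    data.frame(contig_id = cid, gene_index = 0:29,
               protein_id = sprintf("%s_p%d", cid, 0:29),
               stringsAsFactors = FALSE)
  }
  tab <- gt()
  targets <- sprintf("c1_p%d", c(5, 6, 8))
  cl <- colocalization(tab, targets, max_gap = 5L)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_genes, 3L)
  expect_equal(cl$members[[1]], targets)
  expect_equal(c(cl$span_from, cl$span_to), c(5L, 8L))

  far <- sprintf("c1_p%d", c(2, 20))
  expect_equal(nrow(colocalization(tab, far, max_gap = 5L)), 0L)
  expect_equal(nrow(colocalization(tab, "c1_p7")), 0L)

  # boundary: gap of exactly max_gap joins, one more splits
  g5 <- sprintf("c1_p%d", c(0, 6))
  expect_equal(nrow(colocalization(tab, g5, max_gap = 5L)), 1L)
  expect_equal(nrow(colocalization(tab, g5, max_gap = 4L)), 0L)

  # clusters are disjoint and members are target genes on the contig
  targets2 <- sprintf("c1_p%d", c(1, 2, 3, 15, 16, 28))
  cl2 <- colocalization(tab, targets2, max_gap = 3L)
  all_members <- unlist(cl2$members)
  expect_equal(anyDuplicated(all_members), 0L)
  expect_true(all(all_members %in% targets2))
})

test_that("clade prevalence is the planted per-clade fraction", {
  clades <- stats::setNames(rep(c("A", "B"), c(8, 4)),
                            sprintf("g%02d", 1:12))
  presence <- data.frame(genome_id = c(sprintf("g%02d", 1:4), "g09"),
                         feature_id = "SOD", stringsAsFactors = FALSE)
  pv <- clade_prevalence(presence, clades)
  expect_equal(pv$pct[pv$clade_id == "A"], 50)
  expect_equal(pv$pct[pv$clade_id == "B"], 25)

  none <- data.frame(genome_id = "g01", feature_id = "GPx",
                     stringsAsFactors = FALSE)
  pv2 <- clade_prevalence(none, clades)
  expect_equal(pv2$pct[pv2$clade_id == "B"], 0)

  # matrix input gives exactly the count-based fractions
  withr::with_seed(12L, {
    m <- matrix(rbinom(12 * 3, 1, 0.5), 12,
                dimnames = list(names(clades), c("f1", "f2", "f3")))
    pv3 <- clade_prevalence(m, clades)
    for (i in seq_len(nrow(pv3))) {
      members <- names(clades)[clades == pv3$clade_id[i]]
      expect_equal(pv3$pct[i],
                   100 * sum(m[members, pv3$feature_id[i]]) /
                     length(members))
    }
  })
})
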