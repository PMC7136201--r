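test_that("the contig score is the mean per-protein signed maximum", {
  v <- make_hmm_hits("p1", "VOG1", 50, model_db = "viral")
  expect_equal(score_contig("p1", v, v[0, ]), 50)

  # equal viral and cellular maxima cancel
  c1 <- make_hmm_hits("p1", "PF1", 50, model_db = "cellular")
  expect_equal(score_contig("p1", v, c1), 0)

  # two proteins with signed scores -30 and +10 average to -10
  v2 <- make_hmm_hits("p2", "VOG1", 10, model_db = "viral")
  c2 <- make_hmm_hits("p1", "PF1", 30, model_db = "cellular")
  expect_equal(score_contig(c("p1", "p2"), v2, c2), -10)

  expect_equal(score_contig(character(0), v, c1), 0)
  # proteins without hits dilute the mean
  expect_equal(score_contig(c("p1", "px"), v, v[0, ]), 25)
})

test_that("raising viral evidence never lowers the score and vice versa", {
  withr::with_seed(21L, {
    pids <- paste0("p", 1:4)
    v <- make_hmm_hits(pids, "VOG1", runif(4, 10, 90), model_db = "viral")
    c0 <- make_hmm_hits(pids[1:2], "PF1", runif(2, 10, 90),
                        model_db = "cellular")
    base <- score_contig(pids, v, c0)
    v_up <- v
    v_up$bitscore[2] <- v_up$bitscore[2] + 50
    expect_gte(score_contig(pids, v_up, c0), base)
    c_extra <- rbind(c0, make_hmm_hits("p3", "PF2", 40,
                                       model_db = "cellular"))
    expect_lte(score_contig(pids, v, c_extra), base)
  })
})

test_that("removal rules implement the cellular and phage conjunctions", {
  bin <- make_bin("b", c(c1 = 120000L), genes_per_contig = 5L)
  pids <- bin$proteins$protein_id
  no_hits <- make_hmm_hits("x", "m", 1)[0, ]

  # net-cellular contig with 1 VOG-hit protein and no ncldv top-5: removed
  cell <- make_hmm_hits(pids, "PF1", 60, model_db = "cellular")
  weak_vog <- make_hmm_hits(pids[1], "VOG1", 8, model_db = "viral",
                            evalue = 1e-4)
  hom_cell <- make_hom_hits(pids, "cellular")
  v1 <- contig_verdicts(bin, weak_vog, cell, hom_cell)
  expect_true(v1$removed)
  expect_equal(v1$removal_rule, "cellular")

  # same but 4 VOG-hit proteins: retained (AND of the three conditions)
  vog4 <- make_hmm_hits(pids[1:4], "VOG1", 8, model_db = "viral",
                        evalue = 1e-4)
  v2 <- contig_verdicts(bin, vog4, cell, hom_cell)
  expect_false(v2$removed)

  # an ncldv top-5 hit alone protects a net-cellular contig
  hom_mix <- rbind(make_hom_hits(pids[1], "ncldv"),
                   make_hom_hits(pids[-1], "cellular"))
  v3 <- contig_verdicts(bin, weak_vog, cell, hom_mix)
  expect_false(v3$removed)

  # phage rule fires regardless of a positive score
  viral_strong <- make_hmm_hits(pids, "VOG1", 100, model_db = "viral")
  hom_phage <- rbind(make_hom_hits(pids[1], "bacteriophage"),
                     make_hom_hits(pids[-1], "cellular"))
  v4 <- contig_verdicts(bin, viral_strong, no_hits, hom_phage)
  expect_gt(v4$viralrecall_score, 0)
  expect_equal(v4$removal_rule, "phage")

  # ... but an ncldv hit anywhere on the contig blocks it
  hom_both <- rbind(hom_phage, make_hom_hits(pids[2], "ncldv"))
  v5 <- contig_verdicts(bin, viral_strong, no_hits, hom_both)
  expect_false(v5$removed)

  # OR combination removes on any cellular condition
  v6 <- contig_verdicts(bin, vog4, cell, hom_cell,
                        cellular_combine = "or")
  expect_true(v6$removed)
})

test_that("decontamination drops exactly the flagged contigs", {
  bin <- make_bin("b", c(c1 = 90000L, c2 = 60000L))
  pids1 <- bin$proteins$protein_id[bin$proteins$contig_id == "c1"]
  pids2 <- bin$proteins$protein_id[bin$proteins$contig_id == "c2"]
  viral <- make_hmm_hits(pids1, "VOG1", 90, model_db = "viral")
  cell <- make_hmm_hits(pids2, "PF1", 70, model_db = "cellular")
  hom <- make_hom_hits(pids1, "ncldv")
  verdicts <- contig_verdicts(bin, viral, cell, hom)
  res <- decontaminate_bin(bin, verdicts)
  expect_false(res$dropped)
  expect_equal(res$bin$contigs$contig_id, "c1")
  expect_equal(res$report$contig_id, "c2")

  # no removals: bin unchanged
  hom_all <- make_hom_hits(c(pids1, pids2), "ncldv")
  viral_all <- make_hmm_hits(c(pids1, pids2), "VOG1", 90,
                             model_db = "viral")
  res2 <- decontaminate_bin(bin, contig_verdicts(bin, viral_all,
                                                 cell[0, ], hom_all))
  expect_equal(res2$bin$contigs, bin$contigs)
  expect_equal(nrow(res2$report), 0L)

  # all contigs removed: bin dropped with a warning
  cell_all <- make_hmm_hits(c(pids1, pids2), "PF1", 70,
                            model_db = "cellular")
  hom_none <- make_hom_hits(c(pids1, pids2), "cellular")
  expect_warning(
    res3 <- decontaminate_bin(bin, contig_verdicts(bin, viral_all[0, ],
                                                   cell_all, hom_none)),
    "dropped")
  expect_true(res3$dropped)
  expect_null(res3$bin)

  expect_error(decontaminate_bin(bin, verdicts[0, ]), "no verdict")
})
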