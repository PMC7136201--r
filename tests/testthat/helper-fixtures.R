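# Shared fixtures and independent oracles, all built in code.

# -- tiny bin builder -----------------------------------------------------

make_bin <- function(bin_id = "binA",
                     contig_lengths = c(c1 = 60000L, c2 = 50000L),
                     genes_per_contig = 5L) {
  contigs <- data.frame(contig_id = names(contig_lengths),
                        length_bp = unname(contig_lengths),
                        stringsAsFactors = FALSE)
  proteins <- do.call(rbind, lapply(names(contig_lengths), function(cid) {
    slot <- contig_lengths[[cid]] %/% genes_per_contig
    start <- (seq_len(genes_per_contig) - 1L) * slot + 1L
    data.frame(protein_id = sprintf("%s_%d", cid, seq_len(genes_per_contig)),
               contig_id = cid, gene_index = seq_len(genes_per_contig) - 1L,
               start = start, end = start + 900L, strand = "+",
               length_aa = 300L, stringsAsFactors = FALSE)
  }))
  gv_bin(bin_id, contigs, proteins)
}

make_hmm_hits <- function(protein_id, model_id, bitscore,
                          model_db = "marker", evalue = 1e-10,
                          hmm_from = 1L, hmm_to = 100L) {
  data.frame(protein_id = protein_id, model_id = model_id,
             model_db = model_db, bitscore = bitscore, evalue = evalue,
             hmm_from = hmm_from, hmm_to = hmm_to, ali_from = 1L,
             ali_to = 100L, stringsAsFactors = FALSE)
}

make_hom_hits <- function(protein_id, subject_class, rank = 1L) {
  data.frame(query_protein_id = protein_id,
             subject_id = paste0("s_", seq_along(protein_id)),
             rank = rank, pct_identity = 50, aln_len = 100L, evalue = 1e-10,
             bitscore = 100, subject_class = subject_class,
             stringsAsFactors = FALSE)
}

# -- independent oracles --------------------------------------------------

# N50 by explicit cumulative walk
n50_oracle <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(s) / 2
  acc <- 0
  for (l in s) {
    acc <- acc + l
    if (acc >= half) return(l)
  }
}

# Dunn index by direct evaluation of the defining formula
dunn_oracle <- function(clusters, d) {
  ids <- unique(clusters)
  leaves <- names(clusters)
  diam <- 0
  for (i in ids) {
    m <- leaves[clusters == i]
    if (length(m) >= 2) {
      for (a in m) for (b in m) diam <- max(diam, d[a, b])
    }
  }
  if (diam == 0) return(NA_real_)
  min_inter <- Inf
  for (i in ids) for (j in ids) {
    if (i == j) next
    for (a in leaves[clusters == i]) for (b in leaves[clusters == j]) {
      min_inter <- min(min_inter, d[a, b])
    }
  }
  min_inter / diam
}

# two-sided Mann-Whitney permutation p-value by full enumeration:
# Pr(|U - mu| >= |U_obs - mu|) over all label reassignments
mwu_perm_oracle <- function(x, y) {
  all_v <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  ustat <- function(ix) {
    xv <- all_v[ix]
    yv <- all_v[-ix]
    sum(outer(xv, yv, ">")) + 0.5 * sum(outer(xv, yv, "=="))
  }
  obs <- abs(ustat(seq_len(n1)) - mu)
  combs <- utils::combn(length(all_v), n1)
  mean(apply(combs, 2, function(ix) abs(ustat(ix) - mu) >= obs - 1e-9))
}

# per-pair percent identity by direct character comparison
identity_oracle <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  100 * mean(ca == cb)
}

# one shared default bundle per test run (generation is seeded and cheap)
bundle_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "gvpipe-test-bundle")
      if (!file.exists(file.path(dir, "truth.json"))) {
        generate_bundle(sim_config(seed = 101L), dir)
      }
    }
    dir
  }
})
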