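# Seeded generator of complete input bundles with planted ground truth.
#
# The generator plays the role of the external search tools: it emits
# contig/protein FASTAs, HMM hit tables (marker, viral, cellular), ranked
# homology tables with a subject class map, proteome pairs of known
# identity, an ultrametric tree with planted clades, an OG table with
# planted clade-enriched groups, and pathway/fusion/co-localization
# annotations -- together with a truth.json recording everything planted.
# Sequences are i.i.d. uniform over residues: no stage in scope reads
# sequence content except lengths and identities.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
DNA_ALPHABET <- c("A", "C", "G", "T")

MARKER_MODEL_LEN <- c(PolB = 900, VLTF3 = 250, MCP = 500, A32 = 300,
                      SFII = 600)

rand_seq <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Default simulation configuration
#'
#' Bundles every planted parameter of the synthetic generator. Defaults
#' emulate a small but complete study: six bins covering the pass/fail and
#' strain-heterogeneity cases (with one planted split marker gene and
#' planted phage/cellular contaminant contigs), proteome pairs at 80% and
#' 50% amino-acid identity, a 3-clade ultrametric tree with 10 leaves per
#' clade (within-clade depth 1, root depth 5), an OG matrix with 8 planted
#' clade-enriched groups, and a central-carbon pathway repertoire with a
#' fused G3P+PGK protein and a co-localized TCA gene run.
#'
#' @param seed Integer seed; identical seed + config give byte-identical
#'   bundles.
#' @param bin_plans List of per-bin plans (see the default for the fields:
#'   `bin_id`, `n_contigs`, `total_bp`, `markers`, `split_marker`,
#'   `n_phage`, `n_cellular`).
#' @param genes_per_kbp Gene density (default 1 per kbp).
#' @param contig_sdlog Log-normal sdlog of contig lengths (default 0.45).
#' @param mu_viral,sigma_viral Per-protein max viral bitscore model for
#'   viral proteins (default Normal(100, 8)).
#' @param mu_cellular,sigma_cellular Max cellular bitscore model for
#'   planted cellular contigs (default Normal(60, 8)); the 40-bit
#'   separation from `mu_viral` leaves a comfortable margin over the
#'   30-bit separation at which contaminant removal is exact.
#' @param cutoffs Marker score cutoffs, as in [marker_registry()].
#' @param aai_plan List: `n_proteins`, `protein_length`, `pairs` (each with
#'   `id` and `identity` in (0, 100]).
#' @param tree_plan List: `k`, `clade_sizes`, `h_in`, `h_out`
#'   (`h_out > h_in`).
#' @param og_plan List: `n_ogs`, `p0`, `p1`, `n_enriched`,
#'   `enriched_clade`, `annotated_frac`.
#' @param pathway_plan List: `glycolysis_steps`, `fusion_bins`, `tca_run`.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(
    seed = 1L,
    bin_plans = default_bin_plans(),
    genes_per_kbp = 1.0,
    contig_sdlog = 0.45,
    mu_viral = 100, sigma_viral = 8,
    mu_cellular = 60, sigma_cellular = 8,
    cutoffs = c(PolB = 30, VLTF3 = 30, MCP = 30, A32 = 30, SFII = 30),
    aai_plan = list(
      n_proteins = 25L, protein_length = 400L,
      pairs = list(list(id = "aai80", identity = 80),
                   list(id = "aai50", identity = 50))),
    tree_plan = list(k = 3L, clade_sizes = c(10L, 10L, 10L), h_in = 1,
                     h_out = 5),
    og_plan = list(n_ogs = 120L, p0 = 0.1, p1 = 1.0, extra_copy_p = 0.5,
                   n_enriched = 8L, enriched_clade = 1L,
                   annotated_frac = 0.6),
    pathway_plan = list(
      glycolysis_steps = c("PGI", "PFK", "ALD", "TPI", "G3P", "PGK",
                           "PGM"),
      fusion_bins = 2L,
      tca_run = c("CS", "ACON", "SD-A", "MDH"))) {
  stopifnot(og_plan$p0 >= 0, og_plan$p0 <= 1, og_plan$p1 >= 0,
            og_plan$p1 <= 1, og_plan$annotated_frac >= 0,
            og_plan$annotated_frac <= 1,
            tree_plan$h_out > tree_plan$h_in,
            length(tree_plan$clade_sizes) == tree_plan$k,
            all(vapply(aai_plan$pairs,
                       function(p) p$identity > 0 && p$identity <= 100,
                       logical(1))),
            mu_viral > mu_cellular)
  structure(list(seed = as.integer(seed), bin_plans = bin_plans,
                 genes_per_kbp = genes_per_kbp,
                 contig_sdlog = contig_sdlog, mu_viral = mu_viral,
                 sigma_viral = sigma_viral, mu_cellular = mu_cellular,
                 sigma_cellular = sigma_cellular,
                 cutoffs = cutoffs, aai_plan = aai_plan,
                 tree_plan = tree_plan, og_plan = og_plan,
                 pathway_plan = pathway_plan),
            class = "sim_config")
}

#' Default per-bin simulation plans
#'
#' Six bins covering the decision space: a full-marker bin with a split
#' PolB and a duplicated MCP (which must not count against strain
#' heterogeneity), a 4-marker bin, a 3-marker failure, a short-bin failure,
#' a singly-flagged bin, and a strain-heterogeneous reject.
#'
#' @return List of plans consumed by [generate_bundle()].
#' @export
default_bin_plans <- function() {
  list(
    list(bin_id = "bin_pass_full", n_contigs = 8L, total_bp = 240000L,
         markers = c(PolB = 1L, VLTF3 = 1L, MCP = 2L, A32 = 1L,
                     SFII = 1L),
         split_marker = "PolB", n_phage = 1L, n_cellular = 1L),
    list(bin_id = "bin_pass_4", n_contigs = 7L, total_bp = 200000L,
         markers = c(PolB = 1L, VLTF3 = 1L, MCP = 1L, A32 = 1L,
                     SFII = 0L),
         split_marker = NULL, n_phage = 1L, n_cellular = 1L),
    list(bin_id = "bin_few_markers", n_contigs = 8L, total_bp = 300000L,
         markers = c(PolB = 1L, VLTF3 = 1L, MCP = 1L, A32 = 0L,
                     SFII = 0L),
         split_marker = NULL, n_phage = 1L, n_cellular = 1L),
    list(bin_id = "bin_short", n_contigs = 4L, total_bp = 80000L,
         markers = c(PolB = 1L, VLTF3 = 1L, MCP = 1L, A32 = 1L,
                     SFII = 1L),
         split_marker = NULL, n_phage = 0L, n_cellular = 0L),
    list(bin_id = "bin_flagged", n_contigs = 8L, total_bp = 220000L,
         markers = c(PolB = 2L, VLTF3 = 1L, MCP = 1L, A32 = 1L,
                     SFII = 1L),
         split_marker = NULL, n_phage = 1L, n_cellular = 1L),
    list(bin_id = "bin_hetero", n_contigs = 8L, total_bp = 260000L,
         markers = c(PolB = 2L, VLTF3 = 1L, MCP = 1L, A32 = 1L,
                     SFII = 2L),
         split_marker = NULL, n_phage = 1L, n_cellular = 1L)
  )
}

#' Mutate a proteome to a target amino-acid identity
#'
#' Each residue is substituted independently with probability
#' `1 - target_identity/100`, the replacement drawn uniformly from the 19
#' alternative residues, so the expected per-protein identity to the source
#' equals the target. Uses the current RNG state; scope the seed with
#' [withr::with_seed()] for reproducibility.
#'
#' @param proteome Named character vector of amino-acid sequences.
#' @param target_identity Target percent identity in (0, 100].
#' @return Mutated proteome (same names and lengths).
#' @export
mutate_proteome <- function(proteome, target_identity) {
  stopifnot(length(proteome) > 0)
  if (!(target_identity > 0 && target_identity <= 100)) {
    stop("target_identity must be in (0, 100]")
  }
  if (target_identity == 100) return(proteome)
  p_sub <- 1 - target_identity / 100
  out <- vapply(proteome, function(seq) {
    chars <- strsplit(seq, "")[[1]]
    flip <- which(runif(length(chars)) < p_sub)
    if (length(flip)) {
      pos <- match(chars[flip], AA_ALPHABET)
      shift <- sample.int(19L, length(flip), replace = TRUE)
      chars[flip] <- AA_ALPHABET[((pos - 1L + shift) %% 20L) + 1L]
    }
    paste(chars, collapse = "")
  }, character(1))
  stats::setNames(out, names(proteome))
}

observed_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  100 * mean(ca == cb)
}

# ---- low-level writers (generator side of the external formats) --------

write_domtblout_file <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# synthetic domtblout", con)
  if (nrow(hits)) {
    for (i in seq_len(nrow(hits))) {
      ev <- formatC(hits$evalue[i], format = "e", digits = 1)
      bs <- formatC(hits$bitscore[i], format = "f", digits = 1)
      writeLines(paste(c(
        hits$protein_id[i], "-", hits$tlen[i], hits$model_id[i], "-",
        hits$qlen[i], ev, bs, "0.0", "1", "1", ev, ev, bs, "0.0",
        hits$hmm_from[i], hits$hmm_to[i], hits$ali_from[i],
        hits$ali_to[i], hits$ali_from[i], hits$ali_to[i], "0.90", "-"),
        collapse = " "), con)
    }
  }
  invisible(path)
}

write_homology_file <- function(rows, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(rows)) {
    for (i in seq_len(nrow(rows))) {
      writeLines(paste(c(
        rows$query[i], rows$subject[i],
        formatC(rows$pident[i], format = "f", digits = 4),
        rows$aln_len[i], "0", "0", "1", rows$aln_len[i], "1",
        rows$aln_len[i], formatC(rows$evalue[i], format = "e", digits = 1),
        formatC(rows$bitscore[i], format = "f", digits = 1)),
        collapse = "\t"), con)
    }
  }
  invisible(path)
}

# ---- per-component generators ------------------------------------------

gen_contig_lengths <- function(n, total_bp, sdlog) {
  w <- rlnorm(n, meanlog = log(total_bp / n), sdlog = sdlog)
  len <- round(w / sum(w) * total_bp)
  len[1] <- len[1] + (total_bp - sum(len))
  len <- pmax(len, 3000L)
  len[which.max(len)] <- len[which.max(len)] - (sum(len) - total_bp)
  as.integer(len)
}

gen_one_bin <- function(plan, config, dir) {
  bin_id <- plan$bin_id
  lens <- gen_contig_lengths(plan$n_contigs, plan$total_bp,
                             config$contig_sdlog)
  contig_ids <- sprintf("%s_c%d", bin_id, seq_along(lens))
  n_contam <- plan$n_phage + plan$n_cellular
  if (n_contam >= plan$n_contigs) stop("config error: bin ", bin_id,
                                       " has no viral contig")
  class <- rep("viral", plan$n_contigs)
  if (n_contam > 0) {
    tail_idx <- seq(plan$n_contigs - n_contam + 1L, plan$n_contigs)
    class[tail_idx] <- c(rep("phage", plan$n_phage),
                         rep("cellular", plan$n_cellular))
  }

  proteins <- list()
  for (i in seq_along(lens)) {
    n_genes <- max(3L, as.integer(round(lens[i] / 1000 *
                                          config$genes_per_kbp)))
    slot <- lens[i] %/% n_genes
    if (slot < 300L) {
      stop("config error: gene plan infeasible on contig ", contig_ids[i],
           " (", slot, " bp per gene)")
    }
    aa_max <- (slot - 60L) %/% 3L
    aa <- pmin(sample(180:450, n_genes, replace = TRUE), aa_max)
    start <- (seq_len(n_genes) - 1L) * slot + 1L
    proteins[[i]] <- data.frame(
      protein_id = sprintf("%s_%d", contig_ids[i], seq_len(n_genes)),
      contig_id = contig_ids[i], gene_index = seq_len(n_genes) - 1L,
      start = start, end = start + 3L * aa + 2L,
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      length_aa = aa, class = class[i], stringsAsFactors = FALSE)
  }
  proteins <- do.call(rbind, proteins)

  # marker hits on viral-contig proteins, round-robin across contigs
  viral_prot <- proteins$protein_id[proteins$class == "viral"]
  pool <- sample(viral_prot)
  take <- function(n) {
    stopifnot(length(pool) >= n)
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  marker_rows <- list()
  add_marker_row <- function(pid, model, from, to, bitscore) {
    marker_rows[[length(marker_rows) + 1L]] <<- data.frame(
      protein_id = pid, model_id = model, bitscore = bitscore,
      evalue = 1e-20, tlen = 999L, qlen = MARKER_MODEL_LEN[[model]],
      hmm_from = from, hmm_to = to, ali_from = 1L,
      ali_to = max(10L, to - from + 1L), stringsAsFactors = FALSE)
  }
  for (m in names(plan$markers)) {
    k <- plan$markers[[m]]
    if (k == 0L) next
    lm <- MARKER_MODEL_LEN[[m]]
    for (copy in seq_len(k)) {
      score <- config$cutoffs[[m]] + 20 + abs(rnorm(1, 0, 5))
      if (!is.null(plan$split_marker) && m == plan$split_marker &&
            copy == 1L) {
        mid <- lm %/% 2L
        pids <- take(2L)
        add_marker_row(pids[1], m, 1L, mid - 10L, score)
        add_marker_row(pids[2], m, mid + 10L, lm, score)
      } else {
        add_marker_row(take(1L), m, 1L, lm, score)
      }
    }
  }
  # below-cutoff decoy hit: must be dropped by the score filter
  decoy_model <- sample(names(MARKER_MODEL_LEN), 1L)
  add_marker_row(take(1L), decoy_model, 1L,
                 MARKER_MODEL_LEN[[decoy_model]],
                 config$cutoffs[[decoy_model]] - 10)
  marker_hits <- do.call(rbind, marker_rows)

  # viral/cellular HMM hits and homology hits per contig class
  viral_rows <- list()
  cellular_rows <- list()
  hom_rows <- list()
  add_hmm <- function(store, pid, model, bitscore, evalue, aa) {
    row <- data.frame(protein_id = pid, model_id = model,
                      bitscore = bitscore, evalue = evalue, tlen = aa,
                      qlen = 150L, hmm_from = 1L, hmm_to = 150L,
                      ali_from = 1L, ali_to = min(aa, 150L),
                      stringsAsFactors = FALSE)
    if (store == "viral") viral_rows[[length(viral_rows) + 1L]] <<- row
    else cellular_rows[[length(cellular_rows) + 1L]] <<- row
  }
  add_hom <- function(pid, subject, aa) {
    hom_rows[[length(hom_rows) + 1L]] <<- data.frame(
      query = pid, subject = subject, pident = runif(1, 30, 80),
      aln_len = max(30L, as.integer(round(0.9 * aa))), evalue = 1e-20,
      bitscore = runif(1, 80, 200), stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(proteins))) {
    pid <- proteins$protein_id[i]
    aa <- proteins$length_aa[i]
    cls <- proteins$class[i]
    if (cls == "viral") {
      add_hmm("viral", pid, sprintf("VOG%04d", sample.int(500L, 1L)),
              max(30, rnorm(1, config$mu_viral, config$sigma_viral)),
              1e-10, aa)
      if (runif(1) < 0.3) {
        add_hmm("cellular", pid, sprintf("PFAM%05d", sample.int(900L, 1L)),
                runif(1, 5, 20), 1e-4, aa)
      }
      add_hom(pid, sprintf("NCLDV_REF_%03d", sample.int(50L, 1L)), aa)
      if (runif(1) < 0.3) {
        add_hom(pid, sprintf("CELL_REF_%03d", sample.int(50L, 1L)), aa)
      }
    } else if (cls == "cellular") {
      add_hmm("cellular", pid, sprintf("PFAM%05d", sample.int(900L, 1L)),
              max(30, rnorm(1, config$mu_cellular,
                            config$sigma_cellular)), 1e-10, aa)
      add_hom(pid, sprintf("CELL_REF_%03d", sample.int(50L, 1L)), aa)
    } else { # phage: VOG hits too, but homology only to phage/cellular
      add_hmm("viral", pid, sprintf("VOG%04d", sample.int(500L, 1L)),
              max(30, rnorm(1, config$mu_viral, config$sigma_viral)),
              1e-10, aa)
      add_hom(pid, sprintf("PHAGE_REF_%03d", sample.int(50L, 1L)), aa)
      if (runif(1) < 0.5) {
        add_hom(pid, sprintf("CELL_REF_%03d", sample.int(50L, 1L)), aa)
      }
    }
  }
  # at most 2 proteins of each cellular contig get a weak viral hit
  for (cid in contig_ids[class == "cellular"]) {
    pids <- proteins$protein_id[proteins$contig_id == cid]
    for (pid in utils::head(pids, 2L)) {
      aa <- proteins$length_aa[proteins$protein_id == pid]
      add_hmm("viral", pid, sprintf("VOG%04d", sample.int(500L, 1L)),
              runif(1, 5, 15), 1e-4, aa)
    }
  }

  bdir <- file.path(dir, "bins", bin_id)
  dir.create(bdir, recursive = TRUE, showWarnings = FALSE)
  contig_seqs <- stats::setNames(
    vapply(lens, rand_seq, character(1), alphabet = DNA_ALPHABET),
    contig_ids)
  write_fasta(contig_seqs, file.path(bdir, "contigs.fna"))
  prot_seqs <- stats::setNames(
    vapply(proteins$length_aa, rand_seq, character(1),
           alphabet = AA_ALPHABET),
    sprintf("%s # %d # %d # %s", proteins$protein_id, proteins$start,
            proteins$end, ifelse(proteins$strand == "+", "1", "-1")))
  write_fasta(prot_seqs, file.path(bdir, "proteins.faa"))
  write_domtblout_file(marker_hits, file.path(bdir, "markers.domtblout"))
  write_domtblout_file(do.call(rbind, viral_rows),
                       file.path(bdir, "viral.domtblout"))
  write_domtblout_file(do.call(rbind, cellular_rows) %||%
                         marker_hits[0, ],
                       file.path(bdir, "cellular.domtblout"))
  write_homology_file(do.call(rbind, hom_rows),
                      file.path(bdir, "homology.tsv"))

  viral_len <- sum(lens[class == "viral"])
  n_markers <- sum(plan$markers >= 1L)
  het_counts <- plan$markers[c("SFII", "VLTF3", "A32", "PolB")]
  n_multi <- sum(het_counts > 1L, na.rm = TRUE)
  list(
    truth = list(
      bin_id = bin_id, total_length_bp = sum(lens),
      viral_length_bp = viral_len,
      contig_classes = stats::setNames(as.list(class), contig_ids),
      contaminants = contig_ids[class != "viral"],
      contaminant_rules = stats::setNames(
        as.list(ifelse(class[class != "viral"] == "phage", "phage",
                       "cellular")),
        contig_ids[class != "viral"]),
      marker_copies = as.list(plan$markers),
      split_marker = plan$split_marker %||% NA,
      n_markers_present = n_markers,
      screen_pass_initial = n_markers >= 4L && sum(lens) > 100000L,
      screen_pass_final = n_markers >= 4L && viral_len > 100000L,
      qc_decision = if (n_multi >= 2L) "reject"
                    else if (n_multi == 1L) "accept_flagged"
                    else "accept"),
    proteins = proteins)
}

gen_aai_bundle <- function(config, dir) {
  adir <- file.path(dir, "aai")
  dir.create(adir, recursive = TRUE, showWarnings = FALSE)
  plan <- config$aai_plan
  truth <- list()
  for (pair in plan$pairs) {
    ga <- paste0(pair$id, "_src")
    gb <- paste0(pair$id, "_mut")
    src <- stats::setNames(
      vapply(rep(plan$protein_length, plan$n_proteins), rand_seq,
             character(1), alphabet = AA_ALPHABET),
      sprintf("%s_p%02d", ga, seq_len(plan$n_proteins)))
    mut <- mutate_proteome(src, pair$identity)
    names(mut) <- sprintf("%s_p%02d", gb, seq_len(plan$n_proteins))
    write_fasta(src, file.path(adir, paste0(ga, ".faa")))
    write_fasta(mut, file.path(adir, paste0(gb, ".faa")))
    pid <- vapply(seq_along(src), function(i) {
      observed_identity(src[[i]], mut[[i]])
    }, numeric(1))
    fwd <- data.frame(query = names(src), subject = names(mut),
                      pident = pid, aln_len = plan$protein_length,
                      evalue = 1e-50,
                      bitscore = 2 * plan$protein_length * pid / 100,
                      stringsAsFactors = FALSE)
    rev <- fwd
    rev$query <- fwd$subject
    rev$subject <- fwd$query
    write_homology_file(fwd, file.path(adir, paste0(ga, "__vs__", gb,
                                                    ".tsv")))
    write_homology_file(rev, file.path(adir, paste0(gb, "__vs__", ga,
                                                    ".tsv")))
    truth[[length(truth) + 1L]] <- list(
      genome_a = ga, genome_b = gb, target_identity = pair$identity,
      realized_identity = mean(pid), n_proteins = plan$n_proteins)
  }
  truth
}

gen_tree_bundle <- function(config, dir) {
  plan <- config$tree_plan
  subs <- character(plan$k)
  partition <- list()
  for (i in seq_len(plan$k)) {
    s <- plan$clade_sizes[i]
    tips <- sprintf("clade%d_g%02d", i, seq_len(s))
    if (s == 1L) {
      subs[i] <- sprintf("%s:%g", tips, plan$h_out)
    } else {
      sub <- ape::rcoal(s, tip.label = tips)
      depth <- max(ape::node.depth.edgelength(sub))
      sub$edge.length <- sub$edge.length / depth * plan$h_in
      nwk <- sub("[;]$", "", ape::write.tree(sub))
      subs[i] <- sprintf("%s:%g", nwk, plan$h_out - plan$h_in)
    }
    partition[tips] <- i
  }
  # explicit zero-length root edge keeps a k-furcating root recognisably
  # rooted for ape
  tree_str <- paste0("(", paste(subs, collapse = ","), "):0;")
  writeLines(tree_str, file.path(dir, "tree.nwk"))
  list(partition = partition, h_in = plan$h_in, h_out = plan$h_out,
       k = plan$k)
}

gen_og_bundle <- function(config, dir, tree_truth) {
  plan <- config$og_plan
  genomes <- names(tree_truth$partition)
  clade_of <- unlist(tree_truth$partition)
  n_g <- length(genomes)
  mat <- matrix(rbinom(n_g * plan$n_ogs, 1L, plan$p0), nrow = n_g,
                dimnames = list(genomes,
                                sprintf("OG_%05d", seq_len(plan$n_ogs))))
  enriched_idx <- sort(sample.int(plan$n_ogs, plan$n_enriched))
  in_clade <- clade_of == plan$enriched_clade
  for (j in enriched_idx) {
    # planted clade-specific families carry one or two copies per member
    present <- rbinom(sum(in_clade), 1L, plan$p1)
    mat[in_clade, j] <- present *
      (1L + rbinom(sum(in_clade), 1L, plan$extra_copy_p %||% 0.5))
    mat[!in_clade, j] <- rbinom(sum(!in_clade), 1L, plan$p0)
  }
  # every OG must occur somewhere
  empty <- which(colSums(mat) == 0L)
  for (j in empty) mat[sample.int(n_g, 1L), j] <- 1L
  storage.mode(mat) <- "integer"
  write_og_table(mat, file.path(dir, "og_table.tsv"))
  og_ids <- colnames(mat)
  enriched_ids <- og_ids[enriched_idx]
  ann <- data.frame(og_id = character(0), label = character(0))
  background <- setdiff(og_ids, enriched_ids)
  keep_ann <- background[runif(length(background)) < plan$annotated_frac]
  ann <- data.frame(
    og_id = c(enriched_ids, keep_ann),
    label = c(sprintf("planted_function_%02d", seq_along(enriched_ids)),
              sprintf("function_%s", keep_ann)),
    stringsAsFactors = FALSE)
  ann <- ann[order(ann$og_id), ]
  write_tsv(ann, file.path(dir, "og_annotations.tsv"))
  list(enriched_ogs = as.list(enriched_ids),
       enriched_clade_members = genomes[in_clade],
       p0 = plan$p0, p1 = plan$p1)
}

gen_pathway_bundle <- function(config, dir, bin_results) {
  plan <- config$pathway_plan
  pdir <- file.path(dir, "pathways")
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  target <- bin_results[[1]]
  genome_id <- target$truth$bin_id
  prot <- target$proteins[target$proteins$class == "viral", ]

  # glycolysis repertoire on scattered proteins of the first bin
  used <- character(0)
  pick <- function(n, from = prot) {
    avail <- setdiff(from$protein_id, used)
    stopifnot(length(avail) >= n)
    out <- sample(avail, n)
    used <<- c(used, out)
    out
  }
  enz_rows <- data.frame(genome_id = genome_id,
                         protein_id = pick(length(plan$glycolysis_steps)),
                         enzyme_id = plan$glycolysis_steps,
                         stringsAsFactors = FALSE)

  # co-localized TCA run on one contig: gene indices 1,2,4,5 (gaps 0,1,0),
  # plus an isolated ICD far downstream that must stay outside the cluster
  ctg_sizes <- table(prot$contig_id)
  big <- names(ctg_sizes)[ctg_sizes >= 14L]
  stopifnot(length(big) >= 1L)
  run_contig <- big[1]
  on_ctg <- prot[prot$contig_id == run_contig, ]
  on_ctg <- on_ctg[order(on_ctg$gene_index), ]
  run_idx <- c(1L, 2L, 4L, 5L)
  run_prot <- on_ctg$protein_id[match(run_idx, on_ctg$gene_index)]
  iso_prot <- on_ctg$protein_id[nrow(on_ctg)]
  iso_gap <- on_ctg$gene_index[nrow(on_ctg)] - max(run_idx) - 1L
  stopifnot(iso_gap > 5L)
  enz_rows <- rbind(enz_rows, data.frame(
    genome_id = genome_id,
    protein_id = c(run_prot, iso_prot),
    enzyme_id = c(plan$tca_run, "ICD"), stringsAsFactors = FALSE))
  write_tsv(enz_rows, file.path(pdir, "enzyme_annotations.tsv"))

  # fused G3P+PGK proteins, one per planted bin
  fusion_ids <- character(0)
  dom_rows <- list()
  for (b in seq_len(min(plan$fusion_bins, length(bin_results)))) {
    bp <- bin_results[[b]]$proteins
    bp <- bp[bp$class == "viral", ]
    cand <- bp[which.max(bp$length_aa), ]
    L <- cand$length_aa
    cut <- as.integer(floor(0.45 * L))
    dom_rows[[length(dom_rows) + 1L]] <- data.frame(
      protein_id = cand$protein_id,
      domain_id = c("G3P", "PGK"),
      start = c(1L, cut + 11L), end = c(cut, L), stringsAsFactors = FALSE)
    fusion_ids <- c(fusion_ids, cand$protein_id)
  }
  dom <- do.call(rbind, dom_rows)
  write_tsv(dom, file.path(pdir, "domain_annotations.tsv"))

  list(genome_id = genome_id,
       glycolysis_steps = as.list(plan$glycolysis_steps),
       glycolysis_completeness_pct =
         100 * length(plan$glycolysis_steps) / 10,
       tca_cluster = list(contig_id = run_contig,
                          members = as.list(run_prot)),
       isolated_tca_protein = iso_prot,
       fusion_proteins = as.list(fusion_ids))
}

#' Generate a complete synthetic input bundle
#'
#' Writes, under `out_dir`: per-bin contig/protein FASTAs and hit tables
#' (`bins/<id>/`), a subject class map, proteome pairs with directional hit
#' tables (`aai/`), an ultrametric Newick tree with planted clades, a
#' ProteinOrtho-dialect OG table with annotations, pathway/fusion/
#' co-localization annotation tables (`pathways/`), and `truth.json`
#' recording everything planted. Identical seed and config produce
#' byte-identical bundles.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly; the truth list is also written as
#'   `truth.json`.
#' @export
generate_bundle <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- withr::with_seed(config$seed, {
    bin_results <- lapply(config$bin_plans, gen_one_bin, config = config,
                          dir = out_dir)
    class_map <- data.frame(
      subject_id = c("NCLDV_REF_", "PHAGE_REF_", "CELL_REF_"),
      class = c("ncldv", "bacteriophage", "cellular"),
      stringsAsFactors = FALSE)
    utils::write.table(class_map, file.path(out_dir, "class_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    tree_truth <- gen_tree_bundle(config, out_dir)
    list(seed = config$seed,
         bins = lapply(bin_results, `[[`, "truth"),
         aai = gen_aai_bundle(config, out_dir),
         tree = tree_truth,
         og = gen_og_bundle(config, out_dir, tree_truth),
         pathways = gen_pathway_bundle(config, out_dir, bin_results))
  })
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Read the planted truth of a bundle
#' @param bundle_dir Bundle directory.
#' @return The truth list.
#' @export
read_truth <- function(bundle_dir) {
  jsonlite::read_json(file.path(bundle_dir, "truth.json"),
                      simplifyVector = FALSE)
}
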