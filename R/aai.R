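# Average amino acid identity (AAI) and alignment fraction (AF) between
# genome proteomes.
#
# AAI = mean percent identity across reciprocal-best-hit (RBH) protein
# pairs; AF = 100 * n_RBH / min(proteome sizes). For reporting, pairs with
# AF < 10 are masked to an AAI of 0 (too few shared proteins for the mean
# identity to be meaningful).
#
# The search backend is pluggable: best_hits() computes exact global
# Needleman-Wunsch alignments (BLOSUM62, affine gaps) via Biostrings, which
# makes AAI testable without an external aligner; best_hits_from_table()
# adapts parsed tabular output of an external search instead.

#' Best hits between two proteomes by exact global alignment
#'
#' For each query protein, aligns against every subject protein with
#' Needleman-Wunsch (BLOSUM62, affine gap costs) and keeps the
#' highest-scoring subject (ties by input order).
#'
#' @param query,subject_db Named character vectors of amino-acid sequences.
#' @param gap_opening,gap_extension Affine gap costs (defaults 10, 0.5).
#' @return data.frame with `query`, `subject`, `pident` (percent identity of
#'   the best alignment), `bitscore` (alignment score).
#' @export
best_hits <- function(query, subject_db, gap_opening = 10,
                      gap_extension = 0.5) {
  stopifnot(length(query) > 0, length(subject_db) > 0)
  subj_set <- Biostrings::AAStringSet(unname(subject_db))
  names(subj_set) <- names(subject_db)
  rows <- lapply(names(query), function(qid) {
    aln <- Biostrings::pairwiseAlignment(
      subj_set, Biostrings::AAString(query[[qid]]),
      substitutionMatrix = "BLOSUM62", gapOpening = gap_opening,
      gapExtension = gap_extension, type = "global")
    scores <- Biostrings::score(aln)
    b <- which.max(scores)
    data.frame(query = qid, subject = names(subject_db)[b],
               pident = Biostrings::pid(aln[b], type = "PID1"),
               bitscore = scores[b], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Best hits per query from a parsed tabular search
#'
#' Adapter for external-aligner output: reduces a hit table to the best
#' subject per query (max bitscore, ties by input order).
#'
#' @param hits data.frame with columns `query_protein_id` (or `query`),
#'   `subject_id` (or `subject`), `pct_identity` (or `pident`), `bitscore`.
#' @return data.frame with `query`, `subject`, `pident`, `bitscore`.
#' @export
best_hits_from_table <- function(hits) {
  query <- hits$query %||% hits$query_protein_id
  subject <- hits$subject %||% hits$subject_id
  pident <- hits$pident %||% hits$pct_identity
  stopifnot(!is.null(query), !is.null(subject), !is.null(pident),
            !is.null(hits$bitscore))
  df <- data.frame(query = query, subject = subject, pident = pident,
                   bitscore = hits$bitscore, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(df)
  df <- df[order(df$query, -df$bitscore, seq_len(nrow(df)),
                 method = "radix"), ]
  df[!duplicated(df$query), , drop = FALSE]
}

#' Reciprocal best hits between two genomes
#'
#' A pair `(p, q)` is an RBH iff `q` is `p`'s best forward hit and `p` is
#' `q`'s best reverse hit; the pair identity is the mean of the two
#' directional identities.
#'
#' @param hits_ab,hits_ba Directional hit tables (any table accepted by
#'   [best_hits_from_table()]); reduced to best-per-query internally.
#' @return data.frame with `protein_a`, `protein_b`, `pct_identity`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba) {
  ab <- best_hits_from_table(hits_ab)
  ba <- best_hits_from_table(hits_ba)
  if (nrow(ab) == 0L || nrow(ba) == 0L) {
    return(data.frame(protein_a = character(0), protein_b = character(0),
                      pct_identity = numeric(0), stringsAsFactors = FALSE))
  }
  back <- stats::setNames(ba$subject, ba$query)
  back_pid <- stats::setNames(ba$pident, ba$query)
  keep <- !is.na(back[ab$subject]) & back[ab$subject] == ab$query
  rbh <- ab[keep, , drop = FALSE]
  data.frame(protein_a = rbh$query, protein_b = rbh$subject,
             pct_identity = (rbh$pident +
                               unname(back_pid[rbh$subject])) / 2,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' AAI and alignment fraction from an RBH list
#'
#' @param rbh RBH table from [reciprocal_best_hits()].
#' @param n_a,n_b Proteome sizes of the two genomes (>= 1).
#' @param genome_a,genome_b Genome identifiers for the output row.
#' @param af_min AF masking threshold in percent (default 10): below it,
#'   `masked_aai` is 0.
#' @return One-row data.frame: `genome_a`, `genome_b`, `n_rbh`, `aai_pct`
#'   (`NA` when there are no RBHs), `af_pct`, `masked_aai`.
#' @export
compute_aai <- function(rbh, n_a, n_b, genome_a = "A", genome_b = "B",
                        af_min = 10) {
  stopifnot(n_a >= 1, n_b >= 1)
  n_rbh <- nrow(rbh)
  aai <- if (n_rbh == 0L) NA_real_ else mean(rbh$pct_identity)
  af <- 100 * n_rbh / min(n_a, n_b)
  masked <- if (n_rbh == 0L || af < af_min) 0 else aai
  data.frame(genome_a = genome_a, genome_b = genome_b, n_rbh = n_rbh,
             aai_pct = aai, af_pct = af, masked_aai = masked,
             stringsAsFactors = FALSE)
}

#' AAI between two proteomes via the alignment backend
#'
#' Convenience wrapper: directional [best_hits()], [reciprocal_best_hits()],
#' [compute_aai()].
#'
#' @param proteome_a,proteome_b Named character vectors of protein
#'   sequences.
#' @param genome_a,genome_b Genome identifiers.
#' @param ... Passed to [compute_aai()].
#' @return One-row data.frame as from [compute_aai()].
#' @export
aai_pair <- function(proteome_a, proteome_b, genome_a = "A", genome_b = "B",
                     ...) {
  ab <- best_hits(proteome_a, proteome_b)
  ba <- best_hits(proteome_b, proteome_a)
  compute_aai(reciprocal_best_hits(ab, ba), length(proteome_a),
              length(proteome_b), genome_a = genome_a, genome_b = genome_b,
              ...)
}

#' Square masked-AAI matrix over a genome set
#'
#' Each unordered pair is computed once and written symmetrically; the
#' diagonal is 100. Rows/columns can be ordered by a phylogeny's leaf
#' order.
#'
#' @param results data.frame of per-pair rows (as from [compute_aai()])
#'   covering every unordered pair of `genomes`.
#' @param genomes Genome ids; defaults to those present in `results`.
#' @param tree Optional `phylo`; when given, rows/columns follow
#'   `tree$tip.label`.
#' @return Symmetric numeric matrix of `masked_aai` values.
#' @export
aai_matrix <- function(results, genomes = NULL, tree = NULL) {
  if (!is.null(tree)) genomes <- tree$tip.label
  if (is.null(genomes)) {
    genomes <- unique(c(results$genome_a, results$genome_b))
  }
  m <- matrix(NA_real_, length(genomes), length(genomes),
              dimnames = list(genomes, genomes))
  diag(m) <- 100
  for (i in seq_len(nrow(results))) {
    a <- results$genome_a[i]
    b <- results$genome_b[i]
    if (!(a %in% genomes) || !(b %in% genomes)) next
    m[a, b] <- results$masked_aai[i]
    m[b, a] <- results$masked_aai[i]
  }
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)
    miss <- miss[miss[, 1] < miss[, 2], , drop = FALSE]
    stop("missing AAI pairs: ",
         paste(genomes[miss[, 1]], genomes[miss[, 2]], sep = "~",
               collapse = ", "))
  }
  m
}
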