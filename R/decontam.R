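# Per-contig viral-vs-cellular scoring and contamination removal.
#
# Each contig receives a signed score contrasting its proteins' best hits
# against virus-specific (VOG-like) and cellular-specific (Pfam-like) HMMs:
# negative = net cellular signal. Two removal rules follow:
#   cellular: score < 0 AND fewer than 3 proteins with viral-HMM hits AND no
#             top-5 homology hit to a known NCLDV protein;
#   phage:    at least one top-5 hit to a bacteriophage and zero hits to a
#             known NCLDV genome.

#' Score a contig by its viral-vs-cellular HMM signal
#'
#' Score = mean over the contig's proteins of
#' `max viral bitscore - max cellular bitscore`, a missing side contributing
#' 0. Proteins with no hits at all contribute 0 to the sum but still count
#' in the denominator, so the score is length-independent. A contig with no
#' proteins scores 0.
#'
#' @param protein_ids Ids of all proteins encoded on the contig.
#' @param viral_hits,cellular_hits HMM hit data.frames (any rows for other
#'   proteins are ignored).
#' @return Numeric score; positive = net viral signal.
#' @export
score_contig <- function(protein_ids, viral_hits, cellular_hits) {
  p <- length(protein_ids)
  if (p == 0L) return(0)
  max_by <- function(hits) {
    hits <- hits[hits$protein_id %in% protein_ids, , drop = FALSE]
    if (nrow(hits) == 0L) return(numeric(0))
    tapply(hits$bitscore, hits$protein_id, max)
  }
  mv <- max_by(viral_hits)
  mc <- max_by(cellular_hits)
  signed <- stats::setNames(numeric(p), protein_ids)
  if (length(mv)) signed[names(mv)] <- signed[names(mv)] + mv
  if (length(mc)) signed[names(mc)] <- signed[names(mc)] - mc
  mean(signed)
}

#' Compute per-contig contamination verdicts for a bin
#'
#' Applies the cellular rule, then the phage rule, to every contig of the
#' bin. `has_ncldv_top5` is true when any protein on the contig has any
#' rank 1..5 homology hit classed `ncldv` (analogously for
#' `has_phage_top5`).
#'
#' @param bin A `gv_bin`.
#' @param viral_hits,cellular_hits HMM hit data.frames for the bin's
#'   proteins (viral/cellular model databases).
#' @param homology_hits Ranked homology hits from [parse_tabular_hits()].
#' @param min_vog_proteins Cellular-rule threshold: contigs with at least
#'   this many distinct proteins carrying viral-HMM hits are protected
#'   (default 3).
#' @param cellular_combine `"and"` (default) requires all three cellular
#'   conditions; `"or"` removes on any of them.
#' @param max_evalue Viral hits above this e-value are ignored when counting
#'   VOG-hit proteins (default 1e-3).
#' @return data.frame with one row per contig: `contig_id`,
#'   `viralrecall_score`, `n_vog_hit_proteins`, `has_ncldv_top5`,
#'   `has_phage_top5`, `removed`, `removal_rule` (`cellular`, `phage`,
#'   `none`).
#' @export
contig_verdicts <- function(bin, viral_hits, cellular_hits, homology_hits,
                            min_vog_proteins = 3L,
                            cellular_combine = c("and", "or"),
                            max_evalue = 1e-3) {
  stopifnot(inherits(bin, "gv_bin"))
  cellular_combine <- match.arg(cellular_combine)
  vog <- viral_hits[viral_hits$evalue <= max_evalue, , drop = FALSE]
  rows <- lapply(bin$contigs$contig_id, function(cid) {
    pids <- bin$proteins$protein_id[bin$proteins$contig_id == cid]
    score <- score_contig(pids, viral_hits, cellular_hits)
    n_vog <- length(unique(vog$protein_id[vog$protein_id %in% pids]))
    hom <- homology_hits[homology_hits$query_protein_id %in% pids, ,
                         drop = FALSE]
    has_ncldv <- any(hom$subject_class == "ncldv")
    has_phage <- any(hom$subject_class == "bacteriophage")
    cellular_conditions <- c(score < 0, n_vog < min_vog_proteins, !has_ncldv)
    cellular <- if (cellular_combine == "and") all(cellular_conditions)
                else any(cellular_conditions)
    rule <- if (cellular) "cellular"
            else if (has_phage && !has_ncldv) "phage"
            else "none"
    data.frame(contig_id = cid, viralrecall_score = score,
               n_vog_hit_proteins = n_vog, has_ncldv_top5 = has_ncldv,
               has_phage_top5 = has_phage, removed = rule != "none",
               removal_rule = rule, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Remove flagged contigs from a bin
#'
#' @param bin A `gv_bin`.
#' @param verdicts Verdict table from [contig_verdicts()]; must cover every
#'   contig of the bin.
#' @return List with `bin` (the cleaned `gv_bin`, or `NULL` when every
#'   contig was removed), `dropped` (logical), and `report` (data.frame of
#'   removed contigs with rule and score).
#' @export
decontaminate_bin <- function(bin, verdicts) {
  stopifnot(inherits(bin, "gv_bin"))
  missing <- setdiff(bin$contigs$contig_id, verdicts$contig_id)
  if (length(missing)) stop("no verdict for contigs: ",
                            paste(missing, collapse = ", "))
  removed <- verdicts$contig_id[verdicts$removed]
  report <- verdicts[verdicts$removed,
                     c("contig_id", "removal_rule", "viralrecall_score")]
  rownames(report) <- NULL
  keep <- setdiff(bin$contigs$contig_id, removed)
  if (length(keep) == 0L) {
    warning("all contigs of bin ", bin$bin_id, " removed; bin dropped")
    return(list(bin = NULL, dropped = TRUE, report = report))
  }
  clean <- gv_bin(bin$bin_id,
                  bin$contigs[bin$contigs$contig_id %in% keep, ,
                              drop = FALSE],
                  bin$proteins[bin$proteins$contig_id %in% keep, ,
                               drop = FALSE])
  list(bin = clean, dropped = FALSE, report = report)
}
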