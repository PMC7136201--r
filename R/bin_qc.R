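# Strain-heterogeneity screening and assembly statistics.
#
# Multi-copy marker genes signal that a bin may mix closely related strains.
# MCP is ignored (multiple capsid-protein copies are commonplace in giant
# virus genomes); among SFII, VLTF3, A32 and PolB, two or more multi-copy
# markers reject the bin, exactly one flags it.

#' N50 of a set of contig lengths
#'
#' The length of the contig at which the cumulative length of contigs,
#' sorted descending, first reaches at least half the total.
#'
#' @param lengths Positive integer vector of contig lengths.
#' @return The N50, always one of `lengths`.
#' @export
n50 <- function(lengths) {
  stopifnot(length(lengths) >= 1L, all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Assembly statistics for a bin
#'
#' @param bin A `gv_bin` with at least one contig.
#' @return List with `n_contigs`, `total_length_bp`, `n50_bp`.
#' @export
assembly_stats <- function(bin) {
  stopifnot(inherits(bin, "gv_bin"))
  if (nrow(bin$contigs) == 0L) stop("empty bin: ", bin$bin_id)
  list(n_contigs = nrow(bin$contigs),
       total_length_bp = sum(bin$contigs$length_bp),
       n50_bp = n50(bin$contigs$length_bp))
}

#' Strain-heterogeneity decision from a marker profile
#'
#' @param profile A `marker_profile` computed on merged copies.
#' @param markers Markers considered (default SFII, VLTF3, A32, PolB; MCP is
#'   excluded by design).
#' @return List with `multicopy_markers` (ids with copy count > 1) and
#'   `decision` (`accept`, `accept_flagged`, `reject`).
#' @export
strain_heterogeneity <- function(profile,
                                 markers = c("SFII", "VLTF3", "A32",
                                             "PolB")) {
  counts <- copy_counts(profile)[markers]
  multi <- names(counts)[counts > 1L]
  decision <- if (length(multi) >= 2L) "reject"
              else if (length(multi) == 1L) "accept_flagged"
              else "accept"
  list(multicopy_markers = multi, decision = decision)
}

#' Full QC report for a bin
#'
#' @param bin A `gv_bin`.
#' @param profile The bin's `marker_profile` (post-decontamination).
#' @return One-row data.frame: `bin_id`, `multicopy_markers`
#'   (`,`-collapsed), `decision`, `n_contigs`, `n50_bp`, `total_length_bp`.
#' @export
qc_report <- function(bin, profile) {
  het <- strain_heterogeneity(profile)
  stats <- assembly_stats(bin)
  data.frame(bin_id = bin$bin_id,
             multicopy_markers = paste(het$multicopy_markers,
                                       collapse = ","),
             decision = het$decision, n_contigs = stats$n_contigs,
             n50_bp = stats$n50_bp,
             total_length_bp = stats$total_length_bp,
             stringsAsFactors = FALSE)
}
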