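# End-to-end driver: bin -> marker screen -> decontamination -> re-screen
# -> strain-heterogeneity QC, over an on-disk bundle laid out as written by
# generate_bundle() (bins/<id>/{contigs.fna, proteins.faa,
# markers.domtblout, viral.domtblout, cellular.domtblout, homology.tsv}
# plus a shared class_map.tsv).

#' Run screening, decontamination and QC over a bundle of bins
#'
#' For every bin directory: reads the bin and its hit tables, screens on
#' markers and length, computes per-contig contamination verdicts, removes
#' flagged contigs, re-screens the cleaned bin (decontamination may drop a
#' bin below 4 markers or 100 Kbp), and reports strain heterogeneity and
#' assembly statistics for bins passing the final screen.
#'
#' @param bundle_dir Directory containing `bins/` and `class_map.tsv`.
#' @param registry A [marker_registry()].
#' @param min_markers,min_length_bp Screen thresholds (defaults 4, 100000).
#' @return List with `screen_initial`, `screen_final` (data.frames from
#'   [screen_table()]), `removals` (per-bin removal reports, rbind-ed with
#'   a `bin_id` column), `qc` (data.frame from [qc_report()] for bins
#'   passing the final screen), and `bins` (the cleaned `gv_bin` objects).
#' @export
process_bins <- function(bundle_dir, registry = marker_registry(),
                         min_markers = 4L, min_length_bp = 100000L) {
  bin_dirs <- list.dirs(file.path(bundle_dir, "bins"), recursive = FALSE)
  stopifnot(length(bin_dirs) >= 1L)
  class_map <- read_class_map(file.path(bundle_dir, "class_map.tsv"))
  screen_initial <- list()
  screen_final <- list()
  removals <- list()
  qc <- list()
  bins <- list()
  for (bd in bin_dirs) {
    bin_id <- basename(bd)
    bin <- read_bin(file.path(bd, "contigs.fna"),
                    file.path(bd, "proteins.faa"), bin_id = bin_id)
    marker_hits <- parse_domtblout(file.path(bd, "markers.domtblout"),
                                   "marker")
    viral_hits <- parse_domtblout(file.path(bd, "viral.domtblout"),
                                  "viral")
    cellular_hits <- parse_domtblout(file.path(bd, "cellular.domtblout"),
                                     "cellular")
    homology <- parse_tabular_hits(file.path(bd, "homology.tsv"),
                                   class_map)
    profile <- marker_profile(marker_hits, registry, bin_id)
    screen_initial[[bin_id]] <- screen_bin(bin, profile, min_markers,
                                           min_length_bp)
    verdicts <- contig_verdicts(bin, viral_hits, cellular_hits, homology)
    res <- decontaminate_bin(bin, verdicts)
    if (nrow(res$report)) {
      removals[[bin_id]] <- cbind(bin_id = bin_id, res$report)
    }
    if (res$dropped) next
    clean <- res$bin
    keep_prot <- clean$proteins$protein_id
    profile2 <- marker_profile(
      marker_hits[marker_hits$protein_id %in% keep_prot, , drop = FALSE],
      registry, bin_id)
    decision <- screen_bin(clean, profile2, min_markers, min_length_bp)
    screen_final[[bin_id]] <- decision
    bins[[bin_id]] <- clean
    if (decision$pass) {
      qc[[bin_id]] <- qc_report(clean, profile2)
    }
  }
  list(screen_initial = screen_table(screen_initial),
       screen_final = screen_table(screen_final),
       removals = if (length(removals)) do.call(rbind, c(removals,
                                                         make.row.names =
                                                           FALSE))
                  else NULL,
       qc = if (length(qc)) do.call(rbind, c(qc, make.row.names = FALSE))
            else NULL,
       bins = bins)
}
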