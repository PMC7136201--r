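# Marker-gene screening of candidate giant-virus bins.
#
# Five conserved NCLDV protein families are used: DNA Polymerase B (PolB),
# Virus-like transcription factor 3 (VLTF3), Major Capsid Protein (MCP),
# packaging ATPase (A32) and Superfamily II helicase (SFII). A bin is kept
# when at least 4 of the 5 markers are detected (after merging split genes)
# and its total length exceeds 100 Kbp.

#' The five NCLDV marker ids, in supermatrix concatenation order
#' @export
NCLDV_MARKERS <- c("PolB", "VLTF3", "MCP", "A32", "SFII")

#' Marker model registry with per-model bitscore cutoffs
#'
#' Cutoffs are calibrated per model in practice; the default of 30 bits for
#' all five is a conservative configuration value and can be overridden
#' per model.
#'
#' @param cutoffs Named numeric vector of positive bitscore cutoffs for
#'   exactly the five markers.
#' @return Named numeric vector of class `marker_registry`.
#' @export
marker_registry <- function(cutoffs = c(PolB = 30, VLTF3 = 30, MCP = 30,
                                        A32 = 30, SFII = 30)) {
  stopifnot(setequal(names(cutoffs), NCLDV_MARKERS), all(cutoffs > 0))
  structure(cutoffs[NCLDV_MARKERS], class = "marker_registry")
}

#' Filter marker hits by model-specific score cutoffs
#'
#' Keeps hits with bitscore greater than or equal to the model's cutoff
#' (boundary inclusive). All passing domain rows are retained, so split-gene
#' coordinates remain available to [merge_split_hits()].
#'
#' @param hits HMM hit data.frame (`model_db == "marker"`).
#' @param registry A [marker_registry()].
#' @return Filtered hit data.frame.
#' @export
filter_marker_hits <- function(hits, registry) {
  stopifnot(inherits(registry, "marker_registry"))
  if (nrow(hits) == 0L) return(hits)
  unknown <- setdiff(unique(hits$model_id), names(registry))
  if (length(unknown)) stop("hits reference unknown marker models: ",
                            paste(unknown, collapse = ", "))
  hits[hits$bitscore >= unname(registry[hits$model_id]), , drop = FALSE]
}

#' Merge split-gene hits into marker copies
#'
#' Giant-virus marker genes are occasionally split across two proteins
#' (introns, assembly breaks). Hits from distinct proteins against the same
#' model are merged into one copy when their model-coordinate intervals do
#' not overlap by more than `max_overlap` residues; proteins within a copy
#' are ordered by `hmm_from`, giving the concatenation order. Merging never
#' increases the copy count relative to naive per-protein counting.
#'
#' @param hits Hit data.frame for one genome and one marker model (multiple
#'   domain rows per protein allowed; the union interval per protein is
#'   used).
#' @param max_overlap Maximum tolerated model-coordinate overlap in residues
#'   (default 10).
#' @return List of copies; each copy is a list with `proteins` (ids in
#'   concatenation order), `hmm_from`, `hmm_to`.
#' @export
merge_split_hits <- function(hits, max_overlap = 10L) {
  if (nrow(hits) == 0L) return(list())
  stopifnot(length(unique(hits$model_id)) == 1L)
  from <- tapply(hits$hmm_from, hits$protein_id, min)
  to <- tapply(hits$hmm_to, hits$protein_id, max)
  spans <- data.frame(protein_id = names(from), from = as.numeric(from),
                      to = as.numeric(to[names(from)]),
                      stringsAsFactors = FALSE)
  spans <- spans[order(spans$from, spans$to), ]
  copies <- list()
  cur <- NULL
  for (i in seq_len(nrow(spans))) {
    if (is.null(cur)) {
      cur <- list(proteins = spans$protein_id[i], hmm_from = spans$from[i],
                  hmm_to = spans$to[i])
      next
    }
    overlap <- cur$hmm_to - spans$from[i] + 1
    if (overlap <= max_overlap) {
      cur$proteins <- c(cur$proteins, spans$protein_id[i])
      cur$hmm_to <- max(cur$hmm_to, spans$to[i])
    } else {
      copies <- c(copies, list(cur))
      cur <- list(proteins = spans$protein_id[i], hmm_from = spans$from[i],
                  hmm_to = spans$to[i])
    }
  }
  c(copies, list(cur))
}

#' Build a per-genome marker profile
#'
#' Applies the score cutoffs, then merges split genes per marker to obtain
#' copy counts and copy membership.
#'
#' @param hits HMM hit data.frame for one genome against the marker models.
#' @param registry A [marker_registry()].
#' @param genome_id Genome/bin identifier.
#' @param max_overlap Passed to [merge_split_hits()].
#' @return Object of class `marker_profile`: list with `genome_id` and
#'   `markers`, a per-marker list of `copy_count` and `copies`.
#' @export
marker_profile <- function(hits, registry, genome_id,
                           max_overlap = 10L) {
  kept <- filter_marker_hits(hits, registry)
  markers <- lapply(stats::setNames(nm = NCLDV_MARKERS), function(m) {
    copies <- merge_split_hits(kept[kept$model_id == m, , drop = FALSE],
                               max_overlap = max_overlap)
    list(copy_count = length(copies), copies = copies)
  })
  structure(list(genome_id = genome_id, markers = markers),
            class = "marker_profile")
}

#' Marker copy counts from a profile
#' @param profile A `marker_profile`.
#' @return Named integer vector over the five markers.
#' @export
copy_counts <- function(profile) {
  stopifnot(inherits(profile, "marker_profile"))
  vapply(profile$markers, function(m) m$copy_count, integer(1))
}

#' @export
print.marker_profile <- function(x, ...) {
  cat("<marker_profile>", x$genome_id, "--",
      paste(names(copy_counts(x)), copy_counts(x), sep = ":",
            collapse = " "), "\n")
  invisible(x)
}

#' Screen a bin on marker presence and total length
#'
#' A bin passes when at least `min_markers` distinct markers have copy
#' count >= 1 and the summed contig length exceeds `min_length_bp`
#' (strictly). Failed criteria are listed in `reasons`.
#'
#' @param bin A `gv_bin`.
#' @param profile The bin's `marker_profile`.
#' @param min_markers Minimum distinct markers (default 4).
#' @param min_length_bp Length threshold in bp, exclusive (default 100000).
#' @return List of class `screen_decision` with fields `bin_id`,
#'   `n_markers_present`, `total_length_bp`, `pass`, `reasons`.
#' @export
screen_bin <- function(bin, profile, min_markers = 4L,
                       min_length_bp = 100000L) {
  stopifnot(inherits(bin, "gv_bin"), inherits(profile, "marker_profile"))
  n_markers <- sum(copy_counts(profile) >= 1L)
  total_len <- bin_length(bin)
  reasons <- character(0)
  if (n_markers < min_markers) {
    reasons <- c(reasons, sprintf("markers < %d (found %d)", min_markers,
                                  n_markers))
  }
  if (total_len <= min_length_bp) {
    reasons <- c(reasons, sprintf("length <= %d bp (found %d)",
                                  min_length_bp, total_len))
  }
  structure(list(bin_id = bin$bin_id, n_markers_present = n_markers,
                 total_length_bp = total_len,
                 pass = length(reasons) == 0L, reasons = reasons),
            class = "screen_decision")
}

#' Tabulate screen decisions
#' @param decisions List of `screen_decision` objects.
#' @return data.frame, one row per bin; reasons `;`-collapsed.
#' @export
screen_table <- function(decisions) {
  do.call(rbind, lapply(decisions, function(d) {
    data.frame(bin_id = d$bin_id, n_markers_present = d$n_markers_present,
               total_length_bp = d$total_length_bp, pass = d$pass,
               reasons = paste(d$reasons, collapse = "; "),
               stringsAsFactors = FALSE)
  }))
}

#' Concatenate per-marker alignments into a supermatrix
#'
#' Markers are concatenated in the fixed order PolB, VLTF3, MCP, A32, SFII
#' (restricted to those supplied). Genomes missing from a marker alignment
#' are filled with gaps. A partition table records the 1-based column range
#' of each marker.
#'
#' @param alignments Named list (marker -> alignment); an alignment is a
#'   named character vector of equal-length aligned rows, ids = genome ids.
#' @param genomes Genome set for the supermatrix rows; defaults to the union
#'   over alignments.
#' @param marker_order Concatenation order.
#' @return List with `alignment` (named character vector) and `partitions`
#'   (data.frame marker/start/end).
#' @export
build_supermatrix <- function(alignments, genomes = NULL,
                              marker_order = NCLDV_MARKERS) {
  used <- intersect(marker_order, names(alignments))
  stopifnot(length(used) >= 1L)
  for (m in used) {
    aln <- alignments[[m]]
    if (anyDuplicated(names(aln))) {
      stop("duplicate genome id within marker alignment ", m)
    }
    if (length(unique(nchar(aln))) != 1L) {
      stop("ragged alignment for marker ", m)
    }
  }
  if (is.null(genomes)) {
    genomes <- unique(unlist(lapply(alignments[used], names)))
  }
  widths <- vapply(alignments[used], function(a) nchar(a[[1]]), integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  rows <- vapply(genomes, function(g) {
    paste(vapply(used, function(m) {
      aln <- alignments[[m]]
      if (g %in% names(aln)) aln[[g]] else strrep("-", widths[[m]])
    }, character(1)), collapse = "")
  }, character(1))
  list(alignment = rows,
       partitions = data.frame(marker = used, start = starts, end = ends,
                               stringsAsFactors = FALSE, row.names = NULL))
}

#' Trim alignment columns by gap fraction
#'
#' A column is retained when its fraction of non-gap characters is at least
#' `gt` (boundary inclusive, matching trimAl's `-gt` semantics). Only `-` is
#' a gap; `X` counts as a residue. Idempotent.
#'
#' @param alignment Named character vector of equal-length rows.
#' @param gt Minimum non-gap fraction in (0, 1] (default 0.1).
#' @return Trimmed alignment; row order preserved.
#' @export
trim_alignment <- function(alignment, gt = 0.1) {
  stopifnot(gt > 0, gt <= 1, length(alignment) >= 1L)
  widths <- unique(nchar(alignment))
  if (length(widths) != 1L) stop("ragged alignment")
  if (widths == 0L) stop("alignment of width 0")
  mat <- do.call(rbind, strsplit(alignment, ""))
  frac <- colMeans(mat != "-")
  keep <- frac >= gt - 1e-12
  trimmed <- apply(mat[, keep, drop = FALSE], 1L, paste, collapse = "")
  stats::setNames(as.character(trimmed), names(alignment))
}
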