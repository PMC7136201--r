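# Pathway-completeness profiling, fused-domain detection, gene
# co-localization calls and clade-prevalence tables for metabolic genes.
#
# Pathway definitions ship as editable YAML (inst/extdata/pathways.yaml):
# ordered steps, each satisfied by any of a set of acceptable enzyme ids
# (e.g. the succinate dehydrogenase step by any of its subunits).

#' Read pathway definitions from YAML
#'
#' The YAML lists pathways as ordered steps, each with the enzyme ids that
#' satisfy it. The packaged default covers glycolysis (10 steps), the TCA
#' cycle (8 steps, succinate dehydrogenase satisfied by any subunit),
#' gluconeogenesis-specific enzymes and the glyoxylate shunt.
#'
#' @param path YAML path; defaults to the packaged definitions.
#' @return Named list of pathways; each pathway is a named list
#'   step id -> character vector of acceptable enzyme ids, in step order.
#' @export
read_pathway_defs <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pathways.yaml", package = "gvpipe",
                        mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  stopifnot(!is.null(raw$pathways))
  defs <- lapply(raw$pathways, function(pw) {
    steps <- lapply(pw$steps, function(s) as.character(s$enzymes))
    names(steps) <- vapply(pw$steps, function(s) as.character(s$id),
                           character(1))
    if (anyDuplicated(names(steps))) stop("duplicate step ids in pathway")
    steps
  })
  defs
}

#' Pathway completeness for one genome
#'
#' A step counts as present when any of its acceptable enzymes is annotated
#' at least once (copy number is ignored). Completeness is the percentage
#' of steps present. Enzyme ids unknown to the pathway trigger a warning
#' and are ignored.
#'
#' @param enzymes Character vector of enzyme ids annotated in the genome
#'   (or a data.frame with an `enzyme_id` column).
#' @param pathway One pathway from [read_pathway_defs()] (named list
#'   step -> enzyme ids).
#' @param pathway_id Identifier for the output.
#' @param genome_id Identifier for the output.
#' @param warn_unknown Warn about enzyme ids matching no step
#'   (default TRUE; ids are routinely shared across pathway definitions,
#'   so set FALSE when profiling several pathways from one annotation set).
#' @return One-row data.frame: `genome_id`, `pathway_id`, `n_steps`,
#'   `steps_present` (`,`-collapsed), `completeness_pct`.
#' @export
pathway_completeness <- function(enzymes, pathway, pathway_id = "pathway",
                                 genome_id = "genome",
                                 warn_unknown = TRUE) {
  if (is.data.frame(enzymes)) enzymes <- enzymes$enzyme_id
  enzymes <- unique(as.character(enzymes))
  known <- unique(unlist(pathway))
  unknown <- setdiff(enzymes, known)
  if (length(unknown) && warn_unknown) {
    warning("enzyme ids not in pathway '", pathway_id, "', ignored: ",
            paste(unknown, collapse = ", "))
  }
  present <- names(pathway)[vapply(pathway,
                                   function(acc) any(acc %in% enzymes),
                                   logical(1))]
  data.frame(genome_id = genome_id, pathway_id = pathway_id,
             n_steps = length(pathway),
             steps_present = paste(present, collapse = ","),
             completeness_pct = 100 * length(present) / length(pathway),
             stringsAsFactors = FALSE)
}

#' Pathway completeness for many genomes across all pathways
#'
#' @param annotations data.frame with columns `genome_id`, `enzyme_id`
#'   (a `protein_id` column may be present and is ignored here).
#' @param defs Pathway definitions from [read_pathway_defs()].
#' @return data.frame, one row per genome x pathway.
#' @export
pathway_profiles <- function(annotations, defs = read_pathway_defs()) {
  stopifnot(all(c("genome_id", "enzyme_id") %in% names(annotations)))
  rows <- list()
  for (g in unique(annotations$genome_id)) {
    enz <- annotations$enzyme_id[annotations$genome_id == g]
    for (pw in names(defs)) {
      rows[[length(rows) + 1L]] <-
        pathway_completeness(enz, defs[[pw]], pathway_id = pw,
                             genome_id = g, warn_unknown = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Detect fused-domain proteins
#'
#' A protein is called a fusion of domains `d1` and `d2` when it carries at
#' least one copy of each with a coordinate overlap of at most
#' `max_overlap` amino acids (the two catalytic regions must be essentially
#' distinct, as in the G3P+PGK fusion gene). The reported order is the
#' order of the two domains along the protein.
#'
#' @param domains data.frame with columns `protein_id`, `domain_id`,
#'   `start`, `end` (1-based inclusive aa).
#' @param d1,d2 Domain ids of the fusion pair.
#' @param max_overlap Maximum tolerated overlap in aa (default 10).
#' @return data.frame of calls: `protein_id`, `first_domain`,
#'   `second_domain`, `start1`, `end1`, `start2`, `end2`.
#' @export
detect_fusion <- function(domains, d1, d2, max_overlap = 10L) {
  stopifnot(all(c("protein_id", "domain_id", "start", "end") %in%
                  names(domains)))
  calls <- list()
  for (pid in unique(domains$protein_id)) {
    sub <- domains[domains$protein_id == pid, , drop = FALSE]
    a <- sub[sub$domain_id == d1, , drop = FALSE]
    b <- sub[sub$domain_id == d2, , drop = FALSE]
    if (nrow(a) == 0L || nrow(b) == 0L) next
    best <- NULL
    for (i in seq_len(nrow(a))) {
      for (j in seq_len(nrow(b))) {
        overlap <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]) + 1L
        if (overlap <= max_overlap) {
          cand <- if (a$start[i] <= b$start[j]) {
            data.frame(protein_id = pid, first_domain = d1,
                       second_domain = d2, start1 = a$start[i],
                       end1 = a$end[i], start2 = b$start[j],
                       end2 = b$end[j], stringsAsFactors = FALSE)
          } else {
            data.frame(protein_id = pid, first_domain = d2,
                       second_domain = d1, start1 = b$start[j],
                       end1 = b$end[j], start2 = a$start[i],
                       end2 = a$end[i], stringsAsFactors = FALSE)
          }
          if (is.null(best) || cand$start1 < best$start1) best <- cand
        }
      }
    }
    if (!is.null(best)) calls[[length(calls) + 1L]] <- best
  }
  if (length(calls) == 0L) {
    return(data.frame(protein_id = character(0), first_domain = character(0),
                      second_domain = character(0), start1 = integer(0),
                      end1 = integer(0), start2 = integer(0),
                      end2 = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Co-localized runs of target genes on contigs
#'
#' A cluster is a maximal run of target genes in which consecutive members
#' are separated by at most `max_gap` intervening non-target genes; only
#' clusters with at least 2 members are reported. Used to detect e.g. TCA
#' cycle genes co-localized on viral contigs.
#'
#' @param gene_table data.frame with columns `contig_id`, `gene_index`,
#'   `protein_id` (the full gene order per contig).
#' @param target_proteins Protein ids encoding the target enzyme set.
#' @param max_gap Maximum intervening non-target genes (default 5).
#' @return data.frame of clusters: `contig_id`, `n_genes`, `members`
#'   (list-column of protein ids in gene order), `span_from`, `span_to`
#'   (gene indices).
#' @export
colocalization <- function(gene_table, target_proteins, max_gap = 5L) {
  stopifnot(all(c("contig_id", "gene_index", "protein_id") %in%
                  names(gene_table)))
  clusters <- list()
  for (cid in unique(gene_table$contig_id)) {
    sub <- gene_table[gene_table$contig_id == cid, , drop = FALSE]
    sub <- sub[order(sub$gene_index), , drop = FALSE]
    hit <- sub[sub$protein_id %in% target_proteins, , drop = FALSE]
    if (nrow(hit) < 2L) next
    gaps <- diff(hit$gene_index) - 1L
    run_id <- cumsum(c(0L, gaps > max_gap))
    for (r in unique(run_id)) {
      members <- hit[run_id == r, , drop = FALSE]
      if (nrow(members) < 2L) next
      clusters[[length(clusters) + 1L]] <- data.frame(
        contig_id = cid, n_genes = nrow(members),
        members = I(list(members$protein_id)),
        span_from = min(members$gene_index),
        span_to = max(members$gene_index), stringsAsFactors = FALSE)
    }
  }
  if (length(clusters) == 0L) {
    return(data.frame(contig_id = character(0), n_genes = integer(0),
                      members = I(list()), span_from = integer(0),
                      span_to = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, clusters)
  rownames(out) <- NULL
  out
}

#' Per-clade feature prevalence
#'
#' Percentage of genomes in each clade carrying each feature.
#'
#' @param presence data.frame with columns `genome_id`, `feature_id`
#'   (one row per genome-feature occurrence), or a logical/numeric
#'   genome x feature matrix.
#' @param clades Named vector genome -> clade covering every genome.
#' @return data.frame: `clade_id`, `feature_id`, `n_genomes`, `clade_size`,
#'   `pct`.
#' @export
clade_prevalence <- function(presence, clades) {
  if (is.matrix(presence)) {
    idx <- which(presence >= 1, arr.ind = TRUE)
    presence <- data.frame(genome_id = rownames(presence)[idx[, 1]],
                           feature_id = colnames(presence)[idx[, 2]],
                           stringsAsFactors = FALSE)
  }
  stopifnot(all(c("genome_id", "feature_id") %in% names(presence)))
  genomes <- names(clades)
  missing <- setdiff(unique(presence$genome_id), genomes)
  if (length(missing)) stop("genomes without clade assignment: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  sizes <- table(as.character(clades))
  features <- unique(presence$feature_id)
  rows <- list()
  for (clade in names(sizes)) {
    members <- genomes[as.character(clades) == clade]
    for (f in features) {
      carriers <- unique(presence$genome_id[presence$feature_id == f])
      n <- sum(carriers %in% members)
      rows[[length(rows) + 1L]] <- data.frame(
        clade_id = clade, feature_id = f, n_genomes = n,
        clade_size = as.integer(sizes[[clade]]),
        pct = 100 * n / as.integer(sizes[[clade]]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
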