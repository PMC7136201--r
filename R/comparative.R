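# Orthologous-group (OG) matrix analytics: frequency spectrum, annotation
# coverage, power-law fit of the degree distribution, bipartite
# genome-gene-family network, and clade-specific OG enrichment.

#' OG frequency spectrum and catalogue summary
#'
#' Genome count per OG (number of genomes carrying at least one copy),
#' singleton counts, and annotation coverage, with integer-percent
#' fractions.
#'
#' @param mat Genome x OG count matrix (e.g. from [parse_og_table()]).
#' @param annotations Optional named character vector og -> label; OGs
#'   absent from it (or `NA`) count as unannotated.
#' @return List with `genome_counts` (named integer per OG) and `summary`
#'   (list: `n_ogs`, `n_singletons`, `singleton_pct`, `n_annotated`,
#'   `annotated_pct`).
#' @export
frequency_spectrum <- function(mat, annotations = NULL) {
  stopifnot(is.matrix(mat), ncol(mat) >= 1L)
  counts <- colSums(mat >= 1L)
  n_ogs <- ncol(mat)
  n_singletons <- sum(counts == 1L)
  summary <- list(n_ogs = n_ogs, n_singletons = n_singletons,
                  singleton_pct = pct_of(n_singletons, n_ogs))
  if (!is.null(annotations)) {
    ann <- annotations[colnames(mat)]
    n_annotated <- sum(!is.na(ann))
    summary$n_annotated <- n_annotated
    summary$annotated_pct <- pct_of(n_annotated, n_ogs)
  }
  list(genome_counts = counts, summary = summary)
}

#' Continuous maximum-likelihood power-law exponent
#'
#' `alpha = 1 + n / sum(log(x / xmin))` -- the continuous-approximation MLE
#' for a power-law tail with fixed `xmin`. Typically applied to the OG
#' degree distribution (genome counts per OG).
#'
#' @param x Counts, all `>= xmin`.
#' @param xmin Lower bound of the power-law regime (default 1).
#' @return The exponent `alpha`.
#' @export
power_law_alpha <- function(x, xmin = 1) {
  stopifnot(length(x) >= 2L, all(x >= xmin), xmin > 0)
  s <- sum(log(x / xmin))
  if (s == 0) stop("all counts equal xmin; power-law exponent undefined")
  1 + length(x) / s
}

#' Bipartite genome/OG network
#'
#' Genome nodes are connected to the OG nodes they encode; only OGs present
#' in more than `min_genomes` genomes are kept (strict threshold).
#'
#' @param mat Genome x OG count matrix.
#' @param min_genomes Strict lower bound on OG genome count (default 5,
#'   i.e. OGs in more than 5 genomes are kept).
#' @param genome_sizes Optional named numeric vector genome -> genome size,
#'   stored as a vertex attribute.
#' @return An igraph bipartite graph (`V(g)$type`: FALSE = genome, TRUE =
#'   OG); empty (with a warning) when no OG passes the filter.
#' @export
bipartite_network <- function(mat, min_genomes = 5L, genome_sizes = NULL) {
  stopifnot(is.matrix(mat))
  keep <- colSums(mat >= 1L) > min_genomes
  if (!any(keep)) {
    warning("no OG present in more than ", min_genomes,
            " genomes; empty network")
    g <- igraph::make_empty_graph(directed = FALSE)
    return(g)
  }
  sub <- mat[, keep, drop = FALSE]
  idx <- which(sub >= 1L, arr.ind = TRUE)
  edges <- data.frame(from = rownames(sub)[idx[, 1]],
                      to = colnames(sub)[idx[, 2]],
                      stringsAsFactors = FALSE)
  vertices <- data.frame(
    name = c(rownames(sub), colnames(sub)),
    type = c(rep(FALSE, nrow(sub)), rep(TRUE, ncol(sub))),
    stringsAsFactors = FALSE)
  if (!is.null(genome_sizes)) {
    vertices$genome_size <- c(unname(genome_sizes[rownames(sub)]),
                              rep(NA_real_, ncol(sub)))
  }
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = vertices)
}

#' Clade-specific OG enrichment
#'
#' For every clade with more than `min_clade_size` members and every
#' annotated OG present in more than `min_og_genomes` genomes, a two-sided
#' Mann-Whitney U test compares per-genome copy counts inside the clade
#' against all other genomes (normal approximation with tie and continuity
#' correction). P-values are Benjamini-Hochberg corrected across all tests
#' performed; an OG is called significant for a clade when its adjusted
#' p-value is below `alpha` and the clade's mean count exceeds the
#' background mean.
#'
#' @param mat Genome x OG count matrix.
#' @param clades Named character/factor vector genome -> clade id, covering
#'   all rows of `mat`.
#' @param annotations Named character vector og -> label; unannotated OGs
#'   are not tested.
#' @param min_clade_size Strict lower bound on clade size (default 5).
#' @param min_og_genomes Strict lower bound on OG genome count (default 6).
#' @param alpha Significance threshold on the adjusted p-value
#'   (default 0.01).
#' @param membership `"counts"` (default) tests per-genome copy counts;
#'   `"binary"` tests presence/absence.
#' @return data.frame with one row per (clade, OG) test: `og_id`,
#'   `clade_id`, `u_statistic`, `p_value`, `q_value`, `direction`
#'   (`enriched`/`depleted`), `significant`.
#' @export
og_enrichment <- function(mat, clades, annotations,
                          min_clade_size = 5L, min_og_genomes = 6L,
                          alpha = 0.01,
                          membership = c("counts", "binary")) {
  membership <- match.arg(membership)
  stopifnot(is.matrix(mat))
  missing <- setdiff(rownames(mat), names(clades))
  if (length(missing)) stop("genomes without clade assignment: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  cl <- as.character(clades[rownames(mat)])
  sizes <- table(cl)
  tested_clades <- names(sizes)[sizes > min_clade_size]
  og_counts <- colSums(mat >= 1L)
  ann <- annotations[colnames(mat)]
  tested_ogs <- colnames(mat)[!is.na(ann) & og_counts > min_og_genomes]
  if (length(tested_clades) == 0L || length(tested_ogs) == 0L) {
    return(data.frame(og_id = character(0), clade_id = character(0),
                      u_statistic = numeric(0), p_value = numeric(0),
                      q_value = numeric(0), direction = character(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  }
  vals <- if (membership == "binary") (mat >= 1L) * 1L else mat
  rows <- vector("list", length(tested_clades) * length(tested_ogs))
  i <- 0L
  for (clade in tested_clades) {
    in_clade <- cl == clade
    for (og in tested_ogs) {
      x <- vals[in_clade, og]
      y <- vals[!in_clade, og]
      wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                correct = TRUE))
      p <- wt$p.value
      if (is.na(p)) p <- 1  # all values tied: no evidence either way
      i <- i + 1L
      rows[[i]] <- data.frame(
        og_id = og, clade_id = clade,
        u_statistic = unname(wt$statistic), p_value = p,
        direction = if (mean(x) > mean(y)) "enriched" else "depleted",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value < alpha & out$direction == "enriched"
  out[, c("og_id", "clade_id", "u_statistic", "p_value", "q_value",
          "direction", "significant")]
}
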