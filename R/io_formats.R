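# Readers and writers for the external formats the pipeline touches.
# All downstream modules consume only the plain-R structures produced here:
#   - sequences: named character vectors (id -> sequence)
#   - HMM hits:  data.frame(protein_id, model_id, model_db, bitscore, evalue,
#                hmm_from, hmm_to, ali_from, ali_to)
#   - homology hits: data.frame(query_protein_id, subject_id, rank,
#                pct_identity, aln_len, bitscore, subject_class)
#   - OG matrix: integer matrix, genomes x orthologous groups
#   - trees: ape "phylo" objects

SUBJECT_CLASSES <- c("ncldv", "bacteriophage", "cellular", "other")
MODEL_DBS <- c("marker", "viral", "cellular")

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased on read. Record ids are the first whitespace
#' token of each header; full headers are kept in the `"descriptions"`
#' attribute (Prodigal-style coordinate headers are parsed from there by
#' [read_bin()]).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector (id -> sequence) with attribute
#'   `descriptions` holding the full header lines.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  meaningful <- which(nzchar(trimws(lines)))
  if (length(meaningful) == 0L) {
    warning("empty FASTA file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  if (!startsWith(trimws(lines[meaningful[1]]), ">")) {
    stop("FASTA parse error at line ", meaningful[1],
         ": sequence data before first header in ", path)
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) stop("duplicate sequence ids in ", path)
  out <- stats::setNames(toupper(as.character(set)), ids)
  attr(out, "descriptions") <- stats::setNames(headers, ids)
  out
}

#' Write sequences to FASTA
#'
#' @param x Named character vector (id -> sequence); uppercased on write so
#'   that write-then-read round-trips exactly.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return The path, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(length(x) > 0, !is.null(names(x)), all(nzchar(names(x))))
  set <- Biostrings::BStringSet(toupper(unname(as.character(x))))
  names(set) <- names(x)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Parse a HMMER3 per-domain table (domtblout dialect)
#'
#' One hit row is emitted per domain line. The domain (not full-sequence)
#' bitscore and the independent e-value are retained, together with the
#' 1-based inclusive coordinates of the domain on the model (`hmm_from`,
#' `hmm_to`) and on the protein (`ali_from`, `ali_to`).
#'
#' @param path Path to a whitespace-delimited domtblout file; `#` lines are
#'   comments.
#' @param model_db One of `"marker"`, `"viral"`, `"cellular"` -- which HMM
#'   collection the search was run against.
#' @return data.frame of hits (possibly 0 rows).
#' @export
parse_domtblout <- function(path, model_db) {
  model_db <- match.arg(model_db, MODEL_DBS)
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  if (length(idx) == 0L) return(empty_hmm_hits(model_db))
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 23L)) {
    bad <- idx[which(nf < 23L)[1]]
    stop("domtblout parse error at line ", bad, ": expected >= 23 fields, got ",
         nf[which(nf < 23L)[1]], " in ", path)
  }
  col <- function(i) vapply(fields, `[`, character(1), i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(col(i)))
    if (anyNA(v)) stop("domtblout parse error in ", path, ": non-numeric ",
                       what, " at line ", idx[which(is.na(v))[1]])
    v
  }
  data.frame(
    protein_id = col(1), model_id = col(4), model_db = model_db,
    bitscore = num(14, "domain score"), evalue = num(13, "i-Evalue"),
    hmm_from = as.integer(num(16, "hmm_from")),
    hmm_to = as.integer(num(17, "hmm_to")),
    ali_from = as.integer(num(18, "ali_from")),
    ali_to = as.integer(num(19, "ali_to")),
    stringsAsFactors = FALSE
  )
}

empty_hmm_hits <- function(model_db = "marker") {
  data.frame(protein_id = character(0), model_id = character(0),
             model_db = character(0), bitscore = numeric(0),
             evalue = numeric(0), hmm_from = integer(0), hmm_to = integer(0),
             ali_from = integer(0), ali_to = integer(0),
             stringsAsFactors = FALSE)
}

#' Read a subject-to-taxon-class map
#'
#' Two-column TSV (`subject_id`, `class`) assigning each homology-search
#' subject (or subject-id prefix) to `ncldv`, `bacteriophage`, `cellular`
#' or `other`.
#'
#' @param path Path to the TSV (no header).
#' @return Named character vector (subject id/prefix -> class).
#' @export
read_class_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("subject_id", "class"))
  bad <- setdiff(unique(df$class), SUBJECT_CLASSES)
  if (length(bad)) stop("unknown subject classes in ", path, ": ",
                        paste(bad, collapse = ", "))
  stats::setNames(df$class, df$subject_id)
}

classify_subjects <- function(subjects, class_map) {
  cls <- unname(class_map[subjects])
  miss <- which(is.na(cls))
  if (length(miss)) {
    keys <- names(class_map)
    for (i in miss) {
      pref <- keys[startsWith(subjects[i], keys)]
      if (length(pref)) cls[i] <- class_map[[pref[which.max(nchar(pref))]]]
    }
    still <- unique(subjects[is.na(cls)])
    if (length(still)) {
      warning("subjects absent from class map, classed 'other': ",
              paste(utils::head(still, 5), collapse = ", "),
              if (length(still) > 5) " ..." else "")
      cls[is.na(cls)] <- "other"
    }
  }
  cls
}

#' Parse a 12-column BLAST-like tabular homology file
#'
#' Standard outfmt-6 columns are assumed (query, subject, percent identity,
#' alignment length, mismatches, gap opens, qstart, qend, sstart, send,
#' e-value, bitscore). Per query, hits are sorted by descending bitscore
#' (ties broken by input order) and assigned ranks 1..k, truncated at
#' `max_rank`; subjects are classed via `class_map`, defaulting to `"other"`
#' with a warning when unmapped.
#'
#' @param path Path to the tabular file.
#' @param class_map Named character vector from [read_class_map()], mapping
#'   subject ids (or prefixes) to taxon classes; `NULL` classes every
#'   subject `"other"` silently (useful for AAI searches where taxon
#'   classes are irrelevant).
#' @param max_rank Number of top hits retained per query (default 5).
#' @return data.frame of homology hits with a `rank` column; bitscore is
#'   non-increasing in rank within every query.
#' @export
parse_tabular_hits <- function(path, class_map = NULL, max_rank = 5L) {
  stopifnot(file.exists(path), max_rank >= 1L)
  lines <- readLines(path, warn = FALSE)
  idx <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(idx) == 0L) return(empty_homology_hits())
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    stop("tabular hit parse error at line ", idx[which(nf < 12L)[1]],
         ": expected 12 fields in ", path)
  }
  col <- function(i) vapply(fields, `[`, character(1), i)
  pident <- suppressWarnings(as.numeric(col(3)))
  if (anyNA(pident)) {
    stop("tabular hit parse error in ", path, ": non-numeric identity at line ",
         idx[which(is.na(pident))[1]])
  }
  df <- data.frame(
    query_protein_id = col(1), subject_id = col(2), pct_identity = pident,
    aln_len = as.integer(suppressWarnings(as.numeric(col(4)))),
    evalue = suppressWarnings(as.numeric(col(11))),
    bitscore = suppressWarnings(as.numeric(col(12))),
    stringsAsFactors = FALSE
  )
  df$.in_order <- seq_len(nrow(df))
  df <- df[order(df$query_protein_id, -df$bitscore, df$.in_order,
                 method = "radix"), ]
  df$rank <- stats::ave(df$.in_order, df$query_protein_id,
                        FUN = seq_along)
  df <- df[df$rank <= max_rank, ]
  df$.in_order <- NULL
  df$subject_class <- if (is.null(class_map)) "other"
                      else classify_subjects(df$subject_id, class_map)
  rownames(df) <- NULL
  df[, c("query_protein_id", "subject_id", "rank", "pct_identity",
         "aln_len", "evalue", "bitscore", "subject_class")]
}

empty_homology_hits <- function() {
  data.frame(query_protein_id = character(0), subject_id = character(0),
             rank = integer(0), pct_identity = numeric(0),
             aln_len = integer(0), evalue = numeric(0), bitscore = numeric(0),
             subject_class = character(0), stringsAsFactors = FALSE)
}

#' Parse a ProteinOrtho-dialect orthologous-group table
#'
#' Expects a header line starting with `#` whose first three columns are
#' species/genes/alg.-conn. and whose remaining columns are genome ids; each
#' subsequent row is one orthologous group, with per-genome cells holding
#' comma-separated gene ids or `*` for absence.
#'
#' @param path Path to the TSV.
#' @return Integer matrix of per-genome gene counts (genomes as rows, OGs as
#'   columns `OG_00001`, ... in file order).
#' @export
parse_og_table <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L || !startsWith(lines[1], "#")) {
    stop("OG table must start with a '#' header line: ", path)
  }
  header <- strsplit(sub("^#\\s*", "", lines[1]), "\t")[[1]]
  if (length(header) < 4L) stop("OG table header has no genome columns: ", path)
  genomes <- header[-(1:3)]
  rows <- strsplit(lines[-1], "\t")
  nf <- lengths(rows)
  if (any(nf != length(header))) {
    stop("ragged OG table row at line ", 1L + which(nf != length(header))[1],
         ": expected ", length(header), " fields in ", path)
  }
  counts <- vapply(rows, function(r) {
    cells <- r[-(1:3)]
    ifelse(cells == "*" | cells == "", 0L,
           lengths(strsplit(cells, ",", fixed = TRUE)))
  }, integer(length(genomes)))
  counts <- matrix(as.integer(counts), nrow = length(genomes),
                   dimnames = list(genomes,
                                   sprintf("OG_%05d", seq_along(rows))))
  counts
}

#' Write an orthologous-group count matrix as a ProteinOrtho-dialect table
#'
#' Gene ids are fabricated as `<genome>_<og>_<j>`; used by the synthetic
#' generator so that [parse_og_table()] round-trips the counts.
#'
#' @param mat Integer matrix, genomes x OGs.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_og_table <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("# Species", "Genes", "Alg.-Conn.", rownames(mat)),
                   collapse = "\t"), con)
  for (j in seq_len(ncol(mat))) {
    cells <- vapply(seq_len(nrow(mat)), function(i) {
      n <- mat[i, j]
      if (n == 0L) "*" else paste0(rownames(mat)[i], "_", colnames(mat)[j],
                                   "_", seq_len(n), collapse = ",")
    }, character(1))
    writeLines(paste(c(sum(mat[, j] > 0), sum(mat[, j]), "1", cells),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a Newick tree
#'
#' Thin wrapper over [ape::read.tree()] with an explicit error for
#' unparseable input.
#'
#' @param path Path to a Newick file.
#' @return An [ape] `phylo` object.
#' @export
read_genome_tree <- function(path) {
  stopifnot(file.exists(path))
  tr <- tryCatch(ape::read.tree(path), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) stop("failed to parse Newick tree (check parentheses): ",
                        path)
  tr
}

#' Write a data.frame as TSV with fixed-precision floats
#'
#' Doubles are printed with 4 decimals; integers and strings untouched.
#'
#' @param df data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tsv <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt_num), stringsAsFactors = FALSE,
                       check.names = FALSE)
  names(out) <- names(df)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a graph as a two-column edge list TSV
#'
#' @param graph An igraph object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  edges <- igraph::as_data_frame(graph, what = "edges")[, 1:2]
  names(edges) <- c("from", "to")
  write_tsv(edges, path)
}

#' Export a graph as GraphML
#'
#' @param graph An igraph object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Construct a genome bin
#'
#' A bin bundles its contigs (with lengths) and the proteins predicted on
#' them. Invariants checked: unique contig ids, protein coordinates within
#' their contig, gene indices unique per contig.
#'
#' @param bin_id Bin/genome identifier.
#' @param contigs data.frame with columns `contig_id`, `length_bp`.
#' @param proteins data.frame with columns `protein_id`, `contig_id`,
#'   `gene_index` (0-based rank along the contig), `start`, `end` (1-based
#'   inclusive bp), `strand` (`+`/`-`), `length_aa`.
#' @return An object of class `gv_bin`.
#' @export
gv_bin <- function(bin_id, contigs, proteins) {
  stopifnot(is.character(bin_id), length(bin_id) == 1L,
            all(c("contig_id", "length_bp") %in% names(contigs)),
            all(c("protein_id", "contig_id", "gene_index", "start", "end",
                  "strand", "length_aa") %in% names(proteins)))
  if (anyDuplicated(contigs$contig_id)) stop("duplicate contig ids in bin ",
                                             bin_id)
  if (nrow(proteins)) {
    if (!all(proteins$contig_id %in% contigs$contig_id)) {
      stop("protein on unknown contig in bin ", bin_id)
    }
    if (any(proteins$end < proteins$start)) stop("protein end < start in ",
                                                 bin_id)
    len <- stats::setNames(contigs$length_bp, contigs$contig_id)
    if (any(proteins$end > len[proteins$contig_id])) {
      stop("protein coordinates exceed contig length in bin ", bin_id)
    }
    dup <- stats::aggregate(gene_index ~ contig_id, proteins,
                            function(g) anyDuplicated(g) > 0)
    if (any(dup$gene_index)) stop("duplicate gene_index within a contig in ",
                                  bin_id)
    proteins <- proteins[order(proteins$contig_id, proteins$start), ]
    rownames(proteins) <- NULL
  }
  structure(list(bin_id = bin_id, contigs = contigs, proteins = proteins),
            class = "gv_bin")
}

#' @export
print.gv_bin <- function(x, ...) {
  cat("<gv_bin>", x$bin_id, "--", nrow(x$contigs), "contigs,",
      nrow(x$proteins), "proteins,", sum(x$contigs$length_bp), "bp\n")
  invisible(x)
}

#' Total length of a bin in bp
#' @param bin A `gv_bin`.
#' @return Integer total contig length.
#' @export
bin_length <- function(bin) sum(bin$contigs$length_bp)

#' Read a bin from contig and protein FASTA files
#'
#' Protein headers are expected in the Prodigal dialect
#' `>id # start # end # strand`, with ids of the form `<contig>_<n>` where
#' `n` is the 1-based gene rank along the contig.
#'
#' @param contig_fasta Path to the contig FASTA.
#' @param protein_fasta Path to the protein FASTA.
#' @param bin_id Bin identifier; defaults to the contig file name.
#' @return A `gv_bin`.
#' @export
read_bin <- function(contig_fasta, protein_fasta,
                     bin_id = sub("\\.[^.]*$", "", basename(contig_fasta))) {
  ctg <- read_fasta(contig_fasta)
  contigs <- data.frame(contig_id = names(ctg), length_bp = nchar(ctg),
                        stringsAsFactors = FALSE, row.names = NULL)
  prot <- read_fasta(protein_fasta)
  if (length(prot) == 0L) {
    return(gv_bin(bin_id, contigs, empty_protein_table()))
  }
  desc <- attr(prot, "descriptions")
  parts <- strsplit(desc, "\\s*#\\s*")
  if (any(lengths(parts) < 4L)) {
    stop("protein header without Prodigal-style coordinates in ",
         protein_fasta)
  }
  ids <- names(prot)
  rank <- suppressWarnings(as.integer(sub(".*_([0-9]+)$", "\\1", ids)))
  if (anyNA(rank)) stop("protein ids must end in _<rank>: ", protein_fasta)
  proteins <- data.frame(
    protein_id = ids,
    contig_id = sub("_[0-9]+$", "", ids),
    gene_index = rank - 1L,
    start = as.integer(vapply(parts, `[`, character(1), 2L)),
    end = as.integer(vapply(parts, `[`, character(1), 3L)),
    strand = ifelse(vapply(parts, `[`, character(1), 4L) %in% c("1", "+"),
                    "+", "-"),
    length_aa = nchar(prot),
    stringsAsFactors = FALSE, row.names = NULL
  )
  gv_bin(bin_id, contigs, proteins)
}

empty_protein_table <- function() {
  data.frame(protein_id = character(0), contig_id = character(0),
             gene_index = integer(0), start = integer(0), end = integer(0),
             strand = character(0), length_aa = integer(0),
             stringsAsFactors = FALSE)
}
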