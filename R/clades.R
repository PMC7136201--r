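# Tree utilities: ultrametric handling, tree cutting, Dunn-index sweeps for
# clade delineation, and monophyly assessment for viral gene clusters.
#
# All trees are ape "phylo" objects. Node height = distance from the node to
# any of its descendant leaves (equal for all on an ultrametric tree);
# cophenetic distance between two leaves is twice the height of their MRCA.

HEIGHT_TOL <- 1e-6

root_node <- function(tree) length(tree$tip.label) + 1L

parent_vec <- function(tree) {
  n_nodes <- length(tree$tip.label) + tree$Nnode
  p <- rep(NA_integer_, n_nodes)
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

children_list <- function(tree) {
  n_nodes <- length(tree$tip.label) + tree$Nnode
  ch <- vector("list", n_nodes)
  for (i in seq_len(nrow(tree$edge))) {
    ch[[tree$edge[i, 1]]] <- c(ch[[tree$edge[i, 1]]], tree$edge[i, 2])
  }
  ch
}

node_depths <- function(tree) ape::node.depth.edgelength(tree)

#' Test a rooted tree for ultrametricity
#'
#' @param tree A rooted `phylo`.
#' @param tol Tolerance on root-to-leaf path-length differences.
#' @return Logical.
#' @export
is_ultrametric_tree <- function(tree, tol = HEIGHT_TOL) {
  depths <- node_depths(tree)[seq_along(tree$tip.label)]
  diff(range(depths)) <= tol
}

#' Stretch terminal branches to make a rooted tree ultrametric
#'
#' Each terminal branch is extended so that every root-to-leaf distance
#' equals the maximum observed; topology and internal branch lengths are
#' unchanged. Already-ultrametric trees are returned as-is (up to numeric
#' noise).
#'
#' @param tree A rooted `phylo` with non-negative branch lengths.
#' @return An ultrametric `phylo`.
#' @export
stretch_ultrametric <- function(tree) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  stopifnot(!is.null(tree$edge.length), all(tree$edge.length >= 0))
  n_tip <- length(tree$tip.label)
  if (n_tip == 1L) return(tree)
  depths <- node_depths(tree)
  target <- max(depths[seq_len(n_tip)])
  tip_edges <- which(tree$edge[, 2] <= n_tip)
  for (e in tip_edges) {
    tip <- tree$edge[e, 2]
    tree$edge.length[e] <- tree$edge.length[e] + (target - depths[tip])
  }
  tree
}

node_heights <- function(tree) {
  depths <- node_depths(tree)
  max(depths[seq_along(tree$tip.label)]) - depths
}

#' Cut an ultrametric tree at a height
#'
#' Clusters are the maximal clades whose root height is at most `h`; every
#' cluster is monophyletic by construction. Cutting at or above the root
#' height returns a single-cluster partition with a warning.
#'
#' @param tree A rooted ultrametric `phylo`.
#' @param h Cut height, `0 <= h`.
#' @return Object of class `clade_partition`: list with `cut_height`,
#'   `clusters` (named integer vector, leaf -> cluster id), `k`.
#' @export
cut_tree <- function(tree, h) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!is_ultrametric_tree(tree)) stop("tree is not ultrametric; see
stretch_ultrametric()")
  stopifnot(h >= 0)
  n_tip <- length(tree$tip.label)
  heights <- node_heights(tree)
  root_h <- heights[root_node(tree)]
  if (h >= root_h - HEIGHT_TOL) {
    warning("cut height ", h, " at or above root height ", signif(root_h, 6),
            "; returning a single cluster")
    clusters <- stats::setNames(rep(1L, n_tip), tree$tip.label)
    return(structure(list(cut_height = h, clusters = clusters, k = 1L),
                     class = "clade_partition"))
  }
  parent <- parent_vec(tree)
  ch <- children_list(tree)
  below <- heights <= h + HEIGHT_TOL
  is_root_cluster <- below & (is.na(parent) | !below[parent])
  roots <- which(is_root_cluster)
  clusters <- stats::setNames(rep(NA_integer_, n_tip), tree$tip.label)
  cid <- 0L
  # assign cluster ids in tip-label order of first member for determinism
  first_tip <- vapply(roots, function(r) {
    stack <- r
    best <- Inf
    while (length(stack)) {
      nd <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (nd <= n_tip) best <- min(best, nd) else stack <- c(stack, ch[[nd]])
    }
    best
  }, numeric(1))
  for (r in roots[order(first_tip)]) {
    cid <- cid + 1L
    stack <- r
    while (length(stack)) {
      nd <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (nd <= n_tip) clusters[nd] <- cid else stack <- c(stack, ch[[nd]])
    }
  }
  stopifnot(!anyNA(clusters))
  structure(list(cut_height = h, clusters = clusters, k = cid),
            class = "clade_partition")
}

#' @export
print.clade_partition <- function(x, ...) {
  cat("<clade_partition> k =", x$k, "at height", signif(x$cut_height, 6),
      "over", length(x$clusters), "leaves\n")
  invisible(x)
}

#' Dunn index of a partition
#'
#' Ratio of the minimum inter-cluster distance (over all cluster pairs, the
#' minimum pairwise distance) to the maximum intra-cluster diameter.
#' Invariant under uniform scaling of the distances. When every cluster is
#' a singleton or all diameters are zero the index is undefined and `NA` is
#' returned.
#'
#' @param partition A `clade_partition` or a named cluster vector.
#' @param d Symmetric distance matrix with dimnames covering the leaves
#'   (e.g. cophenetic distances from [stats::cophenetic()] on the
#'   ultrametric tree).
#' @return Numeric Dunn index, or `NA` when undefined.
#' @export
dunn_index <- function(partition, d) {
  clusters <- if (inherits(partition, "clade_partition")) partition$clusters
              else partition
  leaves <- names(clusters)
  stopifnot(!is.null(leaves), all(leaves %in% rownames(d)))
  k <- length(unique(clusters))
  n <- length(clusters)
  if (k < 2L || k > n - 1L) {
    stop("dunn_index requires 2 <= k <= n-1 clusters (k = ", k, ", n = ",
         n, ")")
  }
  d <- d[leaves, leaves]
  ids <- unique(clusters)
  members <- lapply(ids, function(i) leaves[clusters == i])
  diam <- vapply(members, function(m) {
    if (length(m) < 2L) 0 else max(d[m, m])
  }, numeric(1))
  denom <- max(diam)
  if (denom == 0) {
    return(NA_real_)
  }
  min_inter <- Inf
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in seq((i + 1), length(ids))) {
      min_inter <- min(min_inter, min(d[members[[i]], members[[j]]]))
    }
  }
  min_inter / denom
}

#' Sweep cut heights and select the Dunn-optimal partition
#'
#' Evaluates [dunn_index()] on the partition at every grid height, skipping
#' heights whose partition is degenerate (k < 2, k > n-1, or undefined
#' index), and selects the height optimising the objective; ties are broken
#' toward the smaller height. The conventional direction for compact,
#' well-separated clusters is `"max"`; `"min"` is exposed as an alternative
#' selection rule.
#'
#' @param tree A rooted ultrametric `phylo`.
#' @param grid Either a single integer (number of evenly spaced heights
#'   strictly inside `(0, root height)`; default 100) or a numeric vector
#'   of heights.
#' @param objective `"max"` (default) or `"min"`.
#' @return List with `trace` (data.frame h/k/dunn over valid heights),
#'   `best_height`, `partition` (the selected `clade_partition`, with its
#'   Dunn index in `$dunn`), `objective`.
#' @export
sweep_heights <- function(tree, grid = 100L, objective = c("max", "min")) {
  objective <- match.arg(objective)
  root_h <- node_heights(tree)[root_node(tree)]
  if (length(grid) == 1L && grid == round(grid) && grid > 1) {
    heights <- seq(0, root_h, length.out = as.integer(grid) + 2L)
    heights <- heights[-c(1L, length(heights))]
  } else {
    heights <- sort(as.numeric(grid))
    if (length(heights) < 2L) stop("grid must contain at least 2 heights")
    if (any(heights <= 0 | heights >= root_h)) {
      stop("grid heights must lie strictly inside (0, root height)")
    }
  }
  d <- stats::cophenetic(tree)
  n <- length(tree$tip.label)
  trace <- list()
  for (h in heights) {
    part <- suppressWarnings(cut_tree(tree, h))
    if (part$k < 2L || part$k > n - 1L) next
    dn <- dunn_index(part, d)
    if (is.na(dn)) next
    trace[[length(trace) + 1L]] <- data.frame(h = h, k = part$k, dunn = dn)
  }
  if (length(trace) == 0L) stop("no valid partition on the height grid")
  trace <- do.call(rbind, trace)
  idx <- if (objective == "max") which.max(trace$dunn)
         else which.min(trace$dunn)
  best <- trace$h[idx]
  partition <- suppressWarnings(cut_tree(tree, best))
  partition$dunn <- trace$dunn[idx]
  list(trace = trace, best_height = best, partition = partition,
       objective = objective)
}

#' Maximal all-viral clades in a labeled tree
#'
#' Returns every maximal clade whose leaves are all labeled `"viral"`; a
#' single viral leaf inside a cellular clade forms a size-1 cluster. Used
#' to assess whether viral homologs of metabolic genes form distinct,
#' deep-branching clusters apart from their cellular counterparts.
#'
#' @param tree A rooted `phylo`.
#' @param labels Named character vector leaf -> label (e.g. `viral`,
#'   `cellular`, `phage`, `environmental`); every leaf must be labeled.
#' @return data.frame with `cluster`, `size` and a `members` list-column of
#'   leaf ids.
#' @export
assess_viral_monophyly <- function(tree, labels) {
  n_tip <- length(tree$tip.label)
  missing <- setdiff(tree$tip.label, names(labels))
  if (length(missing)) stop("unlabeled leaves: ",
                            paste(missing, collapse = ", "))
  n_nodes <- n_tip + tree$Nnode
  ch <- children_list(tree)
  parent <- parent_vec(tree)
  all_viral <- rep(TRUE, n_nodes)
  all_viral[seq_len(n_tip)] <- unname(labels[tree$tip.label] == "viral")
  post <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(post))) {
    all_viral[post[e, 1]] <- all_viral[post[e, 1]] && all_viral[post[e, 2]]
  }
  maximal <- which(all_viral &
                     (is.na(parent) | !all_viral[parent]))
  members <- lapply(maximal, function(r) {
    stack <- r
    tips <- integer(0)
    while (length(stack)) {
      nd <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (nd <= n_tip) tips <- c(tips, nd) else stack <- c(stack, ch[[nd]])
    }
    sort(tree$tip.label[tips])
  })
  if (length(members) == 0L) {
    return(data.frame(cluster = integer(0), size = integer(0),
                      members = I(list())))
  }
  ord <- order(-lengths(members), vapply(members, `[`, character(1), 1L))
  members <- members[ord]
  data.frame(cluster = seq_along(members), size = lengths(members),
             members = I(members))
}
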