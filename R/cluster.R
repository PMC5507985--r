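# Hierarchical clustering (Euclidean distance, complete linkage) of samples
# and miRNAs, fixed-k tree cuts, and cluster-vs-annotation summaries.

#' Pairwise Euclidean distances
#'
#' @param m A normalized \code{ExpressionMatrix} without missing values.
#' @param axis \code{"mirnas"} (rows) or \code{"samples"} (columns).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
euclidean_distances <- function(m, axis = c("mirnas", "samples")) {
  axis <- match.arg(axis)
  validate_expression_matrix(m)
  if (m$state != "normalized") fail("euclidean_distances expects a normalized matrix")
  v <- if (axis == "mirnas") m$values else t(m$values)
  if (anyNA(v)) {
    idx <- which(is.na(v), arr.ind = TRUE)
    fail("missing values at (%s)", paste(apply(utils::head(idx, 3), 1, paste,
                                               collapse = ","), collapse = "; "))
  }
  as.matrix(stats::dist(v, method = "euclidean"))
}

#' Complete-linkage agglomerative clustering
#'
#' Standard agglomerative clustering where the distance between two clusters
#' is the maximum pairwise member distance (via \code{stats::hclust},
#' method \code{"complete"}); merge heights are therefore non-decreasing.
#'
#' @param d Symmetric distance matrix (or a \code{dist} object).
#' @return An \code{hclust} object (merge history, heights, leaf order).
#' @export
complete_linkage <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) fail("d must be a square distance matrix")
  if (nrow(d) < 2L) fail("need at least 2 items")
  if (!isSymmetric(unname(d), tol = 1e-8)) fail("distance matrix is not symmetric")
  stats::hclust(stats::as.dist(d), method = "complete")
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the k-1 highest merges and relabels the resulting groups by
#' decreasing size; equally-sized groups are ordered by their
#' lexicographically smallest member ID. Cuts at k and k+1 are nested.
#'
#' @param dend An \code{hclust} object.
#' @param k Number of clusters, between 1 and the number of leaves.
#' @return Named integer vector mapping item ID to cluster label 1..k.
#' @export
cut_tree <- function(dend, k) {
  if (!inherits(dend, "hclust")) fail("dend must be an hclust object")
  n <- length(dend$order)
  if (k < 1 || k > n) fail("k must lie in [1, %d]", n)
  raw <- stats::cutree(dend, k = k)
  relabel_by_size(raw)
}

relabel_by_size <- function(raw) {
  ids <- names(raw) %||% as.character(seq_along(raw))
  sizes <- table(raw)
  first_member <- tapply(ids, raw, function(x) sort(x, method = "radix")[1])
  ord <- order(-as.integer(sizes), first_member, method = "radix")
  new_label <- integer(length(sizes))
  new_label[ord] <- seq_along(ord)
  out <- new_label[match(raw, as.integer(names(sizes)))]
  stats::setNames(as.integer(out), ids)
}

#' Per-cluster miRBase version summary
#'
#' For each cluster: member count and the quartiles of the first miRBase
#' version of its members, plus a global Kruskal-Wallis statistic of version
#' across clusters (descriptive; NA when fewer than two clusters).
#'
#' @param assign Named cluster assignment (as from \code{\link{cut_tree}}).
#' @param annotation Annotation table covering every clustered item.
#' @return List with \code{table} (data.frame: cluster, size, q1, median,
#'   q3) and \code{kruskal} (list with \code{statistic}, \code{p}).
#' @export
cluster_version_summary <- function(assign, annotation) {
  annotation <- validate_mirbase_annotation(annotation)
  idx <- match(names(assign), annotation$mirna_id)
  if (anyNA(idx)) {
    fail("missing annotation for: %s",
         paste(utils::head(names(assign)[is.na(idx)], 5), collapse = ", "))
  }
  ver <- annotation$first_version[idx]
  labs <- sort(unique(assign))
  tab <- do.call(rbind, lapply(labs, function(k) {
    v <- ver[assign == k]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(cluster = k, size = length(v), q1 = q[1], median = q[2], q3 = q[3])
  }))
  kw <- if (length(labs) >= 2L) {
    t <- stats::kruskal.test(ver, factor(assign))
    list(statistic = unname(t$statistic), p = t$p.value)
  } else {
    list(statistic = NA_real_, p = NA_real_)
  }
  list(table = tab, kruskal = kw)
}

#' Export a dendrogram in Newick format
#'
#' @param dend An \code{hclust} object.
#' @param path Optional output file; when NULL the Newick string is returned.
#' @return The Newick string (invisibly when written to a file).
#' @export
dendrogram_newick <- function(dend, path = NULL) {
  phy <- ape::as.phylo(dend)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Members of the smallest subtree containing a set of leaves
#'
#' Walks the merge history to find the smallest dendrogram node whose leaf
#' set contains all requested labels; used to check co-clustering claims
#' (e.g. that all severely degraded samples fall into one subtree).
#'
#' @param dend An \code{hclust} object.
#' @param leaves Character vector of leaf labels.
#' @return Character vector of all leaf labels inside that subtree.
#' @export
minimal_subtree <- function(dend, leaves) {
  if (!inherits(dend, "hclust")) fail("dend must be an hclust object")
  labs <- dend$labels %||% as.character(seq_along(dend$order))
  missing_l <- setdiff(leaves, labs)
  if (length(missing_l)) fail("unknown leaves: %s", paste(missing_l, collapse = ", "))
  if (length(leaves) <= 1L) return(leaves)
  members <- vector("list", nrow(dend$merge))
  node_members <- function(i) if (i < 0) labs[-i] else members[[i]]
  best <- labs
  for (i in seq_len(nrow(dend$merge))) {
    members[[i]] <- c(node_members(dend$merge[i, 1]), node_members(dend$merge[i, 2]))
    if (all(leaves %in% members[[i]]) && length(members[[i]]) < length(best)) {
      best <- members[[i]]
    }
  }
  best
}
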