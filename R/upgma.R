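#' UPGMA clustering of a dissimilarity matrix
#'
#' Agglomerative clustering with unweighted (per-pair) average linkage:
#' at each step the closest pair of clusters merges, and the distance from
#' the merged cluster to any other is the size-weighted mean of its
#' members' distances. Ties in the minimal distance are broken by the
#' lexicographically smallest label pair, so the result is invariant to
#' the input order of the polygons.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal; dimnames
#'   give the leaf labels.
#' @return an object of classes `upgma_tree` and `hclust` (usable with
#'   [stats::cutree()], [stats::cophenetic()], [stats::as.dendrogram()]),
#'   with elements `merge`, `height`, `labels`, `order`, and `gap`, the
#'   per-internal-node gap statistic (node height minus the larger child
#'   height; leaves have height 0).
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need >= 2 leaves")
  if (is.null(rownames(d))) {
    dimnames(d) <- list(as.character(seq_len(n)), as.character(seq_len(n)))
  }
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12,
                        check.attributes = FALSE))) {
    stop("dissimilarity matrix must be symmetric")
  }
  res <- .upgma_cpp(d, rownames(d))
  tree <- structure(
    list(merge = res$merge, height = as.numeric(res$height),
         labels = rownames(d), method = "average",
         call = match.call(), dist.method = "beta_sim"),
    class = c("upgma_tree", "hclust"))
  tree$order <- tree_order(tree$merge)
  tree$gap <- node_gaps(tree)
  tree
}

# leaf ordering compatible with the merge matrix (no crossings)
tree_order <- function(merge) {
  n <- nrow(merge) + 1L
  expand <- function(i) {
    if (i < 0) return(-i)
    c(expand(merge[i, 1]), expand(merge[i, 2]))
  }
  expand(nrow(merge))
}

# gap statistic: node height minus max child height (leaf height = 0)
node_gaps <- function(tree) {
  h <- tree$height
  m <- tree$merge
  child_h <- function(i) if (i < 0) 0 else h[i]
  vapply(seq_along(h), function(k) {
    h[k] - max(child_h(m[k, 1]), child_h(m[k, 2]))
  }, numeric(1))
}

#' Serialize an UPGMA tree to Newick
#'
#' Branch lengths are derived from the ultrametric node heights.
#'
#' @param tree an `upgma_tree`.
#' @param path optional file path; if `NULL` the Newick string is returned.
#' @export
upgma_newick <- function(tree, path = NULL) {
  m <- tree$merge; h <- tree$height; lab <- tree$labels
  bl <- function(i, parent_h) {
    if (i < 0) {
      sprintf("%s:%g", lab[-i], parent_h)
    } else {
      sprintf("(%s,%s):%g", bl(m[i, 1], h[i]), bl(m[i, 2], h[i]),
              parent_h - h[i])
    }
  }
  root <- nrow(m)
  s <- sprintf("(%s,%s);", bl(m[root, 1], h[root]), bl(m[root, 2], h[root]))
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(path)
}
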