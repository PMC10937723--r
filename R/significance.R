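#' Permutation test for UPGMA node significance
#'
#' Tests which dendrogram clusters are non-random. The null model
#' reassigns each species' occurrences to a uniform random polygon subset
#' of the same size, preserving species prevalence while destroying
#' spatial structure. For every permutation the turnover matrix and UPGMA
#' tree are recomputed; internal nodes are ranked by height (deepest node
#' = rank 1) and the observed rank-r statistic is compared with the
#' permuted rank-r statistics via the (1 + k) / (n_perm + 1) estimator.
#'
#' Three node statistics are available:
#' \describe{
#'   \item{`"height"` (default)}{the node's merge height, tested
#'     one-sided *low*: a node is significant when its cluster is more
#'     cohesive (merges at a lower dissimilarity) than rank-matched null
#'     nodes. This matches the idea of finding the dissimilarity level
#'     below which clusters are non-random: a merge of unrelated realms
#'     sits at a height indistinguishable from random merges and is not
#'     flagged, while each realm's root is.}
#'   \item{`"min_child"`}{gap to the shallower child (node height minus
#'     min child height), tested one-sided high; large wherever a compact
#'     subtree attaches far above its own height.}
#'   \item{`"max_child"`}{gap above the taller child, tested one-sided
#'     high; measures the clear height separation of a node from its
#'     larger subcluster.}
#' }
#' The permutation test is exact (type-I error at most nominal) under
#' each variant.
#'
#' @param table an [incidence_table()] (or binary incidence matrix).
#' @param phase `"before"` or `"after"`.
#' @param n_perm number of permutations (paper default 999).
#' @param seed integer seed for the permutation stream.
#' @param statistic `"height"` (default), `"min_child"` or `"max_child"`.
#' @return an `upgma_tree` with extra elements `p_value` (per internal
#'   node, in merge order), `rank` (height rank, deepest = 1),
#'   `statistic` and `n_perm`.
#' @export
node_significance <- function(table, phase = c("before", "after"),
                              n_perm = 999, seed = NULL,
                              statistic = c("height", "min_child",
                                            "max_child")) {
  statistic <- match.arg(statistic)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_perm >= 1)
  mat <- if (inherits(table, "incidence_table")) {
    incidence_matrix(table, match.arg(phase))
  } else {
    table
  }
  storage.mode(mat) <- "double"
  mat <- mat[, colSums(mat) > 0, drop = FALSE]
  n_poly <- ncol(mat)
  prevalence <- rowSums(mat)
  if (any(prevalence > n_poly)) {
    stop("degenerate null: species more prevalent than the polygon count")
  }
  beta <- beta_sim_matrix(mat)
  tree <- upgma(beta)
  n_nodes <- length(tree$height)
  obs_rank <- rank(-tree$height, ties.method = "first")
  obs_stat <- node_statistic(tree$merge, tree$height, statistic)

  exceed <- integer(n_nodes)
  for (b in seq_len(n_perm)) {
    g <- ranked_null_stats(n_poly, prevalence, n_nodes, statistic)
    exceed <- exceed + if (statistic == "height") {
      g[obs_rank] <= obs_stat          # cohesion: significantly low
    } else {
      g[obs_rank] >= obs_stat          # gap: significantly high
    }
  }
  tree$p_value <- (1 + exceed) / (n_perm + 1)
  tree$rank <- obs_rank
  tree$statistic <- statistic
  tree$n_perm <- n_perm
  tree
}

node_statistic <- function(m, h, statistic) {
  if (statistic == "height") return(h)
  child_h <- matrix(ifelse(m < 0, 0, h[pmax(m, 1)]), nrow(m), 2)
  if (statistic == "min_child") {
    h - pmin(child_h[, 1], child_h[, 2])
  } else {
    h - pmax(child_h[, 1], child_h[, 2])
  }
}

# one prevalence-preserving shuffle; returns node statistics sorted by
# height rank. When empty polygons reduce the node count the missing
# ranks are padded neutrally (height 1 for the cohesion statistic, gap 0
# otherwise).
ranked_null_stats <- function(n_poly, prevalence, n_nodes, statistic) {
  perm <- matrix(0, length(prevalence), n_poly)
  for (s in seq_along(prevalence)) {
    perm[s, sample.int(n_poly, prevalence[s])] <- 1
  }
  keep <- colSums(perm) > 0
  pb <- suppressWarnings(beta_sim_matrix(perm[, keep, drop = FALSE]))
  res <- .upgma_cpp(pb, as.character(seq_len(ncol(pb))))
  h <- as.numeric(res$height)
  stats <- node_statistic(res$merge, h, statistic)
  out <- rep(if (statistic == "height") 1 else 0, n_nodes)
  byrank <- stats[order(-h)]
  take <- seq_len(min(n_nodes, length(byrank)))
  out[take] <- byrank[take]
  out
}

#' Cut a significance-tested tree into biogeographic realms
#'
#' With the default cohesion statistic (`"height"`), realms are the
#' maximal subtrees whose root node is significantly more cohesive than
#' random: starting from the tree root, non-significant merges (which
#' join unrelated realms at dissimilarities indistinguishable from
#' random) are descended through, and each maximal significant node
#' becomes a realm; leaves left between realms become singleton realms.
#' The reported cut height is the level below which every retained
#' cluster is non-random.
#'
#' With the gap statistics, the tree is cut at the lowest height such
#' that every internal node at or above the cut is significant, and the
#' realms are the resulting subtrees.
#'
#' Under either rule, if no node is significant a single realm is
#' returned.
#'
#' @param tree output of [node_significance()].
#' @param alpha significance level (default 0.05).
#' @return a `realm_assignment`: list with `realm` (named integer vector,
#'   polygon -> realm), `k`, `cut_height`, `alpha`, and the `tree`.
#' @export
cut_significant <- function(tree, alpha = 0.05) {
  if (is.null(tree$p_value)) stop("tree carries no p-values")
  n <- length(tree$labels)
  one_realm <- function() {
    structure(list(realm = stats::setNames(rep(1L, n), tree$labels),
                   k = 1L, cut_height = max(tree$height), alpha = alpha,
                   tree = tree),
              class = "realm_assignment")
  }
  if (!any(tree$p_value < alpha)) return(one_realm())

  if (identical(tree$statistic, "height")) {
    m <- tree$merge
    sig <- tree$p_value < alpha
    realm <- integer(n)
    names(realm) <- tree$labels
    next_id <- 0L
    leaves_of <- function(i) {
      if (i < 0) return(-i)
      c(leaves_of(m[i, 1]), leaves_of(m[i, 2]))
    }
    roots_h <- numeric(0)
    assign_realms <- function(i) {
      if (i < 0 || sig[i]) {
        next_id <<- next_id + 1L
        realm[leaves_of(i)] <<- next_id
        if (i > 0) roots_h <<- c(roots_h, tree$height[i])
      } else {
        assign_realms(m[i, 1])
        assign_realms(m[i, 2])
      }
    }
    assign_realms(nrow(m))
    cut_height <- if (length(roots_h)) max(roots_h) else max(tree$height)
  } else {
    ord <- order(tree$rank)            # deepest node first
    p_sorted <- tree$p_value[ord]
    run <- match(FALSE, p_sorted < alpha, nomatch = length(p_sorted) + 1) - 1
    realm <- stats::cutree(tree, k = run + 1L)
    cut_height <- tree$height[ord][run]
    next_id <- run + 1L
  }
  structure(list(realm = realm, k = as.integer(next_id),
                 cut_height = cut_height, alpha = alpha, tree = tree),
            class = "realm_assignment")
}

#' @export
print.realm_assignment <- function(x, ...) {
  cat("realm_assignment:", x$k, "realm(s) over", length(x$realm),
      "polygons; cut height", format(x$cut_height, digits = 4), "\n")
  print(table(x$realm))
  invisible(x)
}

#' Write a realm assignment to CSV
#'
#' @param x a `realm_assignment`.
#' @param path output CSV path.
#' @export
write_realms <- function(x, path) {
  df <- data.frame(polygon_id = names(x$realm), realm = unname(x$realm),
                   k = x$k, cut_height = x$cut_height)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement: 1 for identical partitions, about 0 for
#' independent ones. Only elements named in both assignments are compared.
#'
#' @param a,b named vectors of cluster labels (or `realm_assignment`s).
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (inherits(a, "realm_assignment")) a <- a$realm
  if (inherits(b, "realm_assignment")) b <- b$realm
  if (is.null(names(a)) || is.null(names(b))) {
    stopifnot(length(a) == length(b))
  } else {
    common <- intersect(names(a), names(b))
    if (!length(common)) stop("no common elements between assignments")
    a <- a[common]; b <- b[common]
  }
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  # both partitions all-singletons: identical by construction
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
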