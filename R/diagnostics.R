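#' Cluster-number diagnostics for a dendrogram
#'
#' Three classical criteria for choosing the number of clusters, computed
#' on the dissimilarity matrix for each candidate k: the elbow curve
#' (total within-cluster mean dissimilarity), the mean silhouette width,
#' and a Kelley-Gardner-Sutcliffe-style penalty (mean within-cluster
#' spread min-max rescaled to \[1, n-1\] plus k; minimize).
#'
#' @param d symmetric dissimilarity matrix.
#' @param tree an `upgma_tree` (or any `hclust`) over the same labels.
#' @param k_range integer vector of cluster counts, within \[2, n-1\].
#' @return list with `table` (data.frame: k, within, silhouette, kgs) and
#'   `best` (list: elbow (max curvature), silhouette (max), kgs (min)).
#' @export
cluster_diagnostics <- function(d, tree, k_range = 2:10) {
  n <- nrow(d)
  k_range <- as.integer(k_range)
  if (!length(k_range)) stop("empty k_range")
  if (any(k_range < 2 | k_range > n - 1)) stop("k_range outside [2, n-1]")
  within <- sil <- spread <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    cl <- stats::cutree(tree, k = k_range[i])
    within[i] <- total_within(d, cl)
    sil[i] <- mean_silhouette(d, cl)
    spread[i] <- mean_within_spread(d, cl)
  }
  if (length(k_range) > 1 && diff(range(spread)) > 0) {
    kgs <- 1 + (spread - min(spread)) / diff(range(spread)) * (n - 2) + k_range
  } else {
    kgs <- 1 + k_range
  }
  tab <- data.frame(k = k_range, within = within, silhouette = sil, kgs = kgs)
  curv <- if (length(k_range) >= 3) {
    c(NA, diff(diff(within)), NA)
  } else {
    rep(NA_real_, length(k_range))
  }
  best <- list(
    elbow = if (all(is.na(curv))) k_range[1] else k_range[which.max(curv)],
    silhouette = k_range[which.max(sil)],
    kgs = k_range[which.min(kgs)])
  list(table = tab, best = best)
}

total_within <- function(d, cl) {
  s <- 0
  for (g in unique(cl)) {
    idx <- which(cl == g)
    if (length(idx) > 1) {
      sub <- d[idx, idx]
      s <- s + mean(sub[upper.tri(sub)])
    }
  }
  s
}

mean_within_spread <- function(d, cl) {
  v <- numeric(0)
  for (g in unique(cl)) {
    idx <- which(cl == g)
    if (length(idx) > 1) {
      sub <- d[idx, idx]
      v <- c(v, mean(sub[upper.tri(sub)]))
    }
  }
  if (length(v)) mean(v) else 0
}

# silhouette width from a raw dissimilarity matrix (singletons score 0)
mean_silhouette <- function(d, cl) {
  n <- nrow(d)
  groups <- unique(cl)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(groups, cl[i]), function(g) {
      mean(d[i, cl == g])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Sensitivity of realm delineation to species-pool size
#'
#' Repeatedly subsamples the species pool, reruns the full realm
#' delineation (turnover matrix, permutation-tested UPGMA, significance
#' cut), and scores agreement with the full-data realms by adjusted Rand
#' index.
#'
#' @param table an [incidence_table()].
#' @param sizes species-pool sizes to test.
#' @param reps replicates per size.
#' @param n_perm permutations for the node test.
#' @param phase `"before"` or `"after"`.
#' @param alpha significance level of the cut.
#' @param seed integer seed.
#' @return list with `summary` (data.frame: size, mean_ari, sd_ari) and
#'   `ari` (replicate-level data.frame).
#' @export
subset_sensitivity <- function(table, sizes = c(300, 400, 500, 1000, 2000,
                                                5000, 10000),
                               reps = 10, n_perm = 99,
                               phase = "before", alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(reps >= 1)
  pool <- table$species_ids
  if (any(sizes > length(pool))) stop("size exceeds the species pool")
  full <- cut_significant(
    node_significance(table, phase, n_perm = n_perm), alpha = alpha)
  rows <- list()
  for (size in sizes) {
    for (r in seq_len(reps)) {
      sp <- sample(pool, size)
      occ <- table$occurrences
      sub <- occ[occ$species_id %in% sp, , drop = FALSE]
      subtab <- incidence_table(sub$species_id, sub$polygon_id, sub$status)
      asn <- cut_significant(
        node_significance(subtab, phase, n_perm = n_perm), alpha = alpha)
      rows[[length(rows) + 1]] <- data.frame(
        size = size, rep = r, k = asn$k,
        ari = adjusted_rand_index(full, asn))
    }
  }
  ari <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(ari, ari$size), function(g) {
    data.frame(size = g$size[1], mean_ari = mean(g$ari), sd_ari = stats::sd(g$ari))
  }))
  rownames(summary) <- NULL
  list(summary = summary, ari = ari, full = full)
}
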