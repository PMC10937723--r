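#' Mantel test between two distance/dissimilarity matrices
#'
#' Pearson correlation of the off-diagonal upper-triangle entries, with
#' significance from simultaneous row/column permutations of the first
#' matrix. The permutation p-value uses the (1 + k) / (1 + n_perm)
#' estimator, so p is never exactly zero.
#'
#' @param m1,m2 symmetric matrices with identical dimnames (labels are
#'   checked when present).
#' @param n_perm number of permutations (ignored when `exhaustive`).
#' @param alternative `"greater"` (default, the classical one-sided
#'   distance-decay alternative), `"less"`, or `"two.sided"`.
#' @param seed integer seed.
#' @param exhaustive enumerate all n! label permutations (identity
#'   included) instead of sampling; only allowed for n <= 8. The p-value
#'   is then the exact fraction of permutations at least as extreme.
#' @return list of class `mantel_result`: `r`, `p_value`, `n_perm`,
#'   `alternative`, `seed`.
#' @export
mantel_test <- function(m1, m2, n_perm = 999,
                        alternative = c("greater", "less", "two.sided"),
                        seed = NULL, exhaustive = FALSE) {
  alternative <- match.arg(alternative)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2))) {
    stop("matrix labels differ")
  }
  stopifnot(nrow(m1) == nrow(m2))
  ut <- upper.tri(m1)
  y <- m2[ut]
  r_obs <- stats::cor(m1[ut], y)
  n <- nrow(m1)
  meets <- function(r_perm) switch(alternative,
    greater = r_perm >= r_obs,
    less = r_perm <= r_obs,
    two.sided = abs(r_perm) >= abs(r_obs))
  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration limited to n <= 8")
    perms <- all_permutations(n)
    hits <- vapply(perms, function(idx) {
      meets(stats::cor(m1[idx, idx][ut], y))
    }, logical(1))
    return(structure(list(r = r_obs, p_value = mean(hits),
                          n_perm = length(perms), alternative = alternative,
                          seed = seed),
                     class = "mantel_result"))
  }
  exceed <- 0
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    exceed <- exceed + meets(stats::cor(m1[idx, idx][ut], y))
  }
  structure(list(r = r_obs, p_value = (1 + exceed) / (1 + n_perm),
                 n_perm = n_perm, alternative = alternative, seed = seed),
            class = "mantel_result")
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1)
  out <- vector("list", n * length(sub))
  k <- 0
  for (p in sub) {
    for (pos in 0:(n - 1)) {
      k <- k + 1
      out[[k]] <- append(p, n, after = pos)
    }
  }
  out
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.4f, p = %.4g (%s, %d permutations)\n",
              x$r, x$p_value, x$alternative, x$n_perm))
  invisible(x)
}
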