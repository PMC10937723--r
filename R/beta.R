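#' Simpson turnover dissimilarity between two assemblages
#'
#' beta_sim = 1 - a / (min(b, c) + a), where a is the number of shared
#' species and b, c the numbers of species unique to each assemblage. It
#' isolates species replacement from richness difference: 0 for identical
#' or nested assemblages, 1 for disjoint ones.
#'
#' @param A,B character vectors (species sets), both non-empty.
#' @return value in \[0, 1\].
#' @export
beta_sim_pair <- function(A, B) {
  A <- unique(A); B <- unique(B)
  if (!length(A) || !length(B)) {
    stop("beta_sim undefined for an empty assemblage")
  }
  a <- length(intersect(A, B))
  b <- length(A) - a
  c <- length(B) - a
  1 - a / (min(b, c) + a)
}

#' Pairwise Simpson turnover matrix
#'
#' Computes beta_sim between all pairs of polygons with a non-empty
#' assemblage in the chosen phase. Empty polygons (none in the view) are
#' excluded; all set arithmetic is exact integer work before the single
#' division.
#'
#' @param x an [incidence_table()] or a binary species-by-polygon matrix.
#' @param phase `"before"` (native occurrences only) or `"after"` (all).
#' @return symmetric numeric matrix in \[0, 1\] with zero diagonal,
#'   polygon ids as dimnames.
#' @export
beta_sim_matrix <- function(x, phase = c("before", "after")) {
  mat <- if (inherits(x, "incidence_table")) {
    incidence_matrix(x, match.arg(phase))
  } else {
    x
  }
  storage.mode(mat) <- "double"
  rich <- colSums(mat)
  empty <- rich == 0
  if (any(empty)) {
    warning("excluding ", sum(empty), " empty polygon(s) from beta_sim")
    mat <- mat[, !empty, drop = FALSE]
    rich <- rich[!empty]
  }
  n <- ncol(mat)
  if (n < 2) stop("need >= 2 polygons with non-empty assemblages")
  a <- crossprod(mat)                       # shared species counts
  b <- matrix(rich, n, n) - a               # unique to row polygon
  cc <- t(b)                                # unique to column polygon
  beta <- 1 - a / (pmin(b, cc) + a)
  diag(beta) <- 0
  beta
}

#' Convert between dissimilarity and similarity
#'
#' @param beta a beta_sim matrix.
#' @return `1 - beta` with unit diagonal.
#' @export
similarity_matrix <- function(beta) {
  s <- 1 - beta
  diag(s) <- 1
  s
}
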