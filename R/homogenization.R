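#' Homogenization index matrix from before/after turnover matrices
#'
#' h_ij = beta_after(i,j) - beta_before(i,j). A negative value means the
#' pair of assemblages became compositionally more similar after
#' human-mediated dispersal (biotic homogenization); a positive value
#' means differentiation. Proportions are computed over unordered
#' off-diagonal pairs; exact zeros count as "unchanged".
#'
#' @param before,after symmetric beta_sim matrices; the label intersection
#'   is used (dropped labels trigger a warning).
#' @return a `homogenization_result`: list with `h` (matrix), `h_bar`
#'   (per-polygon mean, see [mean_homogenization()]), `n_pairs`,
#'   `prop_homogenized`, `prop_differentiated`, `prop_unchanged`.
#' @export
homogenization_matrix <- function(before, after) {
  common <- intersect(rownames(before), rownames(after))
  if (!length(common)) stop("empty label intersection")
  dropped <- length(union(rownames(before), rownames(after))) - length(common)
  if (dropped > 0) {
    warning("dropping ", dropped, " polygon(s) absent from one matrix")
  }
  h <- after[common, common] - before[common, common]
  diag(h) <- 0
  up <- h[upper.tri(h)]
  structure(list(
    h = h,
    h_bar = mean_homogenization(h),
    n_pairs = length(up),
    prop_homogenized = mean(up < 0),
    prop_differentiated = mean(up > 0),
    prop_unchanged = mean(up == 0)),
    class = "homogenization_result")
}

#' @export
print.homogenization_result <- function(x, ...) {
  cat("homogenization_result over", nrow(x$h), "polygons:",
      sprintf("%.1f%% homogenized, %.1f%% differentiated, %.1f%% unchanged\n",
              100 * x$prop_homogenized, 100 * x$prop_differentiated,
              100 * x$prop_unchanged))
  invisible(x)
}

#' Per-polygon mean homogenization
#'
#' h_bar_i = sum_j h_ij / N, where N is the number of polygons of the
#' geographic focus; the zero self-pair is included in the sum, and the
#' divisor is N (not N - 1), following the index definition. Set
#' `drop_self = TRUE` to divide by N - 1 instead.
#'
#' @param h an h matrix or a `homogenization_result`.
#' @param focus_n divisor N; defaults to the polygon count of `h`.
#' @param drop_self divide by N - 1 instead of N.
#' @return named numeric vector.
#' @export
mean_homogenization <- function(h, focus_n = NULL, drop_self = FALSE) {
  if (inherits(h, "homogenization_result")) h <- h$h
  n <- if (is.null(focus_n)) nrow(h) else focus_n
  if (n == 0) stop("focus_n must be positive")
  rowSums(h) / (if (drop_self) n - 1 else n)
}

#' Stratified summaries of homogenization
#'
#' Summarizes per-polygon mean homogenization and per-stratum homogenized
#' pair shares for the four island-by-tropical strata and the two marginal
#' splits.
#'
#' @param result a `homogenization_result`.
#' @param meta a `polygon_metadata` data.frame covering all polygons of
#'   the result.
#' @return list with `strata` (data.frame: stratum, n, mean_h_bar,
#'   sd_h_bar, prop_homogenized_pairs) and `polygons` (per-polygon
#'   data.frame with h_bar and flags).
#' @export
stratify_homogenization <- function(result, meta) {
  ids <- rownames(result$h)
  check_metadata_covers(meta, ids)
  m <- meta[match(ids, meta$polygon_id), ]
  poly <- data.frame(polygon_id = ids, h_bar = unname(result$h_bar),
                     is_island = m$is_island, is_tropical = m$is_tropical,
                     region = m$region, stringsAsFactors = FALSE)
  strata <- list(
    island = poly$is_island,
    mainland = !poly$is_island,
    tropical = poly$is_tropical,
    nontropical = !poly$is_tropical,
    tropical_island = poly$is_island & poly$is_tropical,
    tropical_mainland = !poly$is_island & poly$is_tropical,
    nontropical_island = poly$is_island & !poly$is_tropical,
    nontropical_mainland = !poly$is_island & !poly$is_tropical)
  rows <- lapply(names(strata), function(s) {
    sel <- strata[[s]]
    data.frame(stratum = s, n = sum(sel),
               mean_h_bar = if (any(sel)) mean(poly$h_bar[sel]) else NA_real_,
               sd_h_bar = if (sum(sel) > 1) stats::sd(poly$h_bar[sel]) else NA_real_,
               prop_homogenized_pairs = stratum_pair_prop(result$h, sel))
  })
  list(strata = do.call(rbind, rows), polygons = poly)
}

# share of homogenized pairs among unordered pairs within a stratum
stratum_pair_prop <- function(h, sel) {
  if (sum(sel) < 2) return(NA_real_)
  sub <- h[sel, sel]
  up <- sub[upper.tri(sub)]
  mean(up < 0)
}

#' Write per-polygon homogenization table to CSV
#'
#' @param strat output of [stratify_homogenization()].
#' @param path output CSV path.
#' @export
write_homogenization <- function(strat, path) {
  utils::write.csv(strat$polygons, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
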