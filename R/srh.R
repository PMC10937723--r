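#' Scheirer-Ray-Hare test (nonparametric two-way ANOVA)
#'
#' Ranks the pooled response (mid-ranks for ties) and performs a two-way
#' ANOVA decomposition on the ranks with Type-II sums of squares. Each
#' term's statistic H = SS_term / MS_total, where MS_total is the total
#' rank variance (n(n+1)/12 when there are no ties), is referred to a
#' chi-square distribution with the term's degrees of freedom.
#'
#' A factor with a single level contributes nothing; with factor B
#' constant the A statistic reduces exactly to Kruskal-Wallis.
#'
#' @param response numeric response vector.
#' @param factor_a,factor_b grouping factors (coerced with `factor()`).
#' @return data.frame of class `srh_result` with one row per term
#'   (`A`, `B`, `A:B`): `H`, `df`, `p_value`; attribute `ms_total`.
#' @export
scheirer_ray_hare <- function(response, factor_a, factor_b) {
  a <- factor(factor_a)
  b <- factor(factor_b)
  n <- length(response)
  stopifnot(length(a) == n, length(b) == n)
  if (nlevels(a) < 2 && nlevels(b) < 2) {
    stop("at least one factor must have >= 2 levels")
  }
  if (nlevels(a) >= 2 && nlevels(b) >= 2 &&
      any(table(a, b) == 0)) {
    stop("empty cell(s) in the two-way design")
  }
  r <- rank(response)
  ms_total <- sum((r - mean(r))^2) / (n - 1)

  rss <- function(...) {
    terms <- list(...)
    terms <- Filter(function(f) nlevels(f) >= 2, terms)
    if (!length(terms)) return(sum((r - mean(r))^2))
    mm <- stats::model.matrix(~., data = as.data.frame(terms))
    sum(stats::lm.fit(mm, r)$residuals^2)
  }
  ab <- if (nlevels(a) >= 2 && nlevels(b) >= 2) interaction(a, b, drop = TRUE)
        else factor(rep(1, n))
  ss_a <- rss(b) - rss(a, b)
  ss_b <- rss(a) - rss(a, b)
  ss_ab <- rss(a, b) - rss(ab)     # saturated cell-means model
  df_a <- max(nlevels(a) - 1, 0)
  df_b <- max(nlevels(b) - 1, 0)
  df_ab <- df_a * df_b
  h <- c(ss_a, ss_b, ss_ab) / ms_total
  df <- c(df_a, df_b, df_ab)
  p <- ifelse(df > 0, stats::pchisq(h, df, lower.tail = FALSE), NA_real_)
  out <- data.frame(term = c("A", "B", "A:B"), H = h, df = df, p_value = p,
                    stringsAsFactors = FALSE)
  attr(out, "ms_total") <- ms_total
  class(out) <- c("srh_result", "data.frame")
  out
}

#' Pairwise unpaired Wilcoxon rank-sum tests with multiplicity correction
#'
#' Two-sided rank-sum test for each pair of groups; p-values are adjusted
#' for the number of comparisons (Bonferroni by default, capped at 1).
#'
#' @param values numeric response vector.
#' @param groups grouping vector.
#' @param correction a method of [stats::p.adjust()] (default
#'   `"bonferroni"`).
#' @return data.frame with columns `group1`, `group2`, `p_raw`, `p_adj`.
#' @export
pairwise_wilcoxon <- function(values, groups, correction = "bonferroni") {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need >= 2 groups")
  if (any(table(g) == 0)) stop("group with zero members")
  pairs <- utils::combn(levels(g), 2)
  p_raw <- apply(pairs, 2, function(pr) {
    suppressWarnings(stats::wilcox.test(values[g == pr[1]],
                                        values[g == pr[2]],
                                        alternative = "two.sided")$p.value)
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], p_raw = p_raw,
             p_adj = stats::p.adjust(p_raw, method = correction),
             stringsAsFactors = FALSE)
}
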