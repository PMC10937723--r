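#' Distance-decay fit of compositional similarity
#'
#' Least-squares fit of similarity against geographic distance over all
#' unordered polygon pairs. The default model is the negative exponential
#' s(d) = a * exp(-b * d); a power law s(d) = a * d^(-b) is available as
#' an alternative. Starting values: a0 is the mean similarity within the
#' shortest-distance decile, b0 the (negated) slope of a log-linear
#' regression on the positive similarities.
#'
#' The decay rate per 1000 km is reported both as the fractional
#' similarity loss 1 - exp(-1000 b) and as the raw slope b * 1000.
#'
#' @param similarity symmetric similarity matrix (1 - beta_sim).
#' @param distance symmetric distance matrix in km, same labels.
#' @param form `"exponential"` or `"power"`.
#' @return list of class `decay_fit`: `a`, `b`, `r_squared`,
#'   `decay_rate_per_1000km`, `raw_rate_per_1000km`, `form`, `converged`.
#' @export
fit_distance_decay <- function(similarity, distance,
                               form = c("exponential", "power")) {
  form <- match.arg(form)
  if (!is.null(rownames(similarity)) && !is.null(rownames(distance)) &&
      !identical(rownames(similarity), rownames(distance))) {
    stop("matrix labels differ")
  }
  ut <- upper.tri(similarity)
  y <- similarity[ut]
  x <- distance[ut]
  if (length(unique(x)) < 3) stop("need >= 3 distinct distances")
  if (all(y == 0)) stop("all similarities are zero")
  pos <- y > 0
  if (form == "power") pos <- pos & x > 0
  a0 <- mean(y[x <= stats::quantile(x, 0.1)])
  if (!is.finite(a0) || a0 <= 0) a0 <- max(mean(y), 1e-3)
  xfit <- if (form == "exponential") x[pos] else log(x[pos])
  b0 <- -stats::coef(stats::lm(log(y[pos]) ~ xfit))[[2]]
  df <- data.frame(x = x, y = y)
  rhs <- if (form == "exponential") y ~ a * exp(-b * x) else y ~ a * x^(-b)
  # "port" handles zero-residual (noiseless) data that the default
  # Gauss-Newton algorithm stops short on
  fit <- tryCatch(
    stats::nls(rhs, data = df, start = list(a = a0, b = b0),
               algorithm = "port",
               control = stats::nls.control(maxiter = 500, tol = 1e-12)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    ab <- stats::coef(fit)
    converged <- isTRUE(fit$convInfo$isConv)
    resid <- stats::resid(fit)
  } else {
    # degenerate surfaces (e.g. exactly flat data): direct minimization
    obj <- function(p) {
      pred <- if (form == "exponential") p[1] * exp(-p[2] * x)
              else p[1] * x^(-p[2])
      sum((y - pred)^2)
    }
    opt <- stats::optim(c(a0, b0), obj, method = "Nelder-Mead")
    ab <- c(a = opt$par[1], b = opt$par[2])
    converged <- opt$convergence == 0
    pred <- if (form == "exponential") ab[1] * exp(-ab[2] * x)
            else ab[1] * x^(-ab[2])
    resid <- y - pred
  }
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  b <- unname(ab["b"])
  structure(list(a = unname(ab["a"]), b = b,
                 r_squared = 1 - ss_res / ss_tot,
                 decay_rate_per_1000km =
                   if (form == "exponential") 1 - exp(-1000 * b) else NA_real_,
                 raw_rate_per_1000km = 1000 * b,
                 form = form, converged = converged,
                 n_pairs = length(y)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("decay_fit (%s): a = %.4g, b = %.4g, R2 = %.3f, rate/1000km = %.3f\n",
              x$form, x$a, x$b, x$r_squared, x$decay_rate_per_1000km))
  invisible(x)
}
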