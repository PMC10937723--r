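#' Count GLMM with a regional random intercept
#'
#' Log-link mixed model for per-polygon counts of donated or received
#' non-native species, with tropical and island status as fixed effects
#' (optionally their interaction) and a random intercept per
#' subcontinental region to absorb geographic non-independence.
#' Both families use the Laplace approximation by default so their AICs
#' are comparable (lme4 drops constant deviance terms under nAGQ > 1,
#' which would corrupt the Poisson-versus-negative-binomial comparison);
#' set `nagq` above 1 for adaptive Gauss-Hermite quadrature on the
#' Poisson fit when only its coefficients matter.
#'
#' @param counts non-negative integer response, one per polygon.
#' @param tropical,island logical covariates.
#' @param region region labels (>= 2 regions).
#' @param family `"negbin"` or `"poisson"`.
#' @param interaction include the tropical-by-island interaction.
#' @param nagq quadrature points for the Poisson fit.
#' @return list of class `glmm_fit`: `family`, `coefficients`
#'   (data.frame: estimate, se, z, p_value), `theta` (negbin dispersion,
#'   `NA` for Poisson), `re_variance`, `loglik`, `aic`, `converged`,
#'   `model` (the underlying `merMod`).
#' @export
fit_count_glmm <- function(counts, tropical, island, region,
                           family = c("negbin", "poisson"),
                           interaction = FALSE, nagq = 1) {
  family <- match.arg(family)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  region <- factor(region)
  if (nlevels(region) < 2) stop("need >= 2 regions")
  df <- data.frame(count = as.integer(counts),
                   tropical = as.logical(tropical),
                   island = as.logical(island), region = region)
  fe <- if (interaction) "tropical * island" else "tropical + island"
  form <- stats::as.formula(paste("count ~", fe, "+ (1 | region)"))
  if (family == "poisson") {
    fit <- tryCatch(
      lme4::glmer(form, data = df, family = stats::poisson, nAGQ = nagq),
      error = function(e) lme4::glmer(form, data = df,
                                      family = stats::poisson))
    theta <- NA_real_
  } else {
    fit <- suppressWarnings(lme4::glmer.nb(form, data = df))
    theta <- lme4::getME(fit, "glmer.nb.theta")
  }
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      z = sm[, 3], p_value = sm[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  vc <- lme4::VarCorr(fit)
  messages <- fit@optinfo$conv$lme4$messages
  structure(list(family = family, coefficients = coefs, theta = theta,
                 re_variance = as.numeric(vc$region[1]),
                 loglik = as.numeric(stats::logLik(fit)),
                 aic = stats::AIC(fit),
                 converged = is.null(messages), model = fit),
            class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("glmm_fit (%s): AIC = %.1f, RE variance = %.3g%s\n",
              x$family, x$aic, x$re_variance,
              if (!x$converged) " [convergence warning]" else ""))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Model selection for the count GLMM
#'
#' Fits Poisson and negative-binomial families, with and without the
#' tropical-by-island interaction, and ranks them by AIC.
#'
#' @inheritParams fit_count_glmm
#' @return list with `table` (data.frame: family, interaction, aic,
#'   converged) and `best` (the winning `glmm_fit`).
#' @export
select_count_glmm <- function(counts, tropical, island, region) {
  grid <- expand.grid(family = c("poisson", "negbin"),
                      interaction = c(FALSE, TRUE),
                      stringsAsFactors = FALSE)
  fits <- lapply(seq_len(nrow(grid)), function(i) {
    tryCatch(fit_count_glmm(counts, tropical, island, region,
                            family = grid$family[i],
                            interaction = grid$interaction[i]),
             error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  tab <- data.frame(family = grid$family[ok],
                    interaction = grid$interaction[ok],
                    aic = vapply(fits[ok], `[[`, numeric(1), "aic"),
                    converged = vapply(fits[ok], `[[`, logical(1), "converged"))
  list(table = tab[order(tab$aic), ], best = fits[ok][[which.min(tab$aic)]])
}
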