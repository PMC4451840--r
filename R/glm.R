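#' Fit a univariate grouped-binomial grounding-rate model
#'
#' Maximum-likelihood logistic regression of per-colony recovery counts: the
#' response is the two-column matrix (recovered, not recovered) with
#' binomial error and logit link, fitted by iteratively reweighted least
#' squares to convergence tolerance 1e-12. Candidate covariates are the
#' physical and light-pollution colony variables; `"none"` fits the
#' intercept-only (null) model.
#'
#' AICc uses `-2 * logLik + 2k + 2k(k+1)/(n - k - 1)` with `k` counting the
#' intercept plus slope (dispersion fixed at 1) and `n` the number of
#' colonies, not birds.
#'
#' @param colonies data frame with `n_recovered`, `n_banded` and the
#'   covariate columns.
#' @param covariate one of `"distance_to_sea_m"`, `"elevation_m"`,
#'   `"radiance_mean_3km"`, `"radiance_max_3km"`, `"radiance_at_colony"`,
#'   `"none"`.
#' @return list of class `glm_fit` with `covariate`, `coefficients`, `se`,
#'   `ci95` (Wald), `log_likelihood`, `residual_deviance`, `null_deviance`,
#'   `k`, `n`, `aic`, `aicc`, `deviance_explained_pct`, and the underlying
#'   `glm` object as `fit`.
#' @export
fit_binomial_logit <- function(colonies,
                               covariate = c("distance_to_sea_m",
                                             "elevation_m",
                                             "radiance_mean_3km",
                                             "radiance_max_3km",
                                             "radiance_at_colony",
                                             "none")) {
  covariate <- match.arg(covariate)
  n <- nrow(colonies)
  if (n < 3) stop("need at least 3 colonies")
  if (any(colonies$n_banded < colonies$n_recovered))
    stop("n_recovered exceeds n_banded")
  resp <- cbind(colonies$n_recovered, colonies$n_banded - colonies$n_recovered)
  if (covariate == "none") {
    fml <- resp ~ 1
    k <- 1L
  } else {
    x <- colonies[[covariate]]
    if (is.null(x) || any(!is.finite(x)))
      stop("covariate ", covariate, " is missing or non-finite")
    fml <- resp ~ x
    k <- 2L
  }
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial("logit"),
                                     control = stats::glm.control(
                                       epsilon = 1e-12, maxit = 100)))
  ## separation drives fitted logits without bound (|eta| ~ 25 is already
  ## a probability within 1e-11 of 0 or 1)
  if (!fit$converged || max(abs(stats::predict(fit))) > 25)
    stop("complete separation or non-convergence fitting covariate ",
         covariate)
  ll <- as.numeric(stats::logLik(fit))
  if (n - k - 1 <= 0)
    stop("AICc undefined: n - k - 1 <= 0 (n = ", n, ", k = ", k, ")")
  aic <- -2 * ll + 2 * k
  aicc <- aic + 2 * k * (k + 1) / (n - k - 1)
  sm <- summary(fit)
  est <- sm$coefficients[, "Estimate"]
  se <- sm$coefficients[, "Std. Error"]
  names(est) <- names(se) <- if (k == 2L) c("(Intercept)", covariate) else
    "(Intercept)"
  structure(list(
    covariate = covariate, coefficients = est, se = se,
    ci95 = cbind(lower = est - 1.96 * se, upper = est + 1.96 * se),
    log_likelihood = ll,
    residual_deviance = fit$deviance, null_deviance = fit$null.deviance,
    k = k, n = n, aic = aic, aicc = aicc,
    deviance_explained_pct =
      100 * (fit$null.deviance - fit$deviance) / fit$null.deviance,
    fit = fit), class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("Grouped-binomial logit fit [%s]: n = %d colonies\n",
              x$covariate, x$n))
  print(round(cbind(estimate = x$coefficients, se = x$se, x$ci95), 5))
  cat(sprintf("  AICc = %.2f, %% deviance explained = %.1f\n",
              x$aicc, x$deviance_explained_pct))
  invisible(x)
}

#' Rank candidate grounding-rate models by AICc
#'
#' Orders a set of [fit_binomial_logit()] fits by AICc (lower is better) and
#' tabulates estimate, SE, Wald 95% CI, AICc, delta AICc relative to the
#' best model, and percent deviance explained.
#'
#' @param fits list of `glm_fit` objects fitted on the same colony set.
#' @return data frame ordered by `aicc`.
#' @export
rank_models <- function(fits) {
  if (inherits(fits, "glm_fit")) fits <- list(fits)
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1L)
    stop("all fits must use the same colony set (mixed n)")
  rows <- lapply(fits, function(f) {
    slope <- if (f$k == 2L) f$coefficients[2] else NA_real_
    se <- if (f$k == 2L) f$se[2] else NA_real_
    data.frame(covariate = f$covariate, estimate = slope, se = se,
               ci_lower = if (f$k == 2L) f$ci95[2, 1] else NA_real_,
               ci_upper = if (f$k == 2L) f$ci95[2, 2] else NA_real_,
               aicc = f$aicc,
               deviance_explained_pct = f$deviance_explained_pct)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$aicc), ]
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  rownames(tab) <- NULL
  tab[, c("covariate", "estimate", "se", "ci_lower", "ci_upper", "aicc",
          "delta_aicc", "deviance_explained_pct")]
}

#' Variance inflation factors of colony covariates
#'
#' Collinearity diagnostic: `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes
#' from the ordinary least-squares regression of covariate `j` on the other
#' covariates. Perfectly collinear covariates are flagged with `Inf`.
#'
#' @param colonies data frame holding the covariate columns.
#' @param covariates character vector of column names (>= 2).
#' @return named numeric vector of VIFs.
#' @export
vif_table <- function(colonies, covariates) {
  if (length(covariates) < 2) stop("need at least two covariates")
  X <- as.matrix(colonies[, covariates, drop = FALSE])
  if (nrow(X) < length(covariates) + 2)
    stop("need at least covariates + 2 rows")
  out <- vapply(seq_along(covariates), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- covariates
  out
}
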