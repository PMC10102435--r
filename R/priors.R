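#' Global shrinkage scale for the horseshoe prior
#'
#' Scales the horseshoe's global parameter from the expected number of
#' nonzero coefficients: with D predictors and n samples,
#' `tau0 = (p0 / (D - p0)) * (1 / sqrt(n))`, where `p0` is the least
#' integer value of `p0_frac` of the number of predictors (floor, with a
#' minimum of 1). A ceiling reading is available by passing `p0` directly.
#'
#' @param D Number of predictors (>= 2).
#' @param n Number of samples (>= 1).
#' @param p0_frac Expected nonzero fraction of predictors (default 0.1).
#' @param p0 Optional explicit expected nonzero count, overriding `p0_frac`.
#'
#' @return A list with elements `p0` and `tau0`.
#' @export
compute_tau0 <- function(D, n, p0_frac = 0.1, p0 = NULL) {
  stopifnot(D >= 2, n >= 1, p0_frac > 0, p0_frac < 1)
  if (is.null(p0)) p0 <- max(1L, floor(p0_frac * D))
  if (p0 >= D) stop("p0 must be smaller than the number of predictors D")
  list(p0 = as.integer(p0), tau0 = (p0 / (D - p0)) / sqrt(n))
}

#' Shrinkage prior specification for the per-variant regression
#'
#' Three prior families on the regression coefficients of variant dosage on
#' the phenome: the horseshoe (half-Cauchy local scales lambda_j with a
#' global scale tau set from [compute_tau0()]), a ridge prior (normal with
#' zero mean and variance `ridge_variance`, default 5), and a Bayesian
#' lasso (Laplace coefficient priors whose tuning parameter lambda^2
#' carries a chi-squared prior with `lasso_chisq_df` degrees of freedom,
#' default 1, hence expected value one). The residual sd carries a
#' weakly-informative half-t(3, 0, sd(y)) prior in all families.
#'
#' @param family `"horseshoe"` (default), `"ridge"`, or `"lasso"`.
#' @param p0_frac Expected nonzero fraction for tau0 scaling (default 0.1).
#' @param p0 Optional explicit expected-nonzero count.
#' @param tau0 Optional explicit global scale; computed from D and n at fit
#'   time when `NULL`.
#' @param tau_hyperprior If `TRUE` (default), the global scale gets a
#'   half-Cauchy(0, tau0) hyperprior, matching how probabilistic-programming
#'   horseshoe implementations treat the user-supplied global scale; with
#'   `FALSE` tau is fixed at tau0 exactly.
#' @param ridge_variance Ridge prior variance (default 5).
#' @param lasso_chisq_df Degrees of freedom of the chi-squared prior on the
#'   lasso tuning parameter (default 1).
#'
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(family = c("horseshoe", "ridge", "lasso"),
                       p0_frac = 0.1, p0 = NULL, tau0 = NULL,
                       tau_hyperprior = TRUE,
                       ridge_variance = 5, lasso_chisq_df = 1) {
  family <- match.arg(family)
  stopifnot(ridge_variance > 0, lasso_chisq_df >= 1,
            is.null(tau0) || tau0 > 0)
  structure(list(family = family, p0_frac = p0_frac, p0 = p0, tau0 = tau0,
                 tau_hyperprior = tau_hyperprior,
                 ridge_variance = ridge_variance,
                 lasso_chisq_df = lasso_chisq_df,
                 sigma_prior = "half-t(3, 0, sd(y))"),
            class = "prior_spec")
}

#' MCMC sampler configuration
#'
#' @param chains Number of chains (default 4).
#' @param iter Iterations per chain including warmup (default 2000).
#' @param warmup Warmup iterations discarded per chain (default `iter / 2`).
#' @param seed Integer RNG seed; identical seed and configuration give
#'   bit-identical draws.
#'
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(chains = 4, iter = 2000, warmup = floor(iter / 2),
                           seed = 1) {
  stopifnot(chains >= 1, iter >= 2, warmup >= 1, warmup < iter)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed)),
            class = "sampler_config")
}
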