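#' Fit the per-variant Bayesian reverse regression
#'
#' Regresses a variant's alternate-allele dosage on the full predictor
#' matrix (standardized traits plus structure covariates) under the chosen
#' shrinkage prior, by auxiliary-variable Gibbs sampling. The response is
#' left on its 0..2 dosage scale and modeled with a Gaussian likelihood;
#' the horseshoe's global scale defaults to tau0 from [compute_tau0()].
#'
#' @param y Numeric response vector (variant dosage), length n.
#' @param X n x D predictor matrix with unique column names and no missing
#'   entries.
#' @param prior A [prior_spec()].
#' @param sampler A [sampler_config()].
#'
#' @return An object of class `posterior_draws`: `beta` (S x D matrix of
#'   post-warmup draws pooled over chains), `sigma` (length S),
#'   `diagnostics` (per-coefficient split R-hat and effective sample size;
#'   any R-hat >= 1.05 raises a warning, never a silent pass), and
#'   `sampler_meta` (chains, iterations, warmup, seed, prior family, tau0,
#'   p0).
#' @export
fit_variant <- function(y, X, prior = prior_spec(), sampler = sampler_config()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y); D <- ncol(X)
  if (nrow(X) != n) stop("y and X are non-conformable: length(y) = ", n,
                         ", nrow(X) = ", nrow(X))
  if (anyNA(X) || any(!is.finite(X))) stop("X contains missing or non-finite entries")
  if (anyNA(y)) stop("y contains missing values")
  if (stats::var(y) == 0) stop("constant response: variant is monomorphic in this sample")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(D))
  if (anyDuplicated(colnames(X))) stop("predictor names must be unique")

  sc <- compute_tau0(D, n, p0_frac = prior$p0_frac, p0 = prior$p0)
  tau0 <- if (is.null(prior$tau0)) sc$tau0 else prior$tau0

  set.seed(sampler$seed)
  chains <- lapply(seq_len(sampler$chains), function(ch)
    gibbs_chain(y, X, prior, sampler$iter, sampler$warmup, tau0))

  beta <- do.call(rbind, lapply(chains, `[[`, "beta"))
  colnames(beta) <- colnames(X)
  sigma <- unlist(lapply(chains, `[[`, "sigma"))

  keep <- sampler$iter - sampler$warmup
  rhat <- vapply(seq_len(D), function(j)
    split_rhat(vapply(chains, function(c) c$beta[, j], numeric(keep))),
    numeric(1))
  ess <- vapply(seq_len(D), function(j)
    ess_basic(vapply(chains, function(c) c$beta[, j], numeric(keep))),
    numeric(1))
  diagnostics <- data.frame(predictor = colnames(X), rhat = rhat, ess = ess)
  if (any(rhat >= 1.05, na.rm = TRUE))
    warning(sprintf("convergence warning: %d coefficient(s) with split R-hat >= 1.05 (max %.3f)",
                    sum(rhat >= 1.05, na.rm = TRUE), max(rhat, na.rm = TRUE)))

  structure(list(
    beta = beta, sigma = sigma, diagnostics = diagnostics,
    sampler_meta = list(chains = sampler$chains, iter = sampler$iter,
                        warmup = sampler$warmup, seed = sampler$seed,
                        family = prior$family, tau0 = tau0, p0 = sc$p0)
  ), class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("posterior_draws: %d draws x %d coefficients (%s prior, %d chains, max R-hat %.3f)\n",
              nrow(x$beta), ncol(x$beta), x$sampler_meta$family,
              x$sampler_meta$chains, max(x$diagnostics$rhat)))
  invisible(x)
}

hpdi_interval <- function(draws, level) {
  s <- sort(draws)
  S <- length(s)
  k <- max(2L, floor(level * S))
  idx <- seq_len(S - k + 1)
  widths <- s[idx + k - 1] - s[idx]
  i <- which.min(widths)
  c(s[i], s[i + k - 1])
}

#' Call significant predictors from posterior draws
#'
#' A predictor is flagged significant when its 95% (by default) central
#' quantile posterior interval excludes zero. The highest-posterior-density
#' interval is available as an alternative via `method = "hpdi"`.
#'
#' @param draws A `posterior_draws` from [fit_variant()].
#' @param level Interval mass (default 0.95).
#' @param method `"quantile"` (central interval, default) or `"hpdi"`.
#' @param variant_id Optional variant identifier carried into the result.
#'
#' @return An object of class `association_result`: a data frame with one
#'   row per predictor (`predictor`, `post_mean`, `post_median`, `lower`,
#'   `upper`, `significant`, `rhat`, `ess`), with the prior family, level
#'   and sampler metadata in attributes.
#' @export
call_significant <- function(draws, level = 0.95, method = c("quantile", "hpdi"),
                             variant_id = NA_character_) {
  method <- match.arg(method)
  S <- nrow(draws$beta)
  if (S < 100) stop("too few draws for a stable interval: ", S, " < 100")
  alpha <- (1 - level) / 2
  if (method == "quantile") {
    qs <- apply(draws$beta, 2, stats::quantile, probs = c(alpha, 1 - alpha))
    lower <- qs[1, ]; upper <- qs[2, ]
  } else {
    iv <- apply(draws$beta, 2, hpdi_interval, level = level)
    lower <- iv[1, ]; upper <- iv[2, ]
  }
  res <- data.frame(
    predictor = colnames(draws$beta),
    post_mean = colMeans(draws$beta),
    post_median = apply(draws$beta, 2, stats::median),
    lower = unname(lower),
    upper = unname(upper),
    significant = unname(lower > 0 | upper < 0),
    rhat = draws$diagnostics$rhat,
    ess = draws$diagnostics$ess,
    row.names = NULL
  )
  structure(res, class = c("association_result", "data.frame"),
            variant_id = variant_id, level = level, method = method,
            sampler_meta = draws$sampler_meta)
}

#' Build the predictor matrix for one chromosome
#'
#' Column-binds the (complete, standardized) trait matrix with the LOCO
#' principal-component scores for the focal chromosome, checking accession
#' alignment.
#'
#' @param traits A complete `trait_matrix` (no missing entries).
#' @param pcs A `loco_pc_set` (or `NULL` to use traits only).
#' @param chrom Chromosome whose LOCO scores to use.
#' @return Numeric matrix n x D with named columns.
#' @export
build_design <- function(traits, pcs = NULL, chrom = NULL) {
  tm <- as_trait_matrix(traits)
  if (!all(tm$mask)) stop("phenome contains missing values; run mpmm_impute first")
  X <- tm$values
  if (!is.null(pcs)) {
    if (is.null(chrom)) stop("chrom is required when LOCO PCs are supplied")
    if (!chrom %in% names(pcs$scores))
      stop("no LOCO PCs available for chromosome ", chrom)
    sc <- pcs$scores[[chrom]]
    if (!is.null(rownames(sc)) &&
        !identical(unname(rownames(sc)), unname(tm$accession_ids)))
      stop("accession order of LOCO PCs does not match the phenome")
    X <- cbind(X, sc)
  }
  X
}

#' Run the reverse regression over every variant of a gene
#'
#' Fits each variant independently (no multi-response model): the response
#' is the variant's dosage and the predictors are the imputed standardized
#' traits plus the LOCO principal components of the variant's chromosome.
#' Each fit uses the same sampler seed, so identical variants yield
#' identical results.
#'
#' @param vs A `variant_set`; all variants must share one chromosome.
#' @param traits A complete `trait_matrix` aligned to the same accessions.
#' @param pcs A `loco_pc_set` (or `NULL`).
#' @param prior A [prior_spec()].
#' @param sampler A [sampler_config()].
#' @param level Interval mass for significance calling (default 0.95).
#' @param method Interval type, `"quantile"` or `"hpdi"`.
#'
#' @return A list of `association_result`, one per variant in input order;
#'   combine with [association_table()].
#' @export
run_gene <- function(vs, traits, pcs = NULL, prior = prior_spec(),
                     sampler = sampler_config(), level = 0.95,
                     method = "quantile") {
  tm <- as_trait_matrix(traits)
  if (length(vs) == 0L) return(list())
  chroms <- unique(vs$meta$chrom)
  if (length(chroms) != 1L)
    stop("variants span multiple chromosomes: ", paste(chroms, collapse = ", "))
  if (!setequal(vs$accession_ids, tm$accession_ids)) {
    miss <- setdiff(vs$accession_ids, tm$accession_ids)
    extra <- setdiff(tm$accession_ids, vs$accession_ids)
    stop("accession mismatch between variants and phenome; in VCF only: {",
         paste(miss, collapse = ","), "}; in phenome only: {",
         paste(extra, collapse = ","), "}")
  }
  ord <- match(tm$accession_ids, vs$accession_ids)
  X <- build_design(tm, pcs, chroms)
  lapply(seq_len(length(vs)), function(i) {
    y <- vs$dosage[i, ord]
    draws <- fit_variant(y, X, prior = prior, sampler = sampler)
    call_significant(draws, level = level, method = method,
                     variant_id = vs$meta$id[i])
  })
}

#' Flatten association results into one table
#'
#' @param results List of `association_result` (from [run_gene()]).
#' @param vs Optional `variant_set` supplying chrom/pos/ref/alt columns.
#' @return Data frame with one row per variant x predictor.
#' @export
association_table <- function(results, vs = NULL) {
  if (length(results) == 0L)
    return(data.frame(variant_id = character(0), predictor = character(0)))
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    out <- data.frame(variant_id = attr(r, "variant_id"), as.data.frame(r),
                      check.names = FALSE)
    if (!is.null(vs)) {
      out$chrom <- vs$meta$chrom[i]; out$pos <- vs$meta$pos[i]
      out$ref <- vs$meta$ref[i]; out$alt <- vs$meta$alt[i]
      out <- out[, c("variant_id", "chrom", "pos", "ref", "alt",
                     setdiff(names(out), c("variant_id", "chrom", "pos", "ref", "alt")))]
    }
    out
  })
  do.call(rbind, rows)
}
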