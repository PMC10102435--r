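#' Specification for the multi-phenotype mixed-model imputation fit
#'
#' The imputation model decomposes a standardized N x p trait matrix as
#' Y = U + eps with U = S beta, where S ~ MN(0, K, I_r) carries the
#' kinship-structured genetic signal, beta ~ MN(0, I_r, tau^-1 I_p) mixes the
#' r latent columns into traits, eps has i.i.d. rows N(0, E), and the
#' residual precision E^-1 carries a Wishart(p + 5, (1/4) I_p) prior.
#'
#' @param rank Number of latent columns r; `NULL` (default) means full rank
#'   min(N, p).
#' @param tau Regularization parameter on beta (prior column precision
#'   scale); default 1.
#' @param max_iter Maximum coordinate-ascent sweeps (default 1000).
#' @param tol Relative objective-change convergence tolerance (default 1e-6).
#'
#' @return A list of class `mpmm_spec`.
#' @export
mpmm_spec <- function(rank = NULL, tau = 1, max_iter = 1000, tol = 1e-6) {
  stopifnot(is.null(rank) || rank >= 1, tau > 0, max_iter >= 1, tol > 0)
  structure(list(rank = rank, tau = tau, max_iter = max_iter, tol = tol),
            class = "mpmm_spec")
}

#' Impute missing phenotypes with a kinship-aware matrix-normal model
#'
#' Fits the low-rank multi-phenotype mixed model (see [mpmm_spec()]) by
#' block coordinate ascent on the joint log posterior over the latent
#' factors S, the mixing matrix beta, the residual covariance E and the
#' missing entries of Y. Each block update is an exact conditional
#' maximizer (two Sylvester systems solved in eigenbases, a closed-form
#' Wishart-mode update for E, and per-row Gaussian conditional means for
#' the missing entries), so the objective trace is non-decreasing by
#' construction. Missing entries are filled with their model-conditional
#' means; observed entries are never altered.
#'
#' @param Y A standardized `trait_matrix` (see [standardize_traits()]); may
#'   also be a plain numeric matrix with `NA` for missing.
#' @param K N x N kinship matrix aligned with the rows of `Y` (symmetric,
#'   positive semidefinite). See [compute_kinship()].
#' @param spec An [mpmm_spec()].
#'
#' @return An object of class `mpmm_fit` with fields `imputed` (N x p, NA
#'   entries replaced), `S` (N x r), `beta` (r x p), `E` (p x p residual
#'   covariance), `B` (p x p implied genetic covariance, crossprod(beta)),
#'   `objective_trace`, `converged`, `iterations`.
#' @export
mpmm_impute <- function(Y, K, spec = mpmm_spec()) {
  tm <- as_trait_matrix(Y)
  Yv <- tm$values
  mask <- tm$mask
  N <- nrow(Yv); p <- ncol(Yv)
  K <- as.matrix(K)
  if (nrow(K) != N || ncol(K) != N)
    stop(sprintf("dimension mismatch: Y has %d accessions but K is %dx%d",
                 N, nrow(K), ncol(K)))
  if (!is.null(rownames(K)) &&
      !identical(unname(rownames(K)), unname(tm$accession_ids)))
    stop("accession order of K does not match Y")
  if (max(abs(K - t(K))) > 1e-8) stop("K is not symmetric")

  ek <- eigen((K + t(K)) / 2, symmetric = TRUE)
  dmax <- max(ek$values, 0)
  if (min(ek$values) < -1e-8 * max(dmax, 1))
    stop(sprintf("K is not positive semidefinite: most negative eigenvalue %g",
                 min(ek$values)))
  # floor eigenvalues: tiny ridge keeps K invertible (GRMs are singular)
  d <- pmax(ek$values, 1e-8 * max(dmax, 1))
  Q <- ek$vectors

  r <- if (is.null(spec$rank)) min(N, p) else min(spec$rank, N, p)
  tau <- spec$tau
  nu0 <- p + 5                      # Wishart degrees of freedom
  denomE <- N + (nu0 - p - 1)       # = N + 4; Wishart-mode denominator

  Yc <- Yv
  Yc[!mask] <- 0
  any_missing <- !all(mask)
  miss_rows <- which(rowSums(!mask) > 0L)

  # warm start from a truncated SVD of the zero-filled matrix
  sv <- svd(Yc, nu = r, nv = r)
  S <- sv$u %*% diag(sv$d[seq_len(r)], r, r)
  beta <- t(sv$v)

  obj <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  iters <- 0L

  for (it in seq_len(spec$max_iter)) {
    iters <- it
    # E block: Wishart-mode closed form
    Res <- Yc - S %*% beta
    E <- (crossprod(Res) + diag(4, p)) / denomE
    cE <- chol(E)
    W <- chol2inv(cE)                 # E^{-1}

    # missing-entry block: per-row Gaussian conditional mean
    if (any_missing) {
      Mu <- S %*% beta
      for (i in miss_rows) {
        m <- which(!mask[i, ])
        o <- which(mask[i, ])
        if (length(o) == 0L) {
          Yc[i, m] <- Mu[i, m]
        } else {
          Yc[i, m] <- Mu[i, m] -
            solve(W[m, m, drop = FALSE],
                  W[m, o, drop = FALSE] %*% (Yv[i, o] - Mu[i, o]))
        }
      }
    }

    # S block: K^{-1} S + S (beta W beta') = Yc W beta'
    G <- beta %*% W %*% t(beta)
    eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
    lam <- pmax(eg$values, 0)
    Ct <- crossprod(Q, Yc %*% W %*% t(beta)) %*% eg$vectors
    St <- Ct / outer(1 / d, lam, "+")
    S <- Q %*% St %*% t(eg$vectors)

    # beta block: (S'S) beta + tau beta E = S' Yc
    M <- crossprod(S)
    em <- eigen((M + t(M)) / 2, symmetric = TRUE)
    ee <- eigen(E, symmetric = TRUE)
    C2 <- crossprod(em$vectors, crossprod(S, Yc)) %*% ee$vectors
    Bt <- C2 / outer(pmax(em$values, 0), tau * pmax(ee$values, 1e-12), "+")
    beta <- em$vectors %*% Bt %*% t(ee$vectors)

    # joint log posterior (additive constants dropped)
    Res <- Yc - S %*% beta
    E <- (crossprod(Res) + diag(4, p)) / denomE   # keep E at its conditional max
    cE <- chol(E)
    W <- chol2inv(cE)
    logdetE <- 2 * sum(log(diag(cE)))
    St <- crossprod(Q, S)
    L <- -(N / 2) * logdetE - 0.5 * sum(W * crossprod(Res)) -
      (r / 2) * sum(log(d)) - 0.5 * sum((St^2) / d) +
      (r * p / 2) * log(tau) - (tau / 2) * sum(beta^2) +
      ((nu0 - p - 1) / 2) * (-logdetE) - 0.5 * 4 * sum(diag(W))
    obj <- c(obj, L)
    if (is.finite(prev) && abs(L - prev) / (abs(prev) + 1) < spec$tol) {
      converged <- TRUE
      break
    }
    prev <- L
  }

  imputed <- Yv
  imputed[!mask] <- Yc[!mask]

  structure(list(
    imputed = imputed,
    S = S,
    beta = beta,
    E = E,
    B = crossprod(beta),
    objective_trace = obj,
    converged = converged,
    iterations = iters,
    rank = r,
    tau = tau
  ), class = "mpmm_fit")
}

#' @export
print.mpmm_fit <- function(x, ...) {
  cat(sprintf("mpmm_fit: %d x %d, rank %d, %d sweeps (%s), objective %.4f\n",
              nrow(x$imputed), ncol(x$imputed), x$rank, x$iterations,
              if (x$converged) "converged" else "max_iter reached",
              utils::tail(x$objective_trace, 1)))
  invisible(x)
}

#' Imputed trait matrix from an MPMM fit
#'
#' @param fit An `mpmm_fit`.
#' @param Y The `trait_matrix` that was imputed (supplies identifiers and
#'   the standardization record).
#' @return A complete `trait_matrix` whose mask is all-observed.
#' @export
imputed_traits <- function(fit, Y) {
  tm <- as_trait_matrix(Y)
  trait_matrix(fit$imputed, tm$accession_ids, tm$trait_names,
               standardization = tm$standardization)
}
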