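# Auxiliary-variable Gibbs samplers for shrinkage-prior linear regression.
#
# All three families share the Gaussian likelihood y = X beta + eps,
# eps ~ N(0, sigma^2 I), and a half-t(3, 0, sd(y)) prior on sigma expressed
# through the inverse-gamma mixture sigma^2 | a ~ IG(nu/2, nu/a),
# a ~ IG(1/2, 1/s^2), which keeps every conditional conjugate.
#
# horseshoe: beta_j | lambda_j, tau ~ N(0, lambda_j^2 tau^2),
#            lambda_j ~ C+(0,1) via the inverse-gamma mixture
#            lambda_j^2 | nu_j ~ IG(1/2, 1/nu_j), nu_j ~ IG(1/2, 1).
#            tau is fixed at tau0, or (option) tau ~ C+(0, tau0).
# ridge:     beta_j ~ N(0, ridge_variance).
# lasso:     beta_j | t_j^2 ~ N(0, t_j^2), t_j^2 ~ Exp(lambda^2/2),
#            lambda^2 ~ chi-squared(df) (df = 1 => expected value one).

rinvgamma1 <- function(n, shape, rate) 1 / stats::rgamma(n, shape = shape, rate = rate)

# Michael-Schucany-Haas inverse-Gaussian sampler
rinvgauss <- function(n, mu, lambda) {
  mu <- pmin(mu, 1e8)
  y <- stats::rnorm(n)^2
  x <- mu + mu^2 * y / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * y + mu^2 * y^2)
  x <- pmax(x, 1e-12)
  z <- stats::runif(n)
  out <- ifelse(z <= mu / (mu + x), x, mu^2 / x)
  pmax(out, 1e-12)
}

# draw beta | prior precision, sigma^2 from its Gaussian conditional
draw_beta <- function(XtX, Xty, prior_prec, sig2) {
  A <- XtX / sig2
  diag(A) <- diag(A) + prior_prec
  U <- chol(A)
  mu <- backsolve(U, backsolve(U, Xty / sig2, transpose = TRUE))
  drop(mu + backsolve(U, stats::rnorm(length(mu))))
}

# One chain of the Gibbs sampler; returns post-warmup draws.
gibbs_chain <- function(y, X, prior, n_iter, warmup, tau0) {
  n <- length(y); D <- ncol(X)
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  s_y <- stats::sd(y)
  nu_t <- 3                          # residual half-t df

  sig2 <- stats::var(y) * stats::runif(1, 0.5, 2)
  a_aux <- s_y^2
  keep <- n_iter - warmup
  beta_out <- matrix(NA_real_, keep, D)
  sigma_out <- numeric(keep)

  if (prior$family == "horseshoe") {
    lam2 <- rep(1, D); nu_loc <- rep(1, D)
    tau2 <- tau0^2; xi <- 1
  } else if (prior$family == "lasso") {
    t2 <- rep(1, D)
    lam2 <- prior$lasso_chisq_df      # start at prior mean
  }

  for (it in seq_len(n_iter)) {
    prior_prec <- switch(prior$family,
      horseshoe = 1 / (lam2 * tau2),
      ridge = rep(1 / prior$ridge_variance, D),
      lasso = 1 / t2)
    beta <- draw_beta(XtX, Xty, prior_prec, sig2)

    rss <- sum((y - drop(X %*% beta))^2)
    sig2 <- rinvgamma1(1, (n + nu_t) / 2, nu_t / a_aux + rss / 2)
    a_aux <- rinvgamma1(1, (nu_t + 1) / 2, nu_t / sig2 + 1 / s_y^2)

    if (prior$family == "horseshoe") {
      lam2 <- rinvgamma1(D, 1, 1 / nu_loc + beta^2 / (2 * tau2))
      nu_loc <- rinvgamma1(D, 1, 1 + 1 / lam2)
      if (prior$tau_hyperprior) {
        tau2 <- rinvgamma1(1, (D + 1) / 2, 1 / xi + sum(beta^2 / lam2) / 2)
        xi <- rinvgamma1(1, 1, 1 / tau0^2 + 1 / tau2)
      }
    } else if (prior$family == "lasso") {
      invt2 <- rinvgauss(D, sqrt(lam2) / pmax(abs(beta), 1e-10), lam2)
      t2 <- 1 / invt2
      df <- prior$lasso_chisq_df
      lam2 <- stats::rgamma(1, shape = df / 2 + D, rate = 1 / 2 + sum(t2) / 2)
    }

    if (it > warmup) {
      beta_out[it - warmup, ] <- beta
      sigma_out[it - warmup] <- sqrt(sig2)
    }
  }
  list(beta = beta_out, sigma = sigma_out)
}

# split-chain potential scale reduction factor
split_rhat <- function(chains_mat) {
  # chains_mat: draws x chains for one parameter
  m <- ncol(chains_mat); s <- nrow(chains_mat)
  half <- floor(s / 2)
  seqs <- do.call(cbind, lapply(seq_len(m), function(j)
    cbind(chains_mat[seq_len(half), j],
          chains_mat[(s - half + 1):s, j])))
  mu_j <- colMeans(seqs)
  var_j <- apply(seqs, 2, stats::var)
  W <- mean(var_j)
  B <- half * stats::var(mu_j)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# effective sample size via Geyer's initial positive sequence
ess_basic <- function(chains_mat) {
  m <- ncol(chains_mat); s <- nrow(chains_mat)
  centered <- sweep(chains_mat, 2, colMeans(chains_mat))
  v <- mean(apply(chains_mat, 2, stats::var))
  if (v <= 0) return(m * s)
  max_lag <- min(s - 1, 200)
  rho <- numeric(max_lag)
  for (k in seq_len(max_lag)) {
    num <- mean(vapply(seq_len(m), function(j)
      mean(centered[seq_len(s - k), j] * centered[(k + 1):s, j]), numeric(1)))
    rho[k] <- num / v
    if (rho[k] < 0) { rho <- rho[seq_len(k - 1)] ; break }
    if (k == max_lag) rho <- rho[seq_len(max_lag)]
  }
  ess <- m * s / (1 + 2 * sum(rho))
  min(ess, m * s)
}
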