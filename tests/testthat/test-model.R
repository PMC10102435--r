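# Reverse-regression model: tau0 scaling, samplers, significance calling.

test_that("global shrinkage scale follows the p0/(D-p0)/sqrt(n) rule", {
  expect_equal(compute_tau0(10, 1)$tau0, 1 / 9)
  expect_identical(compute_tau0(10, 1)$p0, 1L)
  expect_equal(compute_tau0(20, 100)$tau0, (2 / 18) / 10)
  sc <- compute_tau0(127, 390)
  expect_identical(sc$p0, 12L)
  expect_equal(sc$tau0, (12 / 115) / sqrt(390), tolerance = 1e-12)
  expect_error(compute_tau0(10, 5, p0 = 10), "smaller")
})

test_that("a noiseless single-predictor signal is recovered unshrunk", {
  set.seed(101)
  X <- matrix(rnorm(100 * 5), 100, 5, dimnames = list(NULL, paste0("t", 1:5)))
  y <- X[, 1]
  d <- suppressWarnings(fit_variant(y, X, prior_spec("horseshoe"),
                                    sampler_config(chains = 2, iter = 1000, seed = 5)))
  expect_lt(abs(mean(d$beta[, 1]) - 1), 0.05)
  expect_true(all(abs(colMeans(d$beta[, -1])) < 0.05))
})

test_that("independent responses are shrunk toward zero", {
  set.seed(102)
  X <- matrix(rnorm(150 * 30), 150, 30, dimnames = list(NULL, paste0("t", 1:30)))
  y <- rnorm(150)
  d <- suppressWarnings(fit_variant(y, X, prior_spec("horseshoe"),
                                    sampler_config(chains = 2, iter = 1000, seed = 6)))
  expect_true(all(abs(colMeans(d$beta)) < 0.15))
})

test_that("horseshoe shrinks null coefficients harder than ridge", {
  set.seed(103)
  X <- matrix(rnorm(150 * 20), 150, 20, dimnames = list(NULL, paste0("t", 1:20)))
  y <- X[, 1] + rnorm(150, sd = 0.5)
  nullmean <- function(fam) {
    d <- suppressWarnings(fit_variant(y, X, prior_spec(fam),
                                      sampler_config(chains = 2, iter = 1000, seed = 7)))
    mean(abs(colMeans(d$beta[, -1])))
  }
  expect_lt(nullmean("horseshoe"), nullmean("ridge"))
})

test_that("all three prior families and the tau hyperprior produce sound draws", {
  set.seed(104)
  X <- matrix(rnorm(80 * 8), 80, 8, dimnames = list(NULL, paste0("t", 1:8)))
  y <- X[, 2] + rnorm(80, sd = 0.5)
  for (spec in list(prior_spec("ridge"), prior_spec("lasso"),
                    prior_spec("horseshoe", tau_hyperprior = TRUE))) {
    d <- suppressWarnings(fit_variant(y, X, spec,
                                      sampler_config(chains = 2, iter = 800, seed = 8)))
    expect_true(all(is.finite(d$beta)))
    expect_true(all(d$sigma > 0))
    r <- call_significant(d)
    expect_true(r$significant[2])
  }
})

test_that("significance is exactly the interval-excludes-zero rule", {
  fake <- function(draws_mat) {
    colnames(draws_mat) <- paste0("t", seq_len(ncol(draws_mat)))
    structure(list(beta = draws_mat, sigma = rep(1, nrow(draws_mat)),
                   diagnostics = data.frame(predictor = colnames(draws_mat),
                                            rhat = 1, ess = nrow(draws_mat)),
                   sampler_meta = list()), class = "posterior_draws")
  }
  expect_true(call_significant(fake(matrix(0.5, 200, 1)))$significant)
  sym <- matrix(c(seq(-1, 1, length.out = 500)), 500, 1)
  expect_false(call_significant(fake(sym))$significant)
  # 1000 draws with 30 negative: the 2.5% quantile (25th/26th order stats)
  # is negative, so the interval straddles zero
  set.seed(9)
  d <- c(-runif(30), runif(970))
  r <- call_significant(fake(matrix(sample(d), 1000, 1)))
  expect_lt(r$lower, 0)
  expect_false(r$significant)
  expect_error(call_significant(fake(matrix(0.5, 99, 1))), "100")
})

test_that("intervals are coherent and recompute the significance flag", {
  set.seed(105)
  X <- matrix(rnorm(100 * 10), 100, 10, dimnames = list(NULL, paste0("t", 1:10)))
  y <- 0.8 * X[, 3] + rnorm(100, sd = 0.7)
  d <- suppressWarnings(fit_variant(y, X, sampler = sampler_config(chains = 2, iter = 800, seed = 10)))
  for (m in c("quantile", "hpdi")) {
    r <- call_significant(d, method = m)
    expect_true(all(r$lower <= r$post_median + 1e-12))
    expect_true(all(r$post_median <= r$upper + 1e-12))
    expect_identical(r$significant, r$lower > 0 | r$upper < 0)
  }
})

test_that("identical seed and configuration give bit-identical draws", {
  set.seed(106)
  X <- matrix(rnorm(60 * 6), 60, 6, dimnames = list(NULL, paste0("t", 1:6)))
  y <- rnorm(60)
  d1 <- suppressWarnings(fit_variant(y, X, sampler = sampler_config(chains = 2, iter = 500, seed = 11)))
  d2 <- suppressWarnings(fit_variant(y, X, sampler = sampler_config(chains = 2, iter = 500, seed = 11)))
  expect_identical(d1$beta, d2$beta)
  expect_identical(d1$sigma, d2$sigma)
})

test_that("degenerate inputs fail with informative errors", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_variant(rep(1, 20), X), "monomorphic")
  expect_error(fit_variant(rnorm(19), X), "non-conformable")
})

test_that("per-gene runs align accessions and are deterministic per variant", {
  sp <- small_phenome(n = 50, p = 5, seed = 107)
  # two identical variants plus one distinct, all on chr1
  dos <- rbind(rbinom(50, 2, 0.4), 0, rbinom(50, 2, 0.3))
  dos[2, ] <- dos[1, ]
  meta <- data.frame(chrom = "chr1", pos = c(10L, 10L, 20L),
                     id = c("chr1_10", "chr1_10", "chr1_20"),
                     ref = "A", alt = "AT")
  vs <- variant_set(meta, `colnames<-`(dos, sp$traits$accession_ids))
  pcs <- loco_pcs(sp$pop$G, sp$pop$chrom_labels, 3)
  res <- suppressWarnings(run_gene(vs, sp$traits, pcs,
                                   sampler = sampler_config(chains = 2, iter = 500, seed = 12)))
  expect_length(res, 3L)
  expect_identical(res[[1]]$significant, res[[2]]$significant)
  expect_identical(res[[1]]$post_mean, res[[2]]$post_mean)
  tab <- association_table(res, vs)
  expect_identical(nrow(tab), 3L * (5L + 3L))

  expect_identical(run_gene(subset_variants(vs, integer(0)), sp$traits, pcs), list())

  bad <- vs; colnames(bad$dosage)[1] <- "ghost"; bad$accession_ids[1] <- "ghost"
  expect_error(run_gene(bad, sp$traits, pcs), "ghost")
  multi <- vs; multi$meta$chrom[3] <- "chr2"
  expect_error(run_gene(multi, sp$traits, pcs), "multiple chromosomes")
})
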