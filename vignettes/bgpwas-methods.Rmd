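---
title: "Models and methods behind bgpwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bgpwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical models the package implements, the
numerical choices made where the design was genuinely open, and what the
synthetic benchmarks do and do not establish about behavior on real data.

## 1. The reverse regression

For each variant, `fit_variant()` models the alternate-allele dosage
`y` (left on its 0..2 scale, Gaussian likelihood) as a linear function of
the full predictor block `X`: the standardized phenome plus the top three
leave-one-chromosome-out principal components for the variant's
chromosome. One fit per variant, never a multi-response model over
variants — variants inside one locus are in strong linkage
disequilibrium, and joint models over near-collinear responses mix poorly
and add nothing to the per-variant question "which traits does this
variant touch?".

Significance is interval-based: a predictor is flagged when its central
95% posterior interval excludes zero (`call_significant()`, with the
highest-posterior-density interval available via `method = "hpdi"`).
There is no additional multiple-testing correction across traits or
variants; false-positive control is delegated to the shrinkage prior,
which is the point of using one.

### Priors

* **Horseshoe** (default): `beta_j | lambda_j, tau ~ N(0, lambda_j^2 tau^2)`
  with `lambda_j ~ C+(0, 1)`. The global scale is anchored at
  `tau0 = p0/(D - p0)/sqrt(n)`, where `p0` is 10% of the predictor count
  (floor, minimum 1 — `compute_tau0()` accepts an explicit `p0` for the
  ceiling reading). By default `tau` receives a half-Cauchy(0, `tau0`)
  hyperprior rather than being pinned to `tau0`: probabilistic-programming
  horseshoe implementations treat the user-supplied global scale as the
  scale of a hyperprior, and we follow that convention. The fixed-`tau`
  variant is kept as `tau_hyperprior = FALSE`. The difference matters
  exactly when several correlated predictors are truly associated: with
  `tau` pinned at a value calibrated for ~`p0` escapees, the posterior
  keeps appreciable mass in the "shrunk to zero" configuration for each
  member of a correlated causal pair, and marginal intervals can straddle
  zero even when the least-squares partial test is unambiguous. Letting
  `tau` adapt removes that artifact without hurting null calibration
  (measured: zero flags on independent data at n = 200, D = 50).
* **Ridge**: `beta_j ~ N(0, 5)` — a deliberately diffuse comparison prior.
* **Lasso**: Laplace coefficient priors via the exponential scale-mixture
  representation; the tuning parameter `lambda^2` carries a chi-squared
  prior with 1 degree of freedom (expected value one).
* Residual sd: half-t(3, 0, sd(y)) in all families, via the
  inverse-gamma mixture that keeps the Gibbs conditionals conjugate.

### Sampler

Posterior draws come from auxiliary-variable Gibbs samplers (the
inverse-gamma mixture representation of half-Cauchy scales for the
horseshoe; the inverse-Gaussian conditional for the lasso's local
variances). All conditionals are exact, so no step-size tuning exists;
the contract is "valid posterior draws", checked by the calibration,
power and shrinkage-ordering benchmarks rather than by sampler identity.
Defaults are 4 chains of 2000 iterations with the first half discarded;
split R-hat and an initial-positive-sequence effective sample size are
reported per coefficient, and any R-hat at or above 1.05 raises a warning
rather than passing silently. A fixed seed gives bit-identical draws.

The number of expected escapees `p0` uses floor("10% of D") with a floor
of one. For the phenome sizes in question (D = 127 gives p0 = 12) the
floor/ceiling choice moves `tau0` by under 10%, well inside the
half-Cauchy hyperprior's tolerance.

## 2. Phenome preparation and imputation

Traits with more than 30% missing observations are removed (strictly
greater than; a trait at exactly the threshold stays). Near-duplicate
traits are then dropped by a greedy forward scan: a trait is removed when
its pairwise-complete Pearson correlation with any already-retained trait
exceeds 0.95 in absolute value. Keeping the earlier column makes the
result deterministic for a fixed column order; pairs sharing fewer than
three observations contribute r = 0 with a warning. Standardization is
per-trait over observed entries with the n−1 denominator, and the
(mean, sd) pairs are stored for back-transformation.

Missing entries are imputed once, on the full phenome, before any
association run. The model is a low-rank matrix-normal mixed model:

```
Y = S beta + eps,  S ~ MN(0, K, I_r),  beta ~ MN(0, I_r, tau^-1 I_p),
eps rows ~ N(0, E),  E^-1 ~ Wishart(p + 5, (1/4) I_p)
```

`K` is the VanRaden kinship, so related accessions share genetic signal
and correlated traits share information through `beta` and `E` — the two
channels that make kinship-aware imputation beat per-trait means.

**Fitting.** The fit maximizes the joint log posterior over
`(S, beta, E, Y_missing)` by block coordinate ascent. Each block update
is an exact conditional maximizer: the `S` and `beta` updates are
Sylvester systems solved in eigenbases (O(N^3) once for `K`, then
O(r^3 + p^3) per sweep), `E` has the closed-form Wishart-mode update
`(R'R + 4I)/(N + 4)`, and the missing entries of each row are the
Gaussian conditional means given the observed entries. Because every
step is an exact block maximization, the objective trace is
non-decreasing by construction — the property the tests assert — and the
imputed values are the model's conditional means, which is the quantity
of record. A full variational treatment with posterior covariances would
change the imputed point values only through second-order terms; the
recovery benchmarks validate the point imputation directly. Convergence
is declared when the relative objective change drops below 1e-6
(`tol`), with `max_iter = 1000`; which of the two stopped the fit is
reported.

**Numerical choices.** Kinship matrices are PSD but singular (the
centered GRM annihilates the all-ones vector), so eigenvalues of `K` are
floored at 1e-8 times the largest — equivalent to an infinitesimal ridge
— before inversion. `tau` defaults to 1 and the latent rank to
min(N, p); both are exposed because no canonical values exist for them.
The Wishart prior's `(1/4) I` scale keeps `E` strictly positive definite
even under exactly duplicated traits.

## 3. Genome preparation

Dosage is the per-sample count of the record's alternate allele;
multi-allelic records are decomposed into one record per alternate.
Missing genotypes are rejected, not imputed — the pipeline's input
contract is genotype-imputed data, and silently filling gaps here would
double-impute. The kinship is VanRaden's centered GRM
(`Z Z' / (2 Σ f_j (1 − f_j))`), the standard population-genetics choice
when the construction is otherwise unconstrained. LOCO principal
components for chromosome `c` are eigenvectors of the GRM built from all
variants *not* on `c`, scaled by the square roots of their eigenvalues;
each column's sign is fixed by making its largest-magnitude loading
positive so runs are reproducible. Strict exclusion is tested by
corrupting a chromosome's genotypes and asserting its own scores are
bit-identical.

## 4. Consequence calling

An InDel is mapped into the spliced CDS (minus-strand genes
reverse-complement; the transcript-first base of an allele is its
genomic last base), applied in the VCF anchored-allele convention after
verifying the reference against the transcript, and translated with the
standard code, stopping at the first stop codon. Classification follows
the frame rule — frameshift if and only if the allele length difference
is not a multiple of 3 and the variant overlaps the CDS — with in-frame
variants subdivided into stop_gained (an earlier stop than the length
change explains), stop_lost (no stop reached), in-frame
insertion/deletion, and an equal-length `synonymous_boundary` catch-all.
The truncation fraction is `1 − len(alt protein)/len(ref protein)` on
stop-free lengths, and domains whose intervals extend past the mutant
protein's end are reported as lost or partial. InDels spanning an
exon/intron boundary are rejected explicitly rather than guessed, and
variants touching the start or stop codon fall through to the general
rules — a documented divergence risk, since curated annotation pipelines
sometimes special-case them. The deleted reference substring is reported
verbatim so representation-level discrepancies between genome versions
stay visible.

## 5. Synthetic data: what it shows and what it cannot

The generators forward-simulate exactly the models above: binomial
dosages (optionally with Balding–Nichols deme structure, Fst 0.2, which
yields block kinship), matrix-normal phenomes on that kinship, causal
variants as dosage-proportional shifts on chosen standardized traits,
and MCAR masking (uniform or block). Effects are specified on the
standardized-trait scale so power statements are portable. Everything is
seed-deterministic, and the writers emit real VCF/TSV/GFF3/FASTA so
fixtures exercise the production parsers.

Benchmark problem sizes (also used by `scripts/acceptance.R`): null
calibration and power use n = 200 accessions and D = 50 predictors over
20 replicates at 2 chains × 1000 iterations; the shrinkage comparison
uses n = 150, D = 30 over 10 replicates; imputation recovery uses a
rank-2 phenome (n = 200, p = 10, residual sd 0.3, 10% masked) fitted at
the generating rank; the kinship-sensitivity contrast averages 10–20
replicates of a 3-deme, 90-accession design. The end-to-end benchmark
(10 replicates) uses a 20-trait phenome on a rank-5 latent space with
unit residual variance, one causal variant (MAF ≥ 0.1) shifting two
traits by 0.8 standardized units, 10% masking — the panel's own
missingness level — imputation, LOCO PCs, and the default sampler. The
latent rank matters: on a rank-2 latent space many of 20 traits are
near-duplicates of each other, a regime the pipeline's own |r| > 0.95
de-correlation step exists to remove, and per-trait marginal intervals
cannot cleanly separate near-collinear causal pairs. Rank 5 with unit
noise keeps pairwise trait correlations in the range a de-correlated
real phenome actually exhibits.

These simulations match the model's assumptions by construction. They do
not emulate linkage disequilibrium within genes, informative (non-MCAR)
missingness, non-Gaussian trait distributions, or multi-environment
structure — so passing benchmarks demonstrate correctness of the
machinery and calibration under the stated model, not performance
guarantees on any particular crop panel.

## 6. Known limitations

* Per-variant fits ignore LD between variants of the same gene;
  associations at tightly linked variants are expected to be similar and
  are reported individually.
* The imputation fit is a MAP-style point fit; no posterior uncertainty
  is attached to imputed values downstream.
* Consequence calls cover single-transcript coding effects only — no
  splice-site, UTR or regulatory predictions, and no structure-level
  scoring.
* The Gibbs samplers are exact but serial; at phenome scale (a hundred
  thousand InDels) runs should be parallelized across variants, which is
  embarrassingly parallel.
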