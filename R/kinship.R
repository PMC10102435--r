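col_vars <- function(G) {
  mu <- colMeans(G)
  colSums(sweep(G, 2, mu)^2) / max(1, nrow(G) - 1)
}

#' Genomic relationship (kinship) matrix
#'
#' VanRaden's centered genomic relationship matrix: with G the N x M dosage
#' matrix and f_j the alternate-allele frequency of variant j,
#' Z = G - 2f (column-wise) and K = Z Z' / (2 * sum_j f_j (1 - f_j)).
#' K is symmetric positive semidefinite with column sums of Z equal to
#' zero, so the all-ones vector lies in its null space.
#'
#' @param G N x M dosage matrix (accessions x variants, entries in [0, 2]).
#' @return N x N kinship matrix with accession dimnames.
#' @export
compute_kinship <- function(G) {
  G <- as.matrix(G)
  if (anyNA(G)) stop("missing dosages are not allowed in kinship computation")
  f <- colMeans(G) / 2
  poly <- col_vars(G) > 0
  if (sum(poly) < 2L)
    stop("kinship requires at least 2 polymorphic variants (got ", sum(poly), ")")
  Z <- sweep(G, 2, 2 * f, "-")
  denom <- 2 * sum(f * (1 - f))
  K <- tcrossprod(Z) / denom
  dimnames(K) <- list(rownames(G), rownames(G))
  K
}

#' Leave-one-chromosome-out principal components
#'
#' For every chromosome c, computes principal-component scores from the
#' kinship matrix built from variants on all chromosomes *except* c, so the
#' structure covariates used when testing a variant can never absorb signal
#' from that variant's own chromosome. Scores are eigenvectors of the
#' complement-chromosome kinship scaled by the square root of their
#' eigenvalues; each column's sign is fixed by making its
#' largest-magnitude loading positive, so outputs are reproducible.
#'
#' @param G N x M dosage matrix (accessions x variants).
#' @param chrom_labels Length-M chromosome label per variant column.
#' @param n_pcs Number of components per chromosome (default 3).
#'
#' @return An object of class `loco_pc_set`: a list with `scores` (named
#'   list of N x n_pcs matrices, one per chromosome), `varexp` (explained
#'   variance fractions), and `n_pcs`.
#' @export
loco_pcs <- function(G, chrom_labels, n_pcs = 3) {
  G <- as.matrix(G)
  stopifnot(length(chrom_labels) == ncol(G), n_pcs >= 1)
  chroms <- unique(chrom_labels)
  if (length(chroms) < 2L) stop("LOCO PCs require at least 2 chromosomes")
  scores <- list(); varexp <- list()
  for (ch in chroms) {
    Gc <- G[, chrom_labels != ch, drop = FALSE]
    K <- compute_kinship(Gc)
    e <- eigen(K, symmetric = TRUE)
    pos <- e$values > 1e-8 * max(e$values)
    if (sum(pos) < n_pcs)
      stop(sprintf("chromosome %s: complement has only %d informative dimensions (< %d)",
                   ch, sum(pos), n_pcs))
    idx <- seq_len(n_pcs)
    sc <- e$vectors[, idx, drop = FALSE] %*% diag(sqrt(e$values[idx]), n_pcs)
    for (j in idx) {
      piv <- which.max(abs(sc[, j]))
      if (sc[piv, j] < 0) sc[, j] <- -sc[, j]
    }
    rownames(sc) <- rownames(G)
    colnames(sc) <- paste0("PC", idx)
    scores[[ch]] <- sc
    varexp[[ch]] <- e$values[idx] / sum(e$values[pos])
  }
  structure(list(scores = scores, varexp = varexp, n_pcs = n_pcs),
            class = "loco_pc_set")
}

#' @export
print.loco_pc_set <- function(x, ...) {
  cat(sprintf("loco_pc_set: %d chromosomes x %d PCs\n",
              length(x$scores), x$n_pcs))
  invisible(x)
}

#' Write a kinship matrix (or PC scores) as TSV with accession ids
#'
#' @param M Matrix with accession rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(M, path) {
  df <- data.frame(accession = rownames(M), M, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
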