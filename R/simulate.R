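# Synthetic genotype-phenome data with known causal structure. The
# generators forward-simulate exactly the models the pipeline assumes
# (kinship-structured matrix-normal phenomes; dosage-proportional trait
# shifts for causal variants), so recovery tests have a ground truth.

#' Simulate a genotyped population
#'
#' Dosages are drawn binomial(2, f) per variant with allele frequencies
#' uniform over `maf_range`. With `block_structure`, accessions are split
#' into demes and per-deme frequencies are drawn from a Balding-Nichols
#' beta around the ancestral frequency (Fst 0.2), inducing block kinship.
#'
#' @param n Number of accessions (>= 2).
#' @param n_variants Number of variants.
#' @param n_chrom Number of chromosomes; variants are split evenly.
#' @param maf_range Length-2 allele-frequency range, subset of (0, 0.5].
#' @param block_structure `NULL` (panmictic), an integer number of demes,
#'   or a length-n deme assignment vector.
#' @param seed Integer seed.
#'
#' @return List with `G` (n x M dosage matrix, accession rownames),
#'   `chrom_labels` (length M), `K` (realized kinship via
#'   [compute_kinship()]), `demes` (assignment or NULL), `seed`.
#' @export
simulate_population <- function(n, n_variants, n_chrom = 2,
                                maf_range = c(0.1, 0.5),
                                block_structure = NULL, seed = 1) {
  stopifnot(n >= 2, n_variants >= 2, n_chrom >= 1)
  if (length(maf_range) != 2 || maf_range[1] >= maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("degenerate maf_range: need 0 < lo < hi <= 0.5")
  set.seed(seed)
  demes <- NULL
  if (!is.null(block_structure)) {
    demes <- if (length(block_structure) == 1L)
      sort(rep_len(seq_len(block_structure), n)) else block_structure
    stopifnot(length(demes) == n)
  }
  f <- stats::runif(n_variants, maf_range[1], maf_range[2])
  G <- matrix(0, n, n_variants)
  if (is.null(demes)) {
    for (j in seq_len(n_variants)) G[, j] <- stats::rbinom(n, 2, f[j])
  } else {
    fst <- 0.2
    a <- (1 - fst) / fst
    for (j in seq_len(n_variants)) {
      fd <- stats::rbeta(length(unique(demes)), f[j] * a, (1 - f[j]) * a)
      fd <- pmin(pmax(fd, 0.01), 0.99)
      G[, j] <- stats::rbinom(n, 2, fd[demes])
    }
  }
  rownames(G) <- paste0("acc", seq_len(n))
  chrom_labels <- paste0("chr", rep_len(seq_len(n_chrom), n_variants))
  colnames(G) <- paste0(chrom_labels, "_", seq_len(n_variants))
  list(G = G, chrom_labels = chrom_labels, K = compute_kinship(G),
       demes = demes, seed = seed)
}

rmatnorm_rows <- function(n, p, row_chol) {
  # X = L Z with Z iid N(0,1): X ~ MN(0, L L', I_p)
  row_chol %*% matrix(stats::rnorm(n * p), n, p)
}

psd_factor <- function(M, name) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1))
    stop(name, " is not positive semidefinite (eigenvalue ", min(e$values), ")")
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(M))
}

#' Simulate a complete kinship-structured phenome
#'
#' Forward simulation of the imputation model: Y = S beta + eps with
#' S ~ MN(0, K, I_rank), beta ~ MN(0, I_rank, tau^-1 I_p), and residual
#' rows i.i.d. N(0, `noise_cov`).
#'
#' @param K N x N kinship matrix (PSD).
#' @param p Number of traits.
#' @param rank Latent rank of the genetic term.
#' @param tau Precision scale of beta (large tau shrinks the genetic term
#'   away, leaving Y ~ eps).
#' @param noise_cov p x p residual covariance (default identity), or a
#'   single number meaning `noise_sd^2 * I`.
#' @param seed Integer seed.
#'
#' @return A complete `trait_matrix`; attributes `S`, `beta`, `E` hold the
#'   latent truth.
#' @export
simulate_phenome <- function(K, p, rank = 2, tau = 1, noise_cov = NULL,
                             seed = 1) {
  K <- as.matrix(K)
  N <- nrow(K)
  stopifnot(rank >= 1, rank <= p, tau > 0)
  if (is.null(noise_cov)) noise_cov <- diag(p)
  if (length(noise_cov) == 1L) noise_cov <- diag(as.numeric(noise_cov), p)
  set.seed(seed)
  Lk <- psd_factor(K, "K")
  Le <- psd_factor(noise_cov, "noise_cov")
  S <- rmatnorm_rows(N, rank, Lk)
  beta <- matrix(stats::rnorm(rank * p, sd = 1 / sqrt(tau)), rank, p)
  eps <- t(Le %*% matrix(stats::rnorm(N * p), p, N))
  Y <- S %*% beta + eps
  rownames(Y) <- rownames(K)
  tm <- trait_matrix(Y)
  attr(tm, "S") <- S; attr(tm, "beta") <- beta; attr(tm, "E") <- noise_cov
  tm
}

#' Inject a causal variant into chosen traits
#'
#' Adds a dosage-proportional shift to each causal trait:
#' `Y[, t] <- Y[, t] + effect_t * dosage`, recording the ground truth.
#'
#' @param Y A `trait_matrix`.
#' @param dosage Length-N dosage vector of the causal variant.
#' @param causal_traits Integer trait indices (distinct).
#' @param effect_sizes Effects on the trait scale, recycled to
#'   `causal_traits`.
#' @param variant_id Identifier recorded in the truth.
#'
#' @return List with `traits` (modified `trait_matrix`) and `truth`
#'   (class `sim_truth`: variant id, per-trait effects).
#' @export
inject_causal_variant <- function(Y, dosage, causal_traits, effect_sizes,
                                  variant_id = "causal") {
  tm <- as_trait_matrix(Y)
  p <- ncol(tm$values)
  if (anyDuplicated(causal_traits)) stop("causal traits must be distinct")
  if (any(causal_traits < 1 | causal_traits > p))
    stop("causal trait index out of range 1..", p)
  effect_sizes <- rep_len(effect_sizes, length(causal_traits))
  if (any(!is.finite(effect_sizes))) stop("effects must be finite")
  stopifnot(length(dosage) == nrow(tm$values))
  vals <- tm$values
  for (k in seq_along(causal_traits))
    vals[, causal_traits[k]] <- vals[, causal_traits[k]] +
      effect_sizes[k] * dosage
  truth <- structure(list(variant_id = variant_id,
                          causal = data.frame(trait = as.integer(causal_traits),
                                              trait_name = tm$trait_names[causal_traits],
                                              effect = effect_sizes)),
                     class = "sim_truth")
  list(traits = trait_matrix(vals, tm$accession_ids, tm$trait_names,
                             standardization = tm$standardization),
       truth = truth)
}

#' Mask entries of a phenome, recording the held-out truth
#'
#' @param Y A complete `trait_matrix`.
#' @param rates Per-trait missingness rate(s) in [0, 0.9], recycled.
#' @param pattern `"uniform"` (MCAR everywhere) or `"block"` (MCAR inside
#'   an accession x trait block).
#' @param block Optional list with `accessions` and `traits` index vectors
#'   for `pattern = "block"`; defaults to a random half of each.
#' @param seed Integer seed.
#'
#' @return List with `traits` (masked `trait_matrix`) and `heldout` (data
#'   frame `row`, `col`, `value` of the masked truth).
#' @export
mask_missing <- function(Y, rates, pattern = c("uniform", "block"),
                         block = NULL, seed = 1) {
  pattern <- match.arg(pattern)
  tm <- as_trait_matrix(Y)
  N <- nrow(tm$values); p <- ncol(tm$values)
  rates <- rep_len(rates, p)
  if (any(rates < 0 | rates > 0.9)) stop("rates must lie in [0, 0.9]")
  set.seed(seed)
  drop_mask <- matrix(FALSE, N, p)
  if (pattern == "uniform") {
    for (j in seq_len(p)) drop_mask[, j] <- stats::runif(N) < rates[j]
  } else {
    if (is.null(block))
      block <- list(accessions = sample(N, ceiling(N / 2)),
                    traits = sample(p, ceiling(p / 2)))
    for (j in intersect(seq_len(p), block$traits))
      drop_mask[block$accessions, j] <-
        stats::runif(length(block$accessions)) < rates[j]
  }
  fully <- which(colSums(!drop_mask) == 0L)
  if (length(fully))
    stop("masking would remove every observation of trait(s): ",
         paste(tm$trait_names[fully], collapse = ", "))
  idx <- which(drop_mask, arr.ind = TRUE)
  heldout <- data.frame(row = idx[, 1], col = idx[, 2],
                        value = tm$values[drop_mask])
  vals <- tm$values
  vals[drop_mask] <- NA_real_
  list(traits = trait_matrix(vals, tm$accession_ids, tm$trait_names,
                             standardization = tm$standardization),
       heldout = heldout)
}

random_codons <- function(k) {
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  paste(sample(sense, k, replace = TRUE), collapse = "")
}

#' Generate a toy gene with labeled candidate InDels
#'
#' Builds a random valid CDS (ATG start, stop end, no internal stops),
#' splits it over `n_exons` exons embedded in a synthetic chromosome with
#' random introns and flanks, and emits candidate InDels with their
#' expected consequence classes: a frameshift (1-bp exonic deletion), an
#' in-frame deletion (3-bp, chosen so no premature stop arises) and a
#' noncoding control (intronic when possible, flanking otherwise).
#'
#' @param n_exons Number of CDS exons (>= 1).
#' @param strand `"+"` or `"-"`.
#' @param n_codons Number of codons including start and stop (default 60).
#' @param chrom Chromosome name for the synthetic sequence.
#' @param seed Integer seed.
#'
#' @return List with `gene` (a `gene_model`), `chrom_seq` (the synthetic
#'   chromosome string), and `candidates` (data frame `chrom`, `pos`,
#'   `ref`, `alt`, `expected_class`, VCF anchored alleles in plus-strand
#'   genomic coordinates).
#' @export
make_toy_gene <- function(n_exons = 2, strand = "+", n_codons = 60,
                          chrom = "chr1", seed = 1) {
  stopifnot(n_exons >= 1, n_codons >= 10)
  set.seed(seed)
  stops <- c("TAA", "TAG", "TGA")
  cds <- paste0("ATG", random_codons(n_codons - 2), sample(stops, 1))
  L <- nchar(cds)

  # split CDS into exon pieces (transcript order)
  cuts <- if (n_exons > 1) sort(sample(seq(2, L - 1), n_exons - 1)) else integer(0)
  bounds <- c(0, cuts, L)
  pieces <- vapply(seq_len(n_exons), function(i)
    substr(cds, bounds[i] + 1, bounds[i + 1]), character(1))

  rand_seq <- function(k) paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                                collapse = "")
  flank5 <- rand_seq(sample(30:60, 1))
  introns <- if (n_exons > 1)
    vapply(seq_len(n_exons - 1), function(i) rand_seq(sample(20:50, 1)),
           character(1)) else character(0)
  flank3 <- rand_seq(sample(30:60, 1))

  # genomic order of pieces: transcript order for +, reversed+revcomp for -
  genomic_pieces <- if (strand == "+") pieces else
    rev(vapply(pieces, revcomp, character(1)))

  seq_parts <- character(0)
  starts <- integer(n_exons); ends <- integer(n_exons)
  cursor <- nchar(flank5)
  seq_parts <- flank5
  for (i in seq_len(n_exons)) {
    starts[i] <- cursor + 1L
    ends[i] <- cursor + nchar(genomic_pieces[i])
    seq_parts <- paste0(seq_parts, genomic_pieces[i])
    cursor <- ends[i]
    if (i < n_exons) {
      seq_parts <- paste0(seq_parts, introns[i])
      cursor <- cursor + nchar(introns[i])
    }
  }
  chrom_seq <- paste0(seq_parts, flank3)
  exons <- data.frame(start = starts, end = ends)
  gene <- gene_model(paste0("toy_", chrom), chrom, strand, exons, cds)

  sample1 <- function(v) if (length(v) == 1L) v else sample(v, 1)

  # pick an exon with room for a 4-base anchored allele
  widths <- ends - starts + 1
  host <- which(widths >= 8)[1]
  if (is.na(host)) host <- which.max(widths)
  exon_pick <- function(len) {
    # genomic start for an allele of `len` bases fully inside the host exon,
    # away from the CDS start/stop codons
    lo <- starts[host] + 3L
    hi <- ends[host] - len - 3L
    if (hi < lo) { lo <- starts[host]; hi <- ends[host] - len + 1L }
    sample1(seq(lo, hi))
  }

  gsub_at <- function(s, pos, ref_len, repl) {
    paste0(substr(s, 1, pos - 1), repl, substr(s, pos + ref_len, nchar(s)))
  }
  label_by_translation <- function(pos, ref, alt) {
    # brute-force label: mutate the chromosome, re-splice with shifted
    # downstream exon coordinates, translate codon-by-codon
    mut <- gsub_at(chrom_seq, pos, nchar(ref), alt)
    shift <- nchar(alt) - nchar(ref)
    st <- starts; en <- ends
    en[en >= pos] <- en[en >= pos] + shift
    st[st > pos] <- st[st > pos] + shift
    spl <- paste(vapply(seq_len(n_exons), function(i)
      substr(mut, st[i], en[i]), character(1)), collapse = "")
    if (strand == "-") spl <- revcomp(spl)
    n_cod <- nchar(spl) %/% 3
    aas <- Biostrings::GENETIC_CODE[substring(spl, 3 * (seq_len(n_cod) - 1) + 1,
                                              3 * (seq_len(n_cod) - 1) + 3)]
    stop_at <- which(aas == "*")
    alt_len <- if (length(stop_at)) stop_at[1] - 1 else n_cod
    ref_len_prot <- n_codons - 1  # codons minus the stop
    if ((nchar(alt) - nchar(ref)) %% 3 != 0) return("frameshift")
    if (!length(stop_at)) return("stop_lost")
    if (alt_len < ref_len_prot + (nchar(alt) - nchar(ref)) / 3) return("stop_gained")
    if (nchar(alt) < nchar(ref)) return("inframe_deletion")
    if (nchar(alt) > nchar(ref)) return("inframe_insertion")
    "synonymous_boundary"
  }

  # frameshift: anchored 1-bp deletion in the host exon
  fs_pos <- exon_pick(2)
  fs_ref <- substr(chrom_seq, fs_pos, fs_pos + 1)
  fs_alt <- substr(chrom_seq, fs_pos, fs_pos)

  # in-frame 3-bp deletion avoiding premature stops: resample until clean
  if_pos <- NA_integer_
  for (try in 1:200) {
    cand <- exon_pick(4)
    ref <- substr(chrom_seq, cand, cand + 3)
    alt <- substr(chrom_seq, cand, cand)
    if (label_by_translation(cand, ref, alt) == "inframe_deletion") {
      if_pos <- cand; if_ref <- ref; if_alt <- alt; break
    }
  }
  if (is.na(if_pos)) stop("could not place a clean in-frame deletion; try another seed")

  # noncoding control: intron when available, 5' flank otherwise
  nc_pos <- if (n_exons > 1) {
    iv <- c(ends[1] + 2L, starts[2] - 3L)
    sample1(seq(iv[1], iv[2]))
  } else sample1(seq(2, nchar(flank5) - 2))
  nc_ref <- substr(chrom_seq, nc_pos, nc_pos + 1)
  nc_alt <- substr(chrom_seq, nc_pos, nc_pos)

  candidates <- data.frame(
    chrom = chrom,
    pos = c(fs_pos, if_pos, nc_pos),
    ref = c(fs_ref, if_ref, nc_ref),
    alt = c(fs_alt, if_alt, nc_alt),
    expected_class = c("frameshift", "inframe_deletion", "noncoding"),
    stringsAsFactors = FALSE)

  list(gene = gene, chrom_seq = chrom_seq, candidates = candidates,
       seed = seed)
}

#' Write sequences to FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a gene model to GFF3
#' @param genes A `gene_model` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  if (inherits(genes, "gene_model")) genes <- list(genes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in genes) {
    span <- c(min(g$cds_exons$start), max(g$cds_exons$end))
    writeLines(sprintf("%s\tbgpwas\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, span[1], span[2], g$strand, g$gene_id), con)
    mrna <- paste0(g$gene_id, ".1")
    writeLines(sprintf("%s\tbgpwas\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       g$chrom, span[1], span[2], g$strand, mrna, g$gene_id), con)
    phase <- 0
    ex <- g$cds_exons
    ord <- if (g$strand == "+") order(ex$start) else order(-ex$start)
    for (i in ord) {
      writeLines(sprintf("%s\tbgpwas\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
                         g$chrom, ex$start[i], ex$end[i], g$strand, phase,
                         mrna, mrna), con)
      phase <- (3 - ((ex$end[i] - ex$start[i] + 1 - phase) %% 3)) %% 3
    }
  }
  invisible(path)
}

#' Write a variant set to VCF
#'
#' Emits a minimal valid VCF 4.2 with GT fields derived from integer
#' dosages (0 -> 0/0, 1 -> 0/1, 2 -> 1/1).
#'
#' @param vs A `variant_set` with integer dosages.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path) {
  if (any(!vs$dosage %in% 0:2))
    stop("VCF output requires integer dosages in 0..2")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  samples <- vs$accession_ids
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  gt_map <- c("0/0", "0/1", "1/1")
  ord <- order(vs$meta$chrom, vs$meta$pos)
  for (i in ord) {
    gts <- gt_map[vs$dosage[i, ] + 1]
    writeLines(paste(c(vs$meta$chrom[i], vs$meta$pos[i], vs$meta$id[i],
                       vs$meta$ref[i], vs$meta$alt[i], ".", "PASS", ".",
                       "GT", gts), collapse = "\t"), con)
  }
  invisible(path)
}
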