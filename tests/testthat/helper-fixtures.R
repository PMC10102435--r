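# Shared fixtures and independent oracles, built in code at test time.

# independent brute-force consequence oracle: mutate the CDS string, then
# translate codon by codon with an explicit loop until the first stop.
oracle_mutate <- function(cds, cds_pos, ref, alt) {
  stopifnot(substr(cds, cds_pos, cds_pos + nchar(ref) - 1) == ref)
  paste0(substr(cds, 1, cds_pos - 1), alt,
         substr(cds, cds_pos + nchar(ref), nchar(cds)))
}

oracle_translate <- function(seq) {
  code <- Biostrings::GENETIC_CODE
  prot <- character(0)
  i <- 1
  while (i + 2 <= nchar(seq)) {
    aa <- code[[substr(seq, i, i + 2)]]
    if (aa == "*") return(paste(prot, collapse = ""))
    prot <- c(prot, aa)
    i <- i + 3
  }
  paste(prot, collapse = "")
}

# random valid CDS: ATG + sense codons + stop
random_cds <- function(n_codons, seed) {
  set.seed(seed)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  paste0("ATG", paste(sample(sense, n_codons - 2, replace = TRUE), collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1))
}

# single-exon plus-strand gene wrapping a CDS at a genomic offset
wrap_gene <- function(cds, offset = 50, chrom = "chrX", seed = 99) {
  set.seed(seed)
  pad <- function(k) paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                           collapse = "")
  left <- pad(offset)
  right <- pad(40)
  chrom_seq <- paste0(left, cds, right)
  g <- gene_model("gX", chrom, "+",
                  data.frame(start = offset + 1, end = offset + nchar(cds)),
                  cds)
  list(gene = g, chrom_seq = chrom_seq, cds_start = offset + 1)
}

# a gene whose 1-bp deletion at codon 61 frameshifts into an immediate
# stop, truncating a 100-residue protein to 60 residues (truncation 0.40)
make_truncation40_gene <- function() {
  set.seed(4242)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  head60 <- paste(c("ATG", sample(sense, 59, replace = TRUE)), collapse = "")
  # codon 61 = GTA, codon 62 = AAA: deleting base 181 shifts the frame so
  # the read after residue 60 becomes TAA (stop)
  tail_codons <- paste(sample(sense, 38, replace = TRUE), collapse = "")
  cds <- paste0(head60, "GTA", "AAA", tail_codons, "TAA")
  stopifnot(nchar(cds) == 303)
  wrap_gene(cds, offset = 25, chrom = "chrM", seed = 123)
}

# small standardized phenome on a simulated population
small_phenome <- function(n = 60, p = 6, seed = 7, noise_sd = 0.4) {
  pop <- simulate_population(n, 90, n_chrom = 3, seed = seed)
  phen <- simulate_phenome(pop$K, p, rank = 2, noise_cov = noise_sd^2,
                           seed = seed + 1)
  list(pop = pop, traits = standardize_traits(phen))
}

# write a small VCF from explicit body lines (for parser edge cases)
write_raw_vcf <- function(body_lines, samples, path) {
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               body_lines), path)
  path
}
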