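# InDel -> transcript -> protein consequence calling.

test_that("genomic positions map to spliced CDS offsets on both strands", {
  cds <- paste0("ATG", strrep("GGC", 18), "TAA")  # 60 nt
  gp <- gene_model("gp", "c1", "+", data.frame(start = 101, end = 160), cds,
                   validate = FALSE)
  expect_identical(map_to_cds(gp, 103), 3L)
  gm <- gene_model("gm", "c1", "-", data.frame(start = 101, end = 160), cds,
                   validate = FALSE)
  expect_identical(map_to_cds(gm, 158), 3L)
  g2 <- gene_model("g2", "c1", "+",
                   data.frame(start = c(101, 201), end = c(130, 230)),
                   strrep("A", 60), validate = FALSE)
  expect_identical(map_to_cds(g2, 205), 35L)
  # intron/UTR -> noncoding; boundary-spanning InDel -> explicit failure
  expect_identical(map_to_cds(g2, 150), NA_integer_)
  expect_identical(map_to_cds(g2, 90), NA_integer_)
  expect_error(map_to_cds(g2, 129, allele_len = 4), "boundary")
})

test_that("anchored InDels are applied after verifying the transcript ref", {
  expect_identical(apply_indel("ATGAAAGGGTAG", 4, "AA", "A"), "ATGAAGGGTAG")
  expect_identical(apply_indel("ATGAAAGGGTAG", 3, "GAAA", "G"), "ATGGGGTAG")
  expect_error(apply_indel("ATGAAAGGGTAG", 1, "C", "CA"), "mismatch")
})

test_that("translation stops at the first stop and flags read-through", {
  expect_identical(as.character(translate_cds("ATGAAAGGGTAG")), "MKG")
  p <- translate_cds("ATGAAGGGTAG")  # frameshifted: TAG now out of frame
  expect_identical(as.character(p), "MKG")
  expect_true(attr(p, "stop_lost"))
  expect_identical(as.character(translate_cds("ATGTAG")), "M")
  expect_error(translate_cds("ATGNNN"), "non-ACGT")
})

test_that("a frameshift deletion truncating to 60% reproduces the 0.40 loss", {
  fx <- make_truncation40_gene()
  g <- fx$gene
  expect_identical(nchar(translate_cds(g$cds_sequence)), 100L)
  pos <- fx$cds_start + 179  # anchored deletion removing CDS base 181
  ref <- substr(g$cds_sequence, 180, 181)
  cc <- classify_indel(g, "chrM", pos, ref, substr(ref, 1, 1),
                       domains = data.frame(start = c(5, 70), end = c(30, 95),
                                            label = c("kept_dom", "lost_dom")))
  expect_identical(cc$consequence_class, "frameshift")
  expect_identical(nchar(cc$alt_protein), 60L)
  expect_equal(cc$truncation_fraction, 0.40)
  expect_identical(cc$lost_domains$label, "lost_dom")
  expect_identical(cc$lost_domains$status, "lost")
})

test_that("in-frame, stop-gain, stop-loss and intronic cases classify correctly", {
  cds <- random_cds(40, seed = 210)
  fx <- wrap_gene(cds, offset = 30)
  g <- fx$gene
  # in-frame 3-base anchored deletion at a codon boundary (CDS bases 7-9)
  ref <- substr(cds, 6, 9)
  cc <- classify_indel(g, "chrX", fx$cds_start + 5, ref, substr(ref, 1, 1))
  if (cc$consequence_class == "inframe_deletion") {
    expect_equal(cc$truncation_fraction, 1 / nchar(cc$ref_protein))
    expect_identical(cc$deleted_sequence, substr(ref, 2, 4))
  }
  # in-frame TAA insertion after codon 3 -> premature stop
  anchor <- substr(cds, 9, 9)
  cc2 <- classify_indel(g, "chrX", fx$cds_start + 8, anchor, paste0(anchor, "TAA"))
  expect_identical(cc2$consequence_class, "stop_gained")
  expect_identical(nchar(cc2$alt_protein), 3L)
  # in-frame deletion of the stop codon -> read-through
  L <- nchar(cds)
  ref3 <- substr(cds, L - 3, L)
  cc3 <- classify_indel(g, "chrX", fx$cds_start + L - 4, ref3, substr(ref3, 1, 1))
  expect_identical(cc3$consequence_class, "stop_lost")
  # flanking (outside CDS) -> noncoding, protein untouched
  cc4 <- classify_indel(g, "chrX", 5, "AA", "A")
  expect_identical(cc4$consequence_class, "noncoding")
  expect_identical(cc4$alt_protein, cc4$ref_protein)
  expect_error(classify_indel(g, "chrY", 5, "A", "AT"), "chromosome")
})

test_that("mutant proteins match the brute-force mutate-and-translate oracle", {
  set.seed(321)
  n_match <- 0
  for (i in 1:300) {
    cds <- random_cds(sample(20:60, 1), seed = 1000 + i)
    L <- nchar(cds)
    fx <- wrap_gene(cds, offset = 20, seed = 2000 + i)
    # random anchored InDel inside the CDS (deletion or insertion, 1-6 bp)
    del <- runif(1) < 0.5
    k <- sample(1:6, 1)
    if (del) {
      cds_pos <- sample(seq_len(L - k - 1), 1)
      ref <- substr(cds, cds_pos, cds_pos + k)
      alt <- substr(ref, 1, 1)
    } else {
      cds_pos <- sample(seq_len(L - 1), 1)
      ref <- substr(cds, cds_pos, cds_pos)
      alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                               collapse = ""))
    }
    cc <- classify_indel(fx$gene, "chrX", fx$cds_start + cds_pos - 1, ref, alt)
    expected <- oracle_translate(oracle_mutate(cds, cds_pos, ref, alt))
    expect_identical(cc$alt_protein, expected)
    # frame rule: frameshift iff length difference not a multiple of 3
    expect_identical(cc$consequence_class == "frameshift",
                     (nchar(alt) - nchar(ref)) %% 3 != 0)
    n_match <- n_match + identical(cc$alt_protein, expected)
  }
  expect_identical(n_match, 300)
})

test_that("minus-strand genes mirror plus-strand calls exactly", {
  for (s in c(3, 14)) {
    cds <- random_cds(30, seed = 400 + s)
    fx <- wrap_gene(cds, offset = 40, seed = 500 + s)
    L_chrom <- nchar(fx$chrom_seq)
    # mirror: reverse-complement chromosome, flip exon interval and strand
    chrom_rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(fx$chrom_seq)))
    ex <- fx$gene$cds_exons
    ex_rc <- data.frame(start = L_chrom - ex$end + 1, end = L_chrom - ex$start + 1)
    g_rc <- gene_model("gX_rc", "chrX", "-", ex_rc, cds)
    # anchored 2-bp deletion inside the CDS and its mirrored representation
    cds_pos <- 10
    ref <- substr(cds, cds_pos, cds_pos + 2)
    alt <- substr(ref, 1, 1)
    pos_plus <- fx$cds_start + cds_pos - 1
    cc_plus <- classify_indel(fx$gene, "chrX", pos_plus, ref, alt)
    pos_minus <- L_chrom - (pos_plus + nchar(ref) - 1) + 1
    rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
    cc_minus <- classify_indel(g_rc, "chrX", pos_minus, rc(ref), rc(alt))
    expect_identical(cc_minus$consequence_class, cc_plus$consequence_class)
    expect_identical(cc_minus$alt_protein, cc_plus$alt_protein)
  }
})

test_that("gene models round-trip through GFF3 and FASTA on both strands", {
  for (str in c("+", "-")) {
    toy <- make_toy_gene(n_exons = 3, strand = str, seed = 9)
    fa <- tempfile(fileext = ".fasta"); gff <- tempfile(fileext = ".gff3")
    write_fasta(stats::setNames(toy$chrom_seq, toy$gene$chrom), fa)
    write_gff3(toy$gene, gff)
    gm <- read_gene_models(gff, fa)[[1]]
    expect_identical(gm$cds_sequence, toy$gene$cds_sequence)
    expect_identical(gm$strand, str)
    expect_equal(gm$cds_exons, toy$gene$cds_exons, ignore_attr = TRUE)
  }
  expect_error(read_gene_models(tempfile(), tempfile()), "not found")
})
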