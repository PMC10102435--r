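#' Coding gene model
#'
#' A minimal transcript model for consequence calling: ordered CDS exons in
#' genomic coordinates plus the spliced coding sequence in transcript
#' (5'->3') orientation. For minus-strand genes the spliced sequence is the
#' reverse complement of the genomic exon concatenation.
#'
#' @param gene_id Gene/transcript identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param cds_exons Data frame with 1-based inclusive `start`, `end`
#'   columns (genomic coordinates, any order; sorted internally).
#' @param cds_sequence Spliced CDS, 5'->3' in transcript orientation.
#' @param validate If `TRUE` (default) require the CDS length to match the
#'   exon widths and be a multiple of 3, and the translation to run
#'   start-codon (M) to stop.
#'
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, cds_exons, cds_sequence,
                       validate = TRUE) {
  stopifnot(strand %in% c("+", "-"), is.data.frame(cds_exons),
            all(c("start", "end") %in% names(cds_exons)))
  cds_exons <- cds_exons[order(cds_exons$start), c("start", "end")]
  if (any(cds_exons$end < cds_exons$start)) stop("exon end before start")
  cds_sequence <- toupper(cds_sequence)
  widths <- cds_exons$end - cds_exons$start + 1
  if (validate) {
    if (sum(widths) != nchar(cds_sequence))
      stop(sprintf("CDS length %d does not match summed exon widths %d",
                   nchar(cds_sequence), sum(widths)))
    if (nchar(cds_sequence) %% 3 != 0)
      stop("CDS length is not a multiple of 3")
    prot <- translate_cds(cds_sequence)
    if (substr(prot, 1, 1) != "M")
      stop("CDS does not begin with a start codon")
    last_codon <- substr(cds_sequence, nchar(cds_sequence) - 2, nchar(cds_sequence))
    if (!last_codon %in% c("TAA", "TAG", "TGA"))
      stop("CDS does not end with a stop codon")
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 cds_exons = cds_exons, cds_sequence = cds_sequence),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s: %s:%d-%d (%s), %d CDS exon(s), %d bp\n",
              x$gene_id, x$chrom, min(x$cds_exons$start), max(x$cds_exons$end),
              x$strand, nrow(x$cds_exons), nchar(x$cds_sequence)))
  invisible(x)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Read gene models from GFF3 and reference FASTA
#'
#' Extracts CDS features grouped by their parent transcript (falling back
#' to their ID/gene attribute), splices them against the reference and
#' returns validated [gene_model()] objects.
#'
#' @param gff_path GFF3 file with CDS features.
#' @param fasta_path Reference FASTA.
#' @return Named list of `gene_model`.
#' @export
read_gene_models <- function(gff_path, fasta_path) {
  if (!file.exists(gff_path)) stop("GFF3 file not found: ", gff_path)
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  ref <- Biostrings::readDNAStringSet(fasta_path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  gr <- rtracklayer::import(gff_path)
  cds <- gr[gr$type == "CDS"]
  if (length(cds) == 0L) stop("no CDS features in ", gff_path)
  md <- S4Vectors::mcols(cds)
  grp <- if ("Parent" %in% names(md) && any(lengths(md$Parent) > 0)) {
    vapply(as.list(md$Parent), function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  } else if ("ID" %in% names(md)) as.character(md$ID) else
    rep("gene1", length(cds))
  chrom_names <- as.character(GenomicRanges::seqnames(cds))
  bad <- setdiff(unique(chrom_names), names(ref))
  if (length(bad))
    stop("chromosome name mismatch between GFF3 and FASTA: missing {",
         paste(bad, collapse = ","), "} in FASTA ({",
         paste(names(ref), collapse = ","), "})")
  out <- list()
  for (g in unique(grp)) {
    sel <- which(grp == g)
    chrom <- chrom_names[sel[1]]
    strand <- as.character(GenomicRanges::strand(cds[sel[1]]))
    if (!strand %in% c("+", "-")) strand <- "+"
    ex <- data.frame(start = GenomicRanges::start(cds[sel]),
                     end = GenomicRanges::end(cds[sel]))
    ex <- ex[order(ex$start), ]
    chrom_seq <- ref[[chrom]]
    pieces <- vapply(seq_len(nrow(ex)), function(i)
      as.character(Biostrings::subseq(chrom_seq, ex$start[i], ex$end[i])),
      character(1))
    spliced <- paste(pieces, collapse = "")
    if (strand == "-") spliced <- revcomp(spliced)
    out[[g]] <- gene_model(g, chrom, strand, ex, spliced)
  }
  out
}

#' Map a genomic position into spliced CDS coordinates
#'
#' Returns the 1-based transcript-oriented offset of an allele starting at
#' `pos` (plus-strand genomic coordinates) with reference length
#' `allele_len`. For minus-strand genes the transcript-first base of the
#' allele is its genomic *last* base. Positions outside every CDS exon map
#' to `NA` ("noncoding"); alleles that partially overlap an exon or span
#' an exon/intron boundary are rejected.
#'
#' @param gene A `gene_model`.
#' @param pos 1-based genomic position of the allele's first base.
#' @param allele_len Reference-allele length (default 1).
#' @return Integer CDS offset, or `NA_integer_` when noncoding.
#' @export
map_to_cds <- function(gene, pos, allele_len = 1) {
  ex <- gene$cds_exons
  g1 <- pos; g2 <- pos + allele_len - 1
  overlaps <- which(ex$end >= g1 & ex$start <= g2)
  if (length(overlaps) == 0L) return(NA_integer_)
  if (length(overlaps) > 1L)
    stop("unsupported: InDel spans an exon boundary in ", gene$gene_id)
  i <- overlaps
  if (g1 < ex$start[i] || g2 > ex$end[i])
    stop("unsupported: InDel spans an exon/intron boundary in ", gene$gene_id)
  widths <- ex$end - ex$start + 1
  if (gene$strand == "+") {
    before <- if (i > 1) sum(widths[seq_len(i - 1)]) else 0
    as.integer(before + (g1 - ex$start[i] + 1))
  } else {
    # transcript order is descending genomic; first transcript base of the
    # allele is its genomic last base g2
    after <- if (i < nrow(ex)) sum(widths[(i + 1):nrow(ex)]) else 0
    as.integer(after + (ex$end[i] - g2 + 1))
  }
}

#' Apply an InDel to a spliced CDS
#'
#' Replaces the transcript-oriented reference allele at `cds_pos` with the
#' alternate allele. Alleles follow the VCF anchored convention (REF and
#' ALT share a leading anchor base, kept once); the function verifies the
#' reference allele against the transcript before mutating.
#'
#' @param cds Spliced CDS string.
#' @param cds_pos 1-based offset of the allele's first base.
#' @param ref Reference allele (transcript orientation).
#' @param alt Alternate allele (transcript orientation).
#' @return The mutant CDS string.
#' @export
apply_indel <- function(cds, cds_pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  found <- substr(cds, cds_pos, cds_pos + nchar(ref) - 1)
  if (found != ref)
    stop(sprintf("reference mismatch at CDS position %d: transcript has '%s' but REF is '%s'",
                 cds_pos, found, ref))
  paste0(substr(cds, 1, cds_pos - 1), alt,
         substr(cds, cds_pos + nchar(ref), nchar(cds)))
}

#' Translate a coding sequence
#'
#' Standard-table translation from position 1, stopping at (and excluding)
#' the first stop codon; a trailing partial codon is ignored. When no stop
#' codon is reached the protein runs to the end of the sequence and a
#' `stop_lost` attribute is attached.
#'
#' @param cds Nucleotide string (A/C/G/T).
#' @return Protein string; attribute `stop_lost` is `TRUE` when
#'   translation ran off the end without a stop.
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) < 3) stop("sequence shorter than one codon")
  if (!grepl("^[ACGT]*$", cds)) stop("non-ACGT character in sequence")
  n_codon <- nchar(cds) %/% 3
  starts <- 3 * (seq_len(n_codon) - 1) + 1
  codons <- substring(cds, starts, starts + 2)
  aas <- unname(Biostrings::GENETIC_CODE[codons])
  stop_at <- which(aas == "*")
  if (length(stop_at)) {
    prot <- paste(aas[seq_len(stop_at[1] - 1)], collapse = "")
    attr(prot, "stop_lost") <- FALSE
  } else {
    prot <- paste(aas, collapse = "")
    attr(prot, "stop_lost") <- TRUE
  }
  prot
}

#' Classify the protein-level consequence of an InDel
#'
#' Builds the reference and mutant proteins for a variant overlapping a
#' gene's CDS and classifies the consequence: `frameshift` iff the allele
#' length difference is not a multiple of 3 (the frame rule), otherwise
#' `stop_gained` / `stop_lost` / `inframe_deletion` / `inframe_insertion` /
#' `synonymous_boundary` by the stop and length rules; variants outside the
#' CDS are `noncoding`. The truncation fraction is
#' `1 - len(alt protein) / len(ref protein)` on stop-free lengths.
#'
#' @param gene A `gene_model`.
#' @param chrom,pos,ref,alt The variant (plus-strand genomic convention,
#'   VCF anchored alleles).
#' @param domains Optional data frame of protein domains with columns
#'   `start`, `end` (1-based residues) and `label`; an optional `protein`
#'   column restricts rows to `gene$gene_id`.
#' @param variant_id Optional identifier (defaults to `chrom_pos`).
#'
#' @return An object of class `consequence_call`: fields `variant_id`,
#'   `gene_id`, `consequence_class`, `ref_protein`, `alt_protein`,
#'   `truncation_fraction`, `lost_domains` (data frame label/status),
#'   `deleted_sequence` (reference bases removed, verbatim), `notes`.
#' @export
classify_indel <- function(gene, chrom, pos, ref, alt, domains = NULL,
                           variant_id = NULL) {
  if (chrom != gene$chrom)
    stop("variant chromosome ", chrom, " does not match gene chromosome ",
         gene$chrom)
  if (is.null(variant_id)) variant_id <- paste0(chrom, "_", pos)
  ref <- toupper(ref); alt <- toupper(alt)
  ref_prot <- translate_cds(gene$cds_sequence)
  cds_pos <- map_to_cds(gene, pos, nchar(ref))
  lendiff <- nchar(alt) - nchar(ref)
  deleted <- if (lendiff < 0) substr(ref, nchar(alt) + 1, nchar(ref)) else ""

  if (is.na(cds_pos)) {
    return(structure(list(
      variant_id = variant_id, gene_id = gene$gene_id,
      consequence_class = "noncoding",
      ref_protein = as.character(ref_prot), alt_protein = as.character(ref_prot),
      truncation_fraction = 0,
      lost_domains = data.frame(label = character(0), status = character(0)),
      deleted_sequence = deleted, notes = character(0)
    ), class = "consequence_call"))
  }

  if (gene$strand == "-") {
    ref_t <- revcomp(ref); alt_t <- revcomp(alt)
  } else {
    ref_t <- ref; alt_t <- alt
  }
  mutant <- apply_indel(gene$cds_sequence, cds_pos, ref_t, alt_t)
  alt_prot <- translate_cds(mutant)

  notes <- character(0)
  if (isTRUE(attr(alt_prot, "stop_lost"))) notes <- c(notes, "no in-frame stop reached")
  ref_len <- nchar(ref_prot); alt_len <- nchar(alt_prot)

  if (lendiff %% 3 != 0) {
    cls <- "frameshift"
  } else if (isTRUE(attr(alt_prot, "stop_lost"))) {
    cls <- "stop_lost"
  } else if (alt_len < ref_len + lendiff / 3) {
    cls <- "stop_gained"
  } else if (lendiff < 0) {
    cls <- "inframe_deletion"
  } else if (lendiff > 0) {
    cls <- "inframe_insertion"
  } else {
    cls <- "synonymous_boundary"
  }

  lost <- data.frame(label = character(0), status = character(0))
  if (!is.null(domains) && nrow(domains)) {
    d <- domains
    if ("protein" %in% names(d)) d <- d[d$protein == gene$gene_id, , drop = FALSE]
    if (nrow(d)) {
      status <- ifelse(d$start > alt_len, "lost",
                       ifelse(d$end > alt_len, "partial", "retained"))
      keep <- status != "retained"
      lost <- data.frame(label = d$label[keep], status = status[keep])
    }
  }

  structure(list(
    variant_id = variant_id, gene_id = gene$gene_id,
    consequence_class = cls,
    ref_protein = as.character(ref_prot), alt_protein = as.character(alt_prot),
    truncation_fraction = 1 - alt_len / ref_len,
    lost_domains = lost, deleted_sequence = deleted, notes = notes
  ), class = "consequence_call")
}

#' @export
print.consequence_call <- function(x, ...) {
  cat(sprintf("%s in %s: %s (truncation %.2f%s)\n", x$variant_id, x$gene_id,
              x$consequence_class, x$truncation_fraction,
              if (nrow(x$lost_domains))
                paste0("; domains ", paste(x$lost_domains$label, collapse = ","))
              else ""))
  invisible(x)
}

#' Consequence calls as a table
#'
#' @param calls List of `consequence_call`.
#' @return Data frame with one row per call (`variant_id`, `gene`, `class`,
#'   `ref_len`, `alt_len`, `truncation_fraction`, `lost_domains`).
#' @export
consequence_table <- function(calls) {
  do.call(rbind, lapply(calls, function(x) data.frame(
    variant_id = x$variant_id, gene = x$gene_id, class = x$consequence_class,
    ref_len = nchar(x$ref_protein), alt_len = nchar(x$alt_protein),
    truncation_fraction = x$truncation_fraction,
    lost_domains = paste(x$lost_domains$label, collapse = ";"),
    stringsAsFactors = FALSE)))
}
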