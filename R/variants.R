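#' Variant set container
#'
#' Holds a block of biallelic variant records (multi-allelic sites are
#' decomposed, one record per alternate allele) with their per-accession
#' alternate-allele dosages. Inputs are assumed genotype-imputed: a missing
#' genotype is a contract violation, not something to patch here.
#'
#' @param meta Data frame with columns `chrom`, `pos` (1-based), `id`,
#'   `ref`, `alt`.
#' @param dosage Numeric matrix, variants x accessions, entries in [0, 2].
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(meta, dosage) {
  stopifnot(is.data.frame(meta), nrow(meta) == nrow(dosage))
  need <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need %in% names(meta))) stop("meta must have columns ", paste(need, collapse = ", "))
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (anyNA(dosage)) stop("missing dosages are not allowed: input must be imputed")
  structure(list(meta = meta, dosage = dosage,
                 accession_ids = colnames(dosage)),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d variants x %d accessions (%d chromosome%s)\n",
              nrow(x$meta), ncol(x$dosage), length(unique(x$meta$chrom)),
              if (length(unique(x$meta$chrom)) == 1) "" else "s"))
  invisible(x)
}

#' @export
length.variant_set <- function(x) nrow(x$meta)

#' Subset a variant set by index
#' @param vs A `variant_set`.
#' @param idx Integer or logical index over variants.
#' @return A `variant_set`.
#' @export
subset_variants <- function(vs, idx) {
  variant_set(vs$meta[idx, , drop = FALSE], vs$dosage[idx, , drop = FALSE])
}

parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4) stop("malformed region (expected 'chrom:start-end'): ", region)
  list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

count_allele <- function(gt, allele) {
  # gt like "0/1" or "0|1"; counts occurrences of the given allele index
  parts <- strsplit(gt, "[/|]")
  vapply(parts, function(p) sum(p == as.character(allele)), numeric(1))
}

#' Read variants from a VCF file
#'
#' Parses a VCF 4.x file (plain or bgzipped) into a [variant_set()].
#' Genotype dosage is the per-sample count of the record's alternate allele
#' (0/0 -> 0, 0/1 -> 1, 1/1 -> 2); multi-allelic records are decomposed into
#' one record per alternate allele, each counting only that allele. Variant
#' ids follow the `chrom_pos` convention.
#'
#' @param vcf_path Path to the VCF.
#' @param region Optional `"chrom:start-end"` string, 1-based inclusive.
#'
#' @return A `variant_set`.
#' @export
read_variants <- function(vcf_path, region = NULL) {
  if (!file.exists(vcf_path)) stop("VCF file not found: ", vcf_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(variant_set(data.frame(chrom = character(0), pos = integer(0),
                                  id = character(0), ref = character(0),
                                  alt = character(0)),
                       matrix(0, 0, ncol(v@gt) - 1L,
                              dimnames = list(NULL, colnames(v@gt)[-1L]))))
  }
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos))
    stop("malformed VCF: non-numeric POS at record ", which(is.na(pos))[1])
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  samples <- colnames(v@gt)[-1L]
  colnames(gt) <- samples
  if (anyNA(gt) || any(grepl("\\.", gt)))
    stop("missing genotype found: input VCF must be genotype-imputed (record ",
         which(anyNA(gt) | apply(gt, 1, function(r) any(grepl("\\.", r))))[1], ")")

  meta_rows <- list(); dose_rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ref <- toupper(fix$REF[i])
    for (k in seq_along(alts)) {
      alt <- toupper(alts[k])
      if (!grepl("^[ACGT]+$", ref) || !grepl("^[ACGT]+$", alt))
        stop("unsupported allele at record ", i, ": REF=", ref, " ALT=", alt)
      meta_rows[[length(meta_rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = pos[i],
        id = paste0(fix$CHROM[i], "_", pos[i]),
        ref = ref, alt = alt, stringsAsFactors = FALSE)
      dose_rows[[length(dose_rows) + 1L]] <- count_allele(gt[i, ], k)
    }
  }
  meta <- do.call(rbind, meta_rows)
  dosage <- do.call(rbind, dose_rows)
  colnames(dosage) <- samples
  vs <- variant_set(meta, dosage)
  if (!is.null(region)) {
    r <- parse_region(region)
    keep <- vs$meta$chrom == r$chrom & vs$meta$pos >= r$start & vs$meta$pos <= r$end
    vs <- subset_variants(vs, keep)
  }
  vs
}

#' Is each variant an insertion/deletion?
#'
#' A variant is an InDel iff its REF and ALT allele lengths differ;
#' equal-length multi-base substitutions (MNPs) are not InDels.
#'
#' @param vs A `variant_set`.
#' @return Logical vector, one entry per variant.
#' @export
is_indel <- function(vs) {
  nchar(vs$meta$ref) != nchar(vs$meta$alt)
}

#' Minor-allele-frequency filter
#'
#' The alternate-allele frequency of a variant is `f = mean(dosage)/2`;
#' variants are retained iff `min(f, 1 - f) >= min_maf`.
#'
#' @param vs A `variant_set`.
#' @param min_maf Minimum minor-allele frequency (default 0.1).
#' @return A filtered `variant_set`.
#' @export
maf_filter <- function(vs, min_maf = 0.1) {
  f <- rowMeans(vs$dosage) / 2
  maf <- pmin(f, 1 - f)
  subset_variants(vs, maf >= min_maf)
}

#' Select variants in a gene window
#'
#' Keeps variants on the gene's chromosome with position inside
#' `[start - flank_bp, end + flank_bp]` (window clipped at 1).
#'
#' @param vs A `variant_set`.
#' @param chrom Gene chromosome.
#' @param start,end 1-based inclusive gene interval.
#' @param flank_bp Flank size in bp on each side (default 100000).
#' @return A filtered `variant_set`.
#' @export
select_window <- function(vs, chrom, start, end, flank_bp = 100000) {
  stopifnot(flank_bp >= 0, start <= end)
  lo <- max(1, start - flank_bp)
  hi <- end + flank_bp
  subset_variants(vs, vs$meta$chrom == chrom & vs$meta$pos >= lo & vs$meta$pos <= hi)
}

#' Accessions x variants dosage matrix
#'
#' @param vs A `variant_set`.
#' @return N x M numeric matrix (accessions in rows), suitable for
#'   [compute_kinship()] and [loco_pcs()].
#' @export
dosage_matrix <- function(vs) {
  G <- t(vs$dosage)
  colnames(G) <- vs$meta$id
  G
}
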