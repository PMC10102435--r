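#' Construct a trait matrix
#'
#' A `trait_matrix` holds an accessions x traits phenotype matrix together
#' with its observation mask and, once [standardize_traits()] has been
#' applied, the per-trait centering/scaling record needed to map imputed
#' values back to the original units. Missing values are stored as `NA` and
#' are never read by downstream numerics.
#'
#' @param values Numeric matrix, accessions in rows and traits in columns.
#'   `NA` marks a missing observation.
#' @param accession_ids Character vector of row identifiers. Defaults to
#'   rownames of `values` or `acc1..accN`.
#' @param trait_names Character vector of column identifiers. Defaults to
#'   colnames of `values` or `trait1..traitP`.
#' @param standardization Optional data frame with columns `trait`, `mean`,
#'   `sd` recording how each trait was standardized.
#'
#' @return An object of class `trait_matrix` with fields `values`, `mask`
#'   (TRUE = observed), `accession_ids`, `trait_names`, `standardization`.
#' @export
trait_matrix <- function(values, accession_ids = NULL, trait_names = NULL,
                         standardization = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(accession_ids)) {
    accession_ids <- rownames(values)
    if (is.null(accession_ids)) accession_ids <- paste0("acc", seq_len(nrow(values)))
  }
  if (is.null(trait_names)) {
    trait_names <- colnames(values)
    if (is.null(trait_names)) trait_names <- paste0("trait", seq_len(ncol(values)))
  }
  stopifnot(length(accession_ids) == nrow(values),
            length(trait_names) == ncol(values))
  if (anyDuplicated(trait_names)) stop("trait names must be unique")
  dimnames(values) <- list(accession_ids, trait_names)
  structure(list(
    values = values,
    mask = !is.na(values),
    accession_ids = as.character(accession_ids),
    trait_names = as.character(trait_names),
    standardization = standardization
  ), class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  miss <- 1 - mean(x$mask)
  cat(sprintf("trait_matrix: %d accessions x %d traits (%.1f%% missing%s)\n",
              nrow(x$values), ncol(x$values), 100 * miss,
              if (!is.null(x$standardization)) ", standardized" else ""))
  invisible(x)
}

#' @export
dim.trait_matrix <- function(x) dim(x$values)

as_trait_matrix <- function(Y) {
  if (inherits(Y, "trait_matrix")) Y else trait_matrix(Y)
}

subset_traits <- function(Y, keep) {
  trait_matrix(Y$values[, keep, drop = FALSE],
               accession_ids = Y$accession_ids,
               trait_names = Y$trait_names[keep],
               standardization = Y$standardization)
}

#' Drop traits with excessive missingness
#'
#' Retains a trait if and only if its fraction of missing observations is
#' less than or equal to `max_missing_frac`; strictly greater is removed.
#' With the default threshold of 0.30 this is the phenome filter used before
#' imputation.
#'
#' @param Y_raw A `trait_matrix`, numeric matrix, or data frame (numeric
#'   columns; see [read_phenotypes()] for file input).
#' @param max_missing_frac Maximum tolerated missing fraction per trait
#'   (default 0.30).
#'
#' @return A `trait_matrix` with the surviving columns. The attached
#'   `report` attribute lists `dropped` trait names, their missing
#'   fractions, and `residual_missing_frac`, the overall missing fraction
#'   among retained traits.
#' @export
filter_traits <- function(Y_raw, max_missing_frac = 0.30) {
  Y <- as_trait_matrix(Y_raw)
  if (nrow(Y$values) < 1L || ncol(Y$values) < 1L)
    stop("phenotype table must have at least one accession and one trait")
  miss_frac <- colMeans(!Y$mask)
  keep <- miss_frac <= max_missing_frac
  if (!any(keep)) stop("no traits survive filter: all exceed max_missing_frac = ",
                       max_missing_frac)
  out <- subset_traits(Y, which(keep))
  attr(out, "report") <- list(
    dropped = Y$trait_names[!keep],
    dropped_missing_frac = unname(miss_frac[!keep]),
    residual_missing_frac = mean(!out$mask)
  )
  out
}

#' Drop near-duplicate traits by pairwise correlation
#'
#' Greedy scan in column order: each trait is compared against all traits
#' already retained; if its absolute Pearson correlation (pairwise-complete
#' observations) with any of them exceeds `r_threshold`, the later trait is
#' dropped. Deterministic for a fixed column order. Pairs with fewer than
#' three overlapping observations contribute r = 0 (with a warning).
#'
#' @param Y A `trait_matrix` (or coercible).
#' @param r_threshold Correlation threshold above which the later trait is
#'   removed (default 0.95).
#'
#' @return A `trait_matrix`; attribute `report` holds one row per dropped
#'   trait with the retained partner and the offending correlation.
#' @export
drop_correlated <- function(Y, r_threshold = 0.95) {
  Y <- as_trait_matrix(Y)
  p <- ncol(Y$values)
  keep <- integer(0)
  drop_rows <- list()
  few_obs <- FALSE
  for (j in seq_len(p)) {
    r_with <- NA_character_; r_val <- NA_real_
    clash <- FALSE
    for (i in keep) {
      ok <- Y$mask[, i] & Y$mask[, j]
      if (sum(ok) < 3L) { few_obs <- TRUE; next }  # r treated as 0
      r <- suppressWarnings(stats::cor(Y$values[ok, i], Y$values[ok, j]))
      if (is.na(r)) next
      if (abs(r) > r_threshold) { clash <- TRUE; r_with <- Y$trait_names[i]; r_val <- r; break }
    }
    if (clash) {
      drop_rows[[length(drop_rows) + 1L]] <-
        data.frame(dropped = Y$trait_names[j], kept = r_with, r = r_val)
    } else keep <- c(keep, j)
  }
  if (few_obs) warning("some trait pairs had < 3 overlapping observations; their r was treated as 0")
  out <- subset_traits(Y, keep)
  attr(out, "report") <- if (length(drop_rows)) do.call(rbind, drop_rows) else
    data.frame(dropped = character(0), kept = character(0), r = numeric(0))
  out
}

#' Standardize traits to zero mean and unit variance
#'
#' Centers and scales every trait over its observed entries (sd with the
#' n-1 denominator). The per-trait (mean, sd) pair is stored in the
#' `standardization` field for back-transformation of imputed values.
#'
#' @param Y A `trait_matrix` (or coercible).
#'
#' @return A standardized `trait_matrix`.
#' @export
standardize_traits <- function(Y) {
  Y <- as_trait_matrix(Y)
  mu <- colMeans(Y$values, na.rm = TRUE)
  sd_ <- apply(Y$values, 2, stats::sd, na.rm = TRUE)
  nobs <- colSums(Y$mask)
  bad <- which(nobs < 2L | !is.finite(sd_) | sd_ == 0)
  if (length(bad))
    stop("constant or near-empty trait(s) cannot be standardized: ",
         paste(Y$trait_names[bad], collapse = ", "))
  vals <- sweep(sweep(Y$values, 2, mu, "-"), 2, sd_, "/")
  trait_matrix(vals, Y$accession_ids, Y$trait_names,
               standardization = data.frame(trait = Y$trait_names,
                                            mean = unname(mu), sd = unname(sd_)))
}

#' Read a phenotype table
#'
#' Expects a delimited text file with accession identifiers in the first
#' column and one named trait per remaining column; empty cells or "NA" are
#' missing.
#'
#' @param path Path to a TSV/CSV file.
#' @param sep Field separator; `NULL` (default) picks "," for `.csv`,
#'   otherwise tab.
#' @return A `trait_matrix`.
#' @export
read_phenotypes <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, na.strings = c("", "NA"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  trait_matrix(vals, accession_ids = ids, trait_names = colnames(df)[-1L])
}

#' Write a phenotype table (with optional standardization sidecar)
#'
#' Writes the trait matrix in the same layout [read_phenotypes()] reads,
#' plus, when present, a JSON sidecar (`<path>.json`) recording the
#' per-trait (mean, sd) standardization and any filtering report.
#'
#' @param Y A `trait_matrix`.
#' @param path Output TSV path.
#' @param report Optional list serialized into the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(Y, path, report = NULL) {
  df <- data.frame(accession = Y$accession_ids, Y$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(standardization = Y$standardization, report = report)
  if (!is.null(Y$standardization) || !is.null(report))
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  invisible(path)
}
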