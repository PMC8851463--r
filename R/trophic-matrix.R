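#' Gene-family expression matrix with sample metadata
#'
#' The core container of the package: a non-negative numeric matrix of
#' gene-family (Pfam) abundances with features as rows and samples as
#' columns, a units flag, and a tibble of per-sample metadata. Under the
#' `"tpm"` units flag every sample column must sum to one million
#' (transcripts per million) within a relative tolerance of 1e-6, and
#' all-zero columns are disallowed.
#'
#' @param values Numeric matrix, features x samples, with unique rownames
#'   (gene-family identifiers) and unique colnames (sample identifiers).
#'   All entries must be finite and non-negative.
#' @param units One of `"raw"`, `"tpm"`, `"log"`.
#' @param sample_meta Optional tibble with a `sample_id` column covering all
#'   samples; further columns (species, label, group, size_fraction,
#'   latitude, local_time, station, replicate, ...) are carried along.
#' @return An object of class `trophic_matrix`.
#' @export
trophic_matrix <- function(values, units = c("raw", "tpm", "log"),
                           sample_meta = NULL) {
  units <- match.arg(units)
  abort_if_not(is.matrix(values) && is.numeric(values),
               "`values` must be a numeric matrix")
  abort_if_not(nrow(values) > 0, "expression matrix must have features")
  if (is.null(colnames(values))) colnames(values) <- character(ncol(values))
  abort_if_not(!is.null(rownames(values)),
               "`values` must carry feature rownames")
  dup_f <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_f) > 0) {
    rlang::abort(sprintf("duplicate feature id(s): %s",
                         paste(unique(dup_f), collapse = ", ")))
  }
  dup_s <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_s) > 0) {
    rlang::abort(sprintf("duplicate sample id(s): %s",
                         paste(unique(dup_s), collapse = ", ")))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    idx <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    rlang::abort(sprintf("non-finite value at feature '%s', sample '%s'",
                         rownames(values)[idx[1]], colnames(values)[idx[2]]))
  }
  if (units != "log" && any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1, ]
    rlang::abort(sprintf("negative value at feature '%s', sample '%s'",
                         rownames(values)[idx[1]], colnames(values)[idx[2]]))
  }
  if (units == "tpm") {
    sums <- colSums(values)
    off <- abs(sums - 1e6) > 1e-6 * 1e6
    if (any(off)) {
      rlang::abort(sprintf(
        "under units = 'tpm' every column must sum to 1e6; sample '%s' sums to %g",
        colnames(values)[which(off)[1]], sums[which(off)[1]]
      ))
    }
  }
  if (is.null(sample_meta)) {
    sample_meta <- tibble::tibble(sample_id = colnames(values))
  } else {
    sample_meta <- tibble::as_tibble(sample_meta)
    abort_if_not("sample_id" %in% names(sample_meta),
                 "`sample_meta` must have a sample_id column")
    missing <- setdiff(colnames(values), sample_meta$sample_id)
    abort_if_not(length(missing) == 0,
                 sprintf("sample(s) missing from metadata: %s",
                         paste(missing, collapse = ", ")))
    sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), ]
  }
  structure(
    list(values = values, units = units, sample_meta = sample_meta),
    class = "trophic_matrix"
  )
}

#' @export
print.trophic_matrix <- function(x, ...) {
  cat(sprintf("<trophic_matrix> %d features x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$units))
  cat("metadata columns:", paste(names(x$sample_meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.trophic_matrix <- function(x) dim(x$values)

#' Feature and sample identifiers of an expression matrix
#' @param m A [trophic_matrix].
#' @return Character vector of identifiers.
#' @export
feature_ids <- function(m) rownames(m$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(m) colnames(m$values)

#' Read a gene-family expression table
#'
#' Reads a tab-separated table with gene-family identifiers in the first
#' column (header `feature_id`) and one column per sample, as produced by
#' [write_expression_matrix()] or by upstream annotation/quantification
#' pipelines.
#'
#' @param path Path to the TSV file.
#' @param units Units flag for the stored values (see [trophic_matrix()]).
#' @param sample_meta Optional sample metadata tibble or path to a metadata
#'   TSV (see [read_sample_metadata()]).
#' @return A [trophic_matrix] with row and column order as in the file.
#' @export
read_expression_matrix <- function(path, units = c("raw", "tpm", "log"),
                                   sample_meta = NULL) {
  units <- match.arg(units)
  abort_if_not(file.exists(path), sprintf("file not found: %s", path))
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  abort_if_not(length(header) >= 2, "file has no sample columns")
  samples <- header[-1]
  dup <- unique(samples[duplicated(samples)])
  if (length(dup) > 0) {
    rlang::abort(sprintf("duplicate sample id(s) in header: %s",
                         paste(dup, collapse = ", ")))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  abort_if_not(nrow(df) > 0, "empty expression matrix")
  features <- df[[1]]
  vals <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df)))
  )
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(features, samples))
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    rlang::abort(sprintf("non-numeric cell at feature '%s', sample '%s'",
                         features[idx[1]], samples[idx[2]]))
  }
  if (is.character(sample_meta)) sample_meta <- read_sample_metadata(sample_meta)
  trophic_matrix(vals, units = units, sample_meta = sample_meta)
}

#' Write a gene-family expression table
#'
#' @param m A [trophic_matrix].
#' @param path Output TSV path. Floats are written with round-trippable
#'   precision so write-then-read is bit-identical.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  df <- tibble::as_tibble(m$values, rownames = "feature_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expects a TSV with at least `sample_id`, `species`, and `label` columns
#' (label may be `"unlabeled"`); optional columns such as `group`,
#' `size_fraction`, `latitude`, `local_time`, `station`, `replicate`,
#' `known_mixotroph`, `light`, `bacteria_present`, `literature_label` are
#' kept as-is.
#'
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path) {
  abort_if_not(file.exists(path), sprintf("file not found: %s", path))
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  abort_if_not("sample_id" %in% names(meta),
               "metadata must have a sample_id column")
  meta
}

#' Rescale each sample column to transcripts per million
#'
#' Rescales every sample column of a non-negative abundance matrix so it
#' sums to 1e6 (TPM). Zeros are preserved and the operation is idempotent.
#'
#' @param m A [trophic_matrix] with non-negative values and no all-zero
#'   sample column.
#' @return A [trophic_matrix] with `units = "tpm"`.
#' @export
tpm_normalize <- function(m) {
  stopifnot(inherits(m, "trophic_matrix"))
  sums <- colSums(m$values)
  zero <- sums <= 0
  if (any(zero)) {
    rlang::abort(sprintf("all-zero sample column(s): %s",
                         paste(colnames(m$values)[zero], collapse = ", ")))
  }
  vals <- sweep(m$values, 2, sums, "/") * 1e6
  trophic_matrix(vals, units = "tpm", sample_meta = m$sample_meta)
}

#' Element-wise log10 transform with pseudocount
#'
#' @param m A [trophic_matrix] with non-negative values.
#' @param pseudocount Positive offset added before taking log10 (default 1,
#'   so zeros map to zero).
#' @return A [trophic_matrix] with `units = "log"`. Within-column rank
#'   order of values is preserved.
#' @export
log_transform <- function(m, pseudocount = 1) {
  stopifnot(inherits(m, "trophic_matrix"))
  abort_if_not(is.numeric(pseudocount) && length(pseudocount) == 1 &&
                 pseudocount > 0, "`pseudocount` must be a positive number")
  trophic_matrix(log10(m$values + pseudocount), units = "log",
                 sample_meta = m$sample_meta)
}

#' Bin completeness: nonzero gene families in a sample
#'
#' Counts the strictly positive entries in one sample's column. Used as the
#' completeness estimate for environmental bin profiles (a profile passes
#' the default deployment filter when this count is at least 800).
#'
#' @param m A [trophic_matrix].
#' @param sample A sample identifier present in `m`.
#' @return Non-negative integer count.
#' @export
nonzero_feature_count <- function(m, sample) {
  stopifnot(inherits(m, "trophic_matrix"))
  abort_if_not(sample %in% colnames(m$values),
               sprintf("unknown sample id: %s", sample))
  sum(m$values[, sample] > 0)
}

#' Reduce a matrix to a feature set, zero-filling absent families
#'
#' Returns a matrix with exactly the feature set's members, in the set's
#' order. Members absent from `m` (common for environmental profiles, where
#' not every selected family is detected) are included as all-zero rows and
#' reported via the `"zero_filled"` attribute.
#'
#' @param m A [trophic_matrix].
#' @param fs A [feature_set] or character vector of feature identifiers
#'   (nonempty).
#' @return A [trophic_matrix]; `attr(, "zero_filled")` lists the members
#'   that were absent from `m`.
#' @export
subset_features <- function(m, fs) {
  stopifnot(inherits(m, "trophic_matrix"))
  members <- if (inherits(fs, "feature_set")) fs$members else as.character(fs)
  abort_if_not(length(members) > 0, "feature set must be nonempty")
  present <- intersect(members, rownames(m$values))
  absent <- setdiff(members, rownames(m$values))
  vals <- matrix(0, nrow = length(members), ncol = ncol(m$values),
                 dimnames = list(members, colnames(m$values)))
  vals[present, ] <- m$values[present, , drop = FALSE]
  # TPM column sums survive only if no feature of m was dropped
  units <- m$units
  if (units == "tpm" && !setequal(members, rownames(m$values))) units <- "raw"
  out <- trophic_matrix(vals, units = units, sample_meta = m$sample_meta)
  attr(out, "zero_filled") <- absent
  out
}
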