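#' @keywords internal
"_PACKAGE"

# Subset labels a manifest may carry: primary tumor, solid normal,
# peripheral blood, metastasis, immune cells.
SUBSET_LEVELS <- c("PT", "SN", "PB", "Met", "Imm")

#' Read a beta-value matrix
#'
#' Reads a tab-separated probes-by-samples matrix of methylation beta
#' values (fraction methylated, in \[0, 1\]). The layout follows the
#' UCSC Xena / GEO series-matrix convention: a header row of sample
#' identifiers and a first column of CpG probe identifiers.
#'
#' @param path Path to a TSV file.
#' @param missing_tokens Character vector of tokens parsed as missing.
#' @param transpose If `TRUE`, the file holds samples in rows and is
#'   transposed after reading. Defaults to `FALSE` (probes in rows).
#' @return A numeric matrix, probes in rows, samples in columns, with
#'   `NA` for missing values.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("probe\ts1\ts2", "cg01\t0.1\tNA", "cg02\t0.9\t0.5"), tf)
#' read_beta_matrix(tf)
#' @export
read_beta_matrix <- function(path, missing_tokens = c("NA", ""),
                             transpose = FALSE) {
  mat <- read_numeric_matrix(path, missing_tokens, what = "beta matrix")
  if (transpose) mat <- t(mat)
  bad <- which(!is.na(mat) & (mat < 0 | mat > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "beta value %g outside [0, 1] at probe '%s', sample '%s'",
      mat[bad[1, 1], bad[1, 2]],
      rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]]
    ), call. = FALSE)
  }
  mat
}

#' Read an expression matrix
#'
#' Same TSV layout as [read_beta_matrix()] (genes in rows, samples in
#' columns) but values are unconstrained continuous expression measures,
#' assumed already normalized/log-scaled.
#'
#' @inheritParams read_beta_matrix
#' @return A numeric matrix, genes in rows, samples in columns.
#' @export
read_expression_matrix <- function(path, missing_tokens = c("NA", ""),
                                   transpose = FALSE) {
  mat <- read_numeric_matrix(path, missing_tokens, what = "expression matrix")
  if (transpose) mat <- t(mat)
  mat
}

# Shared TSV reader for id-by-sample numeric matrices. Hand-rolled line
# handling so malformed rows are reported with their line number instead
# of being silently recycled.
read_numeric_matrix <- function(path, missing_tokens, what) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1) {
    stop(sprintf("parse error in %s: file '%s' is empty", what, path),
         call. = FALSE)
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  if (length(sample_ids) == 0) {
    stop(sprintf("parse error in %s: header has no sample columns", what),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop(sprintf("duplicate sample ids: %s",
                 paste(unique(sample_ids[duplicated(sample_ids)]),
                       collapse = ", ")), call. = FALSE)
  }
  body <- lines[-1]
  if (length(body) == 0) {
    stop(sprintf("parse error in %s: no data rows", what), call. = FALSE)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  lens <- lengths(fields)
  bad <- which(lens != length(header))
  if (length(bad) > 0) {
    stop(sprintf(
      "parse error in %s at line %d: expected %d fields, found %d",
      what, bad[1] + 1L, length(header), lens[bad[1]]
    ), call. = FALSE)
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate row ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  vals <- vapply(fields, function(f) {
    v <- f[-1]
    v[v %in% missing_tokens] <- NA_character_
    suppressWarnings(as.numeric(v))
  }, numeric(length(sample_ids)))
  # vapply gives samples in rows; transpose back to probes-in-rows
  mat <- t(matrix(vals, nrow = length(sample_ids),
                  dimnames = list(sample_ids, ids)))
  raw <- t(vapply(fields, function(f) f[-1], character(length(sample_ids))))
  not_numeric <- is.na(mat) & !(raw %in% missing_tokens)
  if (any(not_numeric)) {
    idx <- which(not_numeric, arr.ind = TRUE)[1, ]
    stop(sprintf("parse error in %s: non-numeric value '%s' at row '%s'",
                 what, raw[idx[1], idx[2]], ids[idx[1]]), call. = FALSE)
  }
  mat
}

#' Write a beta or expression matrix as TSV
#'
#' Inverse of [read_beta_matrix()] / [read_expression_matrix()]: writes
#' the matrix with full precision so a read round-trip is bit-exact for
#' finite entries and preserves missingness.
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_col Name for the first (id) column in the header.
#' @export
write_beta_matrix <- function(mat, path, id_col = "probe_id") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  header <- paste(c(id_col, colnames(mat)), collapse = "\t")
  rows <- vapply(seq_len(nrow(mat)), function(i) {
    v <- format_full(mat[i, ])
    paste(c(rownames(mat)[i], v), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

# format doubles so that as.numeric() recovers them exactly
format_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Read a sample manifest
#'
#' A manifest maps each sample to its cohort and subset label, with
#' optional clinical covariates (stage, subtype, age, race, ethnicity).
#' Required columns: `sample_id`, `cohort`, `subset`. Subset labels must
#' be one of PT, SN, PB, Met, Imm.
#'
#' @param path Path to a TSV file with a header row.
#' @return A data.frame with one row per sample.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = c("NA", ""))
  validate_manifest(df)
}

#' Validate a sample manifest data.frame
#'
#' @param df A data.frame with columns `sample_id`, `cohort`, `subset`
#'   and optional covariates.
#' @return The validated data.frame (invisibly unchanged).
#' @export
validate_manifest <- function(df) {
  required <- c("sample_id", "cohort", "subset")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("manifest is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop(sprintf("duplicate sample_id in manifest: %s",
                 paste(unique(df$sample_id[duplicated(df$sample_id)]),
                       collapse = ", ")), call. = FALSE)
  }
  unknown <- setdiff(unique(df$subset), SUBSET_LEVELS)
  if (length(unknown) > 0) {
    stop(sprintf("unknown subset label(s): %s (allowed: %s)",
                 paste(unknown, collapse = ", "),
                 paste(SUBSET_LEVELS, collapse = ", ")), call. = FALSE)
  }
  if ("age" %in% names(df)) df$age <- as.numeric(df$age)
  df
}

#' Write a sample manifest as TSV
#'
#' @param df Manifest data.frame.
#' @param path Output path.
#' @export
write_manifest <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line; tab-separated fields are the
#' set name, a description, then the member genes. Duplicate members
#' within a set are de-duplicated; duplicate set names are an error.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of gene ids, with a
#'   `description` attribute (named character vector) on the list.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  lens <- lengths(fields)
  bad <- which(lens < 3)
  if (length(bad) > 0) {
    stop(sprintf("GMT parse error at line %d: fewer than 3 fields", bad[1]),
         call. = FALSE)
  }
  names_ <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names_)) {
    stop(sprintf("duplicate gene-set name(s): %s",
                 paste(unique(names_[duplicated(names_)]), collapse = ", ")),
         call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- names_
  empty <- names_[lengths(sets) == 0]
  if (length(empty) > 0) {
    stop(sprintf("empty gene set(s) after parsing: %s",
                 paste(empty, collapse = ", ")), call. = FALSE)
  }
  attr(sets, "description") <- stats::setNames(
    vapply(fields, `[[`, character(1), 2L), names_)
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets Named list of character vectors of gene ids.
#' @param path Output path.
#' @param descriptions Optional named character vector of descriptions;
#'   defaults to the `description` attribute or `"na"`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions)) {
      descriptions[[nm]]
    } else "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
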