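## Standard-format I/O: count matrices (TSV and MatrixMarket), design
## tables, GMT gene-set collections, and the TSV writers shared by the
## pipeline. Dialect: tab-delimited, UTF-8, header row, '.' decimal.

#' Read a count matrix
#'
#' @param path For `format = "tsv"`: a tab-delimited file whose first
#'   column (`gene_id`) holds gene IDs and remaining columns one sample
#'   each. For `format = "mtx"`: a MatrixMarket file; `row_ids` and
#'   `col_ids` then name the sidecar ID files (one ID per line) and
#'   default to `genes.tsv` / `barcodes.tsv` next to the matrix.
#' @param format `"tsv"` or `"mtx"`.
#' @param orientation `"genes_by_cols"` if rows are genes (the default), or
#'   `"cols_by_genes"` to transpose on read so genes always end up in rows.
#' @param row_ids,col_ids Sidecar ID files (MTX only).
#' @return Integer matrix, genes in rows, with ID dimnames. Duplicate IDs,
#'   negative or non-integer entries are rejected.
#' @export
read_counts <- function(path, format = c("tsv", "mtx"),
                        orientation = c("genes_by_cols", "cols_by_genes"),
                        row_ids = NULL, col_ids = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "tsv") {
    df <- read_tsv(path)
    if (names(df)[1] != "gene_id")
      stopf("malformed header: first column must be 'gene_id', got '%s'",
            names(df)[1])
    ids <- df[[1]]
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- ids
  } else {
    base <- dirname(path)
    row_ids <- row_ids %||% file.path(base, "genes.tsv")
    col_ids <- col_ids %||% file.path(base, "barcodes.tsv")
    for (f in c(row_ids, col_ids))
      if (!file.exists(f)) stopf("missing MTX sidecar file: %s", f)
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(row_ids); cn <- readLines(col_ids)
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stopf("sidecar ID counts (%d, %d) do not match matrix dim (%d, %d)",
            length(rn), length(cn), nrow(m), ncol(m))
    dimnames(m) <- list(rn, cn)
  }
  if (orientation == "cols_by_genes") m <- t(m)
  dup <- rownames(m)[duplicated(rownames(m))]
  if (length(dup)) stopf("duplicate gene ID(s): %s",
                         paste(unique(dup), collapse = ", "))
  dup <- colnames(m)[duplicated(colnames(m))]
  if (length(dup)) stopf("duplicate sample/cell ID(s): %s",
                         paste(unique(dup), collapse = ", "))
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stopf("counts must be non-negative integers")
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix as TSV
#'
#' @param counts Gene x sample matrix with dimnames.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read and validate a sample design table
#'
#' @param path TSV with columns `sample_id`, `diet` (LFD or WD), `time`
#'   (1 or 40) and `sex` (F or M).
#' @return Validated data.frame; unknown factor levels and missing columns
#'   are rejected with informative errors.
#' @export
read_design <- function(path) {
  df <- read_tsv(path)
  validate_design(df)
}

validate_design <- function(df) {
  need <- c("sample_id", "diet", "time", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("design table missing column(s): %s",
                          paste(miss, collapse = ", "))
  check_levels <- function(x, allowed, what) {
    bad <- setdiff(unique(as.character(x)), as.character(allowed))
    if (length(bad))
      stopf("unknown %s level(s) %s; allowed: %s", what,
            paste(bad, collapse = ", "), paste(allowed, collapse = ", "))
  }
  check_levels(df$diet, c("LFD", "WD"), "diet")
  check_levels(df$time, c(1, 40), "time")
  check_levels(df$sex, c("F", "M"), "sex")
  if (anyDuplicated(df$sample_id))
    stopf("duplicate sample_id(s) in design table")
  df$time <- as.integer(df$time)
  df[, need]
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then member genes, tab-delimited.
#' Duplicate genes within a set are de-duplicated with a warning;
#' duplicate set names are an error.
#'
#' @param path GMT file.
#' @return Named list of unique gene-ID vectors; descriptions in attribute
#'   `"description"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) stopf("GMT line %d has fewer than 3 fields", short[1])
  nms <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nms))
    stopf("duplicate gene-set name(s): %s",
          paste(unique(nms[duplicated(nms)]), collapse = ", "))
  desc <- vapply(fields, `[[`, character(1), 2)
  sets <- lapply(fields, function(f) {
    g <- f[-(1:2)]
    if (anyDuplicated(g))
      warnf("duplicate gene(s) within set '%s' de-duplicated", f[[1]])
    unique(g)
  })
  names(sets) <- nms
  attr(sets, "description") <- stats::setNames(desc, nms)
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of gene-ID vectors.
#' @param path Output file.
#' @param descriptions Optional named descriptions (defaults to the set
#'   name).
#' @return The path, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  desc <- descriptions %||% stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]] %||% nm, sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
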