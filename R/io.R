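# Tabular I/O for the pipeline: expression matrices, trait tables, GMT gene
# sets, plain gene lists and the run configuration.
#
# Conventions used throughout the package:
#   * an expression matrix is a numeric matrix, rows = samples, cols = features,
#     with unique dimnames;
#   * a trait table is a tibble whose first column is `sample_id`, remaining
#     columns numeric traits (NA allowed);
#   * a gene-set collection is a named list of character vectors with a
#     "descriptions" attribute.

MISSING_TOKENS <- c("", "na", "nan")

.parse_numeric_cells <- function(chr_mat, what) {
  vals <- suppressWarnings(as.numeric(chr_mat))
  # read.table has already turned the literal token "NA" into NA_character_
  is_missing <- is.na(chr_mat) | tolower(trimws(chr_mat)) %in% MISSING_TOKENS
  bad <- matrix(is.na(vals) & !is_missing, nrow(chr_mat), ncol(chr_mat))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "non-numeric cell in %s at row '%s', column '%s': \"%s\"",
      what,
      rownames(chr_mat)[idx[1]] %||% idx[1],
      colnames(chr_mat)[idx[2]] %||% idx[2],
      chr_mat[idx[1], idx[2]]
    ))
  }
  vals[is_missing] <- NA_real_
  matrix(vals, nrow(chr_mat), ncol(chr_mat), dimnames = dimnames(chr_mat))
}

.read_delim_chr <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.table(path, sep = sep, header = TRUE, colClasses = "character",
                   check.names = FALSE, quote = "\"", comment.char = "",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) {
    abort(sprintf("'%s': expected an ID column plus at least one data column", path))
  }
  header <- colnames(df)[-1]
  if (anyDuplicated(header)) {
    abort(sprintf("'%s': duplicate IDs in header: %s", path,
                  paste(unique(header[duplicated(header)]), collapse = ", ")))
  }
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    abort(sprintf("'%s': duplicate IDs in first column: %s", path,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(ids, header)
  m
}

#' Read a normalized expression matrix
#'
#' Reads a delimited text file (TSV by default, CSV if the extension is
#' `.csv`) with a header row and an ID column, and returns a numeric matrix
#' oriented samples x features regardless of the on-disk orientation.
#'
#' Empty cells and the tokens `NA` / `NaN` (case-insensitive) become `NA`;
#' any other non-numeric cell is an error naming the offending row and column.
#'
#' @param path Path to the file.
#' @param orientation `"rows-are-samples"` (default) or `"rows-are-features"`.
#' @return Numeric matrix, rows = samples, columns = features.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_expression_matrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("s1", "s2"), c("g1", "g2", "g3"))), f)
#' read_expression_matrix(f)
read_expression_matrix <- function(path,
                                   orientation = c("rows-are-samples",
                                                   "rows-are-features")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort(sprintf("file not found: '%s'", path))
  m <- .parse_numeric_cells(.read_delim_chr(path), path)
  if (orientation == "rows-are-features") m <- t(m)
  m
}

#' Write an expression matrix as TSV
#'
#' Full-precision TSV with a leading ID column; the exact inverse of
#' [read_expression_matrix()] with `orientation = "rows-are-samples"`.
#'
#' @param m Numeric matrix, samples x features.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a quantitative trait table
#'
#' Reads a delimited table (header row, sample-ID first column) of
#' quantitative histological traits, e.g. microvessel density (MVD),
#' percentage CD105+ microvessels, alpha-SMA coverage. Blank cells and
#' `NA`/`NaN` tokens become `NA`. A trait column that is entirely missing
#' triggers a warning but is retained.
#'
#' @param path Path to the TSV/CSV file.
#' @return A tibble; first column `sample_id`, remaining columns numeric.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: '%s'", path))
  m <- .parse_numeric_cells(.read_delim_chr(path), path)
  all_na <- colnames(m)[colSums(!is.na(m)) == 0]
  if (length(all_na)) {
    warn(sprintf("trait column(s) entirely missing, retained: %s",
                 paste(all_na, collapse = ", ")))
  }
  tibble::as_tibble(as.data.frame(m), rownames = "sample_id")
}

#' Write a trait table as TSV
#'
#' @param traits Tibble with `sample_id` first column (as returned by
#'   [read_trait_table()] or [generate_traits()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  write.table(format(as.data.frame(traits), digits = 17, trim = TRUE,
                     scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name TAB description TAB member...`.
#' Members are de-duplicated within a set. Lines with fewer than three fields
#' are skipped with a warning. If the same set name occurs twice the last
#' occurrence wins, with a warning (GMT files in the wild contain duplicates).
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors, with a `descriptions` attribute
#'   (named character vector).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      warn(sprintf("GMT line %d has fewer than 3 fields; skipped", i))
      next
    }
    nm <- f[1]
    if (nm %in% names(sets)) {
      warn(sprintf("duplicate gene-set name '%s'; later definition kept", nm))
    }
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    sets[[nm]] <- members
    desc[nm] <- f[2]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Read a plain gene list (one identifier per line)
#'
#' @param path Path to the text file.
#' @return Character vector of unique, non-empty identifiers.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: '%s'", path))
  ids <- trimws(readLines(path, warn = FALSE))
  unique(ids[nzchar(ids)])
}
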