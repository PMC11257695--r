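#' Library-size normalisation and log transform of raw counts
#'
#' Converts a raw count table into log pseudocounts
#' \eqn{x_{c,g} = \log(x^{raw}_{c,g} / S_c + 1)} with per-cell size factor
#' \eqn{S_c = \sum_g x^{raw}_{c,g} / \mathrm{scale}}. With the default
#' `scale = 1e6` this is the usual counts-per-million (CPM) normalisation.
#' Zero counts map to exactly 0. Matrices normalised by other size-factor
#' schemes (TPM, RPKM) can be ingested directly with [read_expression()].
#'
#' @param counts Data frame with a cell-id first column and non-negative
#'   integer gene-count columns (cells as rows, genes as columns).
#' @param scale Positive scaling constant of the size factor (default `1e6`).
#' @return A tibble of log pseudocounts with the same shape as `counts`.
#' @examples
#' counts <- tibble::tibble(cell = c("c1", "c2"), g1 = c(10L, 0L), g2 = c(999990L, 50L))
#' normalise_log1p(counts)
#' @export
normalise_log1p <- function(counts, scale = 1e6) {
  if (!is.data.frame(counts) || ncol(counts) < 2L)
    abort("`counts` must be a data frame with an id column plus gene columns")
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    abort("`scale` must be a single positive number")
  m <- tbl_to_matrix(counts)
  if (any(m < 0) || any(m != floor(m)))
    abort("`counts` must contain non-negative integers")
  s <- rowSums(m) / scale
  zero_cells <- rownames(m)[s == 0]
  if (length(zero_cells))
    abort(sprintf("cell(s) with all-zero counts (size factor S_c = 0): %s",
                  paste(zero_cells, collapse = ", ")))
  out <- log1p(m / s)
  matrix_to_tbl(out, id_name = id_column(counts))
}

guess_delim <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

#' Read an expression matrix from delimited text
#'
#' Expects a header row and an index column of ids. The internal orientation
#' is cells as rows and genes as columns; files stored transposed are
#' accepted via `orientation = "genes_as_rows"`.
#'
#' @param path File path.
#' @param delim Field delimiter; `NULL` (default) guesses between comma and tab.
#' @param orientation `"cells_as_rows"` (default) or `"genes_as_rows"`.
#' @param id_name Name for the id column of the returned tibble.
#' @return A tibble: id column plus numeric gene columns.
#' @export
read_expression <- function(path, delim = NULL,
                            orientation = c("cells_as_rows", "genes_as_rows"),
                            id_name = "cell") {
  orientation <- match.arg(orientation)
  delim <- delim %||% guess_delim(path)
  df <- read.csv(path, sep = delim, check.names = FALSE, row.names = NULL,
                 stringsAsFactors = FALSE)
  check_unique(names(df)[-1L], "header ids")   # before `[.data.frame` repairs them
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) abort(sprintf("non-numeric entries in '%s'", path))
  rownames(m) <- ids
  if (orientation == "genes_as_rows") m <- t(m)
  check_unique(rownames(m), "row ids")
  check_unique(colnames(m), "column ids")
  out <- matrix_to_tbl(m, id_name = id_name)
  validate_expression(out, arg = path)
  out
}

#' Write an expression matrix to delimited text
#'
#' @param x Expression tibble (id column + gene columns).
#' @param path Output file path.
#' @param delim Field delimiter (default `","`).
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, delim = ",") {
  validate_expression(x)
  df <- as.data.frame(x[, -1L, drop = FALSE])
  rownames(df) <- as.character(x[[1L]])
  write.csv_delim(df, path, delim, id_name = id_column(x))
  invisible(path)
}

write.csv_delim <- function(df, path, delim, id_name) {
  out <- cbind(setNames(data.frame(rownames(df), stringsAsFactors = FALSE), id_name), df)
  utils::write.table(out, path, sep = delim, row.names = FALSE, quote = FALSE)
}

#' Read / write three-valued binary activity matrices
#'
#' Binary matrices hold entries in \{0, 1, undetermined\}; internally the
#' undetermined symbol is `NA` and it is serialised as a configurable token
#' (`"?"` by default; the `"NA"` dialect is also supported). Readers and
#' writers are exact inverses on their own output.
#'
#' @param x Binary tibble (id column + gene columns of 0/1/`NA`).
#' @param path File path.
#' @param undetermined Token used for undetermined entries; must differ from
#'   `"0"` and `"1"`.
#' @param delim Field delimiter; reading guesses between comma and tab when `NULL`.
#' @param id_name Name for the id column of the returned tibble.
#' @return `write_binary()` returns `path` invisibly; `read_binary()` a tibble.
#' @export
write_binary <- function(x, path, undetermined = "?", delim = ",") {
  validate_binary(x)
  if (undetermined %in% c("0", "1"))
    abort("`undetermined` token must be distinct from \"0\" and \"1\"")
  m <- as.matrix(x[, -1L, drop = FALSE])
  ch <- matrix(as.character(m), nrow = nrow(m), dimnames = dimnames(m))
  ch[is.na(m)] <- undetermined
  df <- as.data.frame(ch, stringsAsFactors = FALSE)
  rownames(df) <- as.character(x[[1L]])
  write.csv_delim(df, path, delim, id_name = id_column(x))
  invisible(path)
}

#' @rdname write_binary
#' @export
read_binary <- function(path, undetermined = "?", delim = NULL, id_name = "cell") {
  delim <- delim %||% guess_delim(path)
  df <- read.csv(path, sep = delim, check.names = FALSE, colClasses = "character",
                 stringsAsFactors = FALSE, na.strings = NULL)
  ids <- as.character(df[[1L]])
  ch <- as.matrix(df[, -1L, drop = FALSE])
  bad <- setdiff(unique(as.vector(ch)), c("0", "1", undetermined))
  if (length(bad))
    abort(sprintf("unexpected symbols in '%s': %s", path, paste(bad, collapse = ", ")))
  m <- matrix(NA_real_, nrow(ch), ncol(ch), dimnames = list(NULL, colnames(ch)))
  m[ch == "0"] <- 0
  m[ch == "1"] <- 1
  rownames(m) <- ids
  out <- matrix_to_tbl(m, id_name = id_name)
  validate_binary(out)
  out
}

#' Read / write strictly binary Boolean state matrices
#'
#' Boolean state (configuration/trace) matrices must be strictly binary;
#' undetermined entries are rejected.
#'
#' @inheritParams read_binary
#' @return A tibble with an id column plus 0/1 node columns.
#' @export
read_states <- function(path, delim = NULL, id_name = "state") {
  out <- read_binary(path, undetermined = "never", delim = delim,
                     id_name = id_name)
  validate_states(out)
  out
}

#' @rdname read_states
#' @param x State tibble to write.
#' @export
write_states <- function(x, path, delim = ",") {
  validate_states(x)
  write_binary(x, path, undetermined = "?", delim = delim)
}
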