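# Internal helpers shared across modules.

# Deterministic child seed derived from a base seed and a string key, so that
# per-gene random streams do not depend on gene iteration order.
derive_seed <- function(seed, key) {
  h <- strtoi(substr(digest::digest(paste0("boolexpr::", key)), 1L, 7L), base = 16L)
  as.integer((as.numeric(seed) + h) %% (.Machine$integer.max - 1)) + 1L
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; when `seed`
# is NULL the global RNG stream is consumed as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

id_column <- function(x) names(x)[1L]

# First column = identifiers, remaining columns numeric values.
tbl_to_matrix <- function(x) {
  ids <- as.character(x[[1L]])
  m <- as.matrix(x[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

matrix_to_tbl <- function(m, id_name = "cell") {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  out <- tibble::add_column(out, !!id_name := rownames(m), .before = 1L)
  out
}

check_unique <- function(ids, what) {
  if (anyDuplicated(ids))
    abort(sprintf("duplicate %s: %s", what,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  invisible(ids)
}

# Validate a samples-by-genes log-pseudocount table (id column + numeric gene
# columns, finite and non-negative).
validate_expression <- function(x, arg = "x") {
  if (!is.data.frame(x) || ncol(x) < 2L)
    abort(sprintf("`%s` must be a data frame with an id column plus gene columns", arg))
  check_unique(as.character(x[[1L]]), "cell ids")
  check_unique(names(x)[-1L], "gene ids")
  m <- tbl_to_matrix(x)
  if (!all(is.finite(m))) abort(sprintf("`%s` contains non-finite values", arg))
  if (any(m < 0)) abort(sprintf("`%s` contains negative values; log pseudocounts must be >= 0", arg))
  invisible(x)
}

# Three-valued activity table: 0 / 1 / NA (undetermined).
validate_binary <- function(x, arg = "x") {
  if (!is.data.frame(x) || ncol(x) < 1L)
    abort(sprintf("`%s` must be a data frame with an id column", arg))
  m <- as.matrix(x[, -1L, drop = FALSE])
  vals <- m[!is.na(m)]
  if (length(vals) && !all(vals %in% c(0, 1)))
    abort(sprintf("`%s` must contain only 0, 1 and NA (undetermined)", arg))
  invisible(x)
}

# Strictly binary state table (Boolean configurations, no undetermined).
validate_states <- function(x, arg = "states") {
  if (!is.data.frame(x) || ncol(x) < 2L)
    abort(sprintf("`%s` must be a data frame with an id column plus node columns", arg))
  m <- as.matrix(x[, -1L, drop = FALSE])
  if (anyNA(m) || !all(m %in% c(0, 1)))
    abort(sprintf(paste0("`%s` must be strictly binary (entries in {0, 1}); ",
                         "resolve undetermined states upstream, e.g. with resolve_undetermined()"), arg))
  invisible(x)
}

gene_ids <- function(x) names(x)[-1L]
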