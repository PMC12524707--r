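#' Construct a perturbagen signature library
#'
#' The connectivity-map reference: a perturbagen x gene matrix of
#' differential-expression z-scores plus per-perturbagen metadata (compound
#' name, cell line, perturbagen type).
#'
#' @param zscores Numeric matrix, perturbagens x genes, with dimnames.
#' @param meta Data frame with columns `perturbagen_id`, `compound`,
#'   `cell_line`, `type` (`"compound"` or `"knockdown"`), one row per matrix
#'   row, same order or matched by id.
#' @return List with elements `zscores` (matrix) and `meta` (tibble).
#' @export
perturbagen_library <- function(zscores, meta) {
  stopifnot(is.matrix(zscores), !is.null(rownames(zscores)), !is.null(colnames(zscores)))
  if (anyNA(zscores)) abort("missing z-scores in signature library")
  meta <- as_tibble(meta)
  need <- c("perturbagen_id", "compound", "cell_line", "type")
  if (!all(need %in% names(meta))) {
    abort(paste("library metadata needs columns:", paste(need, collapse = ", ")))
  }
  if (nrow(meta) != nrow(zscores)) {
    abort(sprintf("metadata rows (%d) != signature matrix rows (%d)", nrow(meta), nrow(zscores)))
  }
  hit <- match(rownames(zscores), meta$perturbagen_id)
  if (anyNA(hit)) abort("metadata perturbagen_id does not cover all matrix rows")
  colnames(zscores) <- toupper(colnames(zscores))
  list(zscores = zscores, meta = meta[hit, ])
}

#' Read a perturbagen signature library (GCT-like matrix + metadata sidecar)
#'
#' @param path GCT file of z-scores with perturbagens as columns and genes as
#'   rows (the transpose is stored internally).
#' @param meta_path TSV with columns `perturbagen_id`, `compound`,
#'   `cell_line`, `type`.
#' @return See [perturbagen_library()].
#' @export
read_signature_library <- function(path, meta_path) {
  mat <- read_expression_matrix(path, format = "gct")
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE, progress = FALSE)
  perturbagen_library(t(mat), meta)
}

#' Write a perturbagen signature library
#'
#' @param lib Library from [perturbagen_library()].
#' @param path GCT output path (genes x perturbagens).
#' @param meta_path Metadata TSV output path.
#' @export
write_signature_library <- function(lib, path, meta_path) {
  write_expression_matrix(t(lib$zscores), path, format = "gct")
  write_tsv_lf(lib$meta, meta_path)
  invisible(path)
}

#' Read a survival table
#'
#' TSV with columns `sample_id`, `time` (positive, days), `event` (0 =
#' censored, 1 = death observed), plus optional covariates.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_survival_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_survival_table(df)
}

#' Validate a survival table
#' @param df Data frame with `sample_id`, `time`, `event` columns.
#' @return Validated tibble.
#' @export
validate_survival_table <- function(df) {
  df <- as_tibble(df)
  if (!all(c("sample_id", "time", "event") %in% names(df))) {
    abort("survival table needs sample_id, time, event columns")
  }
  if (any(df$time <= 0)) abort("survival times must be positive")
  if (!all(df$event %in% c(0, 1))) abort("event must be 0 or 1")
  if (anyDuplicated(df$sample_id)) abort("duplicate sample ids in survival table")
  df
}

#' Read a compound score table
#'
#' TSV keyed by a unique `compound` column, with arbitrary named numeric or
#' categorical columns (BBB permeability scores, P-gp substrate calls,
#' literature co-occurrence counts, ...).
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_score_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"compound" %in% names(df)) abort("score table needs a 'compound' column")
  if (anyDuplicated(df$compound)) abort("duplicate compound ids in score table")
  df
}

# Byte-stable TSV writer (LF endings, fixed number formatting) so that rerun
# artifacts are identical.
write_tsv_lf <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  fmt <- function(x) {
    if (is.double(x)) format(x, digits = 15, trim = TRUE, scientific = FALSE) else as.character(x)
  }
  cells <- vapply(df, fmt, character(nrow(df) %||% 0L))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) writeLines(apply(cells, 1, paste, collapse = "\t"), con)
  invisible(path)
}
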