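#' Read gene sets from the standard gene-set text format
#'
#' One set per line: set name, description, then one gene symbol per field,
#' all tab-separated. Gene symbols are upper-cased and de-duplicated so that
#' joins against expression matrices and interaction graphs are
#' case-insensitive.
#'
#' @param path File path.
#' @return Named list of character vectors; descriptions stored in
#'   `attr(, "description")`.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(trimws(fields))]
    if (length(fields) < 3) {
      abort(sprintf("gene-set line %d has fewer than 3 fields (name, description, genes...)", i))
    }
    genes <- unique(toupper(trimws(fields[-(1:2)])))
    sets[[fields[1]]] <- genes
    descs[fields[1]] <- fields[2]
  }
  attr(sets, "description") <- descs
  sets
}

#' Write gene sets to the standard gene-set text format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions (defaults to set names).
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% attr(sets, "description") %||%
    setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]] %||% nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
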