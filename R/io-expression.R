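#' Validate a genes-by-samples expression matrix
#'
#' Enforces the container contract shared by the enrichment, co-expression and
#' correlation stages: a dense numeric matrix with unique gene row names and
#' unique sample column names, no missing values, and at least 2 genes and 2
#' samples. Genes containing any missing value are dropped with a warning;
#' duplicate gene rows are collapsed by their mean.
#'
#' @param values Numeric matrix (genes in rows, samples in columns) with
#'   dimnames.
#' @return The validated matrix (possibly with rows dropped/collapsed).
#' @export
as_expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("expression values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("expression matrix needs gene row names and sample column names")
  }
  if (anyDuplicated(colnames(values))) {
    abort("duplicate sample identifiers")
  }
  na_gene <- rowSums(is.na(values)) > 0
  if (any(na_gene)) {
    warn(sprintf("dropping %d gene(s) with missing values: %s",
                 sum(na_gene), paste(head(rownames(values)[na_gene], 5), collapse = ", ")))
    values <- values[!na_gene, , drop = FALSE]
  }
  if (anyDuplicated(rownames(values))) {
    warn("collapsing duplicate gene rows by mean")
    values <- rowsum(values, rownames(values)) /
      as.vector(table(rownames(values))[unique(sort(rownames(values)))])
    # rowsum sorts groups; restore a deterministic (sorted) order is fine
  }
  if (nrow(values) < 2 || ncol(values) < 2) {
    abort("expression matrix needs at least 2 genes and 2 samples")
  }
  values
}

#' Read an expression matrix from TSV or GCT
#'
#' The TSV dialect is a header row of sample ids with gene ids in the first
#' column. The GCT dialect is version line `#1.2`, a dimensions line
#' `n_genes<TAB>n_samples`, then a header with `Name` and `Description`
#' columns.
#'
#' @param path File path.
#' @param format `"tsv"` or `"gct"`; `"auto"` picks GCT for `.gct` files.
#' @return Validated numeric matrix, genes x samples.
#' @export
read_expression_matrix <- function(path, format = c("auto", "tsv", "gct")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  }
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "gct") {
    lines <- readLines(path)
    if (length(lines) < 3 || trimws(lines[1]) != "#1.2") {
      abort("not a GCT v1.2 file (missing '#1.2' version line)")
    }
    dims <- as.integer(strsplit(lines[2], "\t")[[1]][1:2])
    body <- utils::read.delim(text = paste(lines[-(1:2)], collapse = "\n"),
                              check.names = FALSE, stringsAsFactors = FALSE)
    if (!all(c("Name", "Description") %in% names(body)[1:2])) {
      abort("GCT header must start with Name and Description columns")
    }
    if (nrow(body) != dims[1] || ncol(body) - 2L != dims[2]) {
      abort(sprintf("GCT dimension mismatch: header declares %d x %d, body is %d x %d",
                    dims[1], dims[2], nrow(body), ncol(body) - 2L))
    }
    vals <- as.matrix(body[, -(1:2), drop = FALSE])
    rownames(vals) <- body$Name
  } else {
    body <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    vals <- as.matrix(body[, -1, drop = FALSE])
    rownames(vals) <- as.character(body[[1]])
  }
  if (!is.numeric(vals)) {
    bad <- which(!vapply(as.data.frame(vals), is.numeric, logical(1)))[1]
    abort(sprintf("non-numeric expression values in column '%s'", colnames(vals)[bad]))
  }
  storage.mode(vals) <- "double"
  as_expression_matrix(vals)
}

#' Write an expression matrix to TSV or GCT
#'
#' @param expr Genes x samples matrix.
#' @param path Output path.
#' @param format `"tsv"` or `"gct"` (`"auto"` by extension).
#' @export
write_expression_matrix <- function(expr, path, format = c("auto", "tsv", "gct")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  }
  df <- as.data.frame(expr, check.names = FALSE)
  con <- file(path, open = "wb")  # binary mode: fixed "\n" endings for byte-stable artifacts
  on.exit(close(con))
  if (format == "gct") {
    writeLines(c("#1.2", paste(nrow(expr), ncol(expr), sep = "\t")), con)
    header <- paste(c("Name", "Description", colnames(expr)), collapse = "\t")
    writeLines(header, con)
    body <- cbind(rownames(expr), rownames(expr),
                  format(expr, digits = 15, trim = TRUE, scientific = FALSE))
    writeLines(apply(body, 1, paste, collapse = "\t"), con)
  } else {
    writeLines(paste(c("gene_id", colnames(expr)), collapse = "\t"), con)
    body <- cbind(rownames(expr), format(expr, digits = 15, trim = TRUE, scientific = FALSE))
    writeLines(apply(body, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Construct a two-condition count matrix
#'
#' @param counts Non-negative integer matrix, genes x samples, with dimnames.
#' @param condition One condition label per sample (exactly two levels, each
#'   with >= 2 samples).
#' @return List with elements `counts` and `condition` (named character).
#' @export
count_matrix <- function(counts, condition) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("counts must be a matrix with gene and sample dimnames")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  if (length(condition) != ncol(counts)) {
    abort("one condition label per sample required")
  }
  condition <- setNames(as.character(condition), colnames(counts))
  tab <- table(condition)
  if (length(tab) != 2 || any(tab < 2)) {
    abort("need exactly two conditions with >= 2 samples each")
  }
  storage.mode(counts) <- "double"
  list(counts = counts, condition = condition)
}

#' Log-CPM normalization of a count matrix
#'
#' Stand-in for variance-stabilizing count normalization:
#' `log2(1e6 * c / library_size + 1)` per cell. Any monotone variance-damping
#' transform serves the downstream rank- and correlation-based stages; the
#' divergence from model-based variance stabilization is documented in the
#' methods vignette.
#'
#' @param cm Count matrix from [count_matrix()] (or a bare counts matrix).
#' @return Expression matrix (genes x samples) of log-CPM values.
#' @export
lognorm_counts <- function(cm) {
  counts <- if (is.list(cm)) cm$counts else cm
  libsize <- colSums(counts)
  if (any(libsize == 0)) {
    abort(sprintf("sample(s) with zero total counts: %s",
                  paste(colnames(counts)[libsize == 0], collapse = ", ")))
  }
  vals <- log2(sweep(counts, 2, libsize, "/") * 1e6 + 1)
  as_expression_matrix(vals)
}
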