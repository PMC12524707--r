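#' Build an interaction graph from an edge table
#'
#' @param edges Data frame with columns `node_a`, `node_b`, `confidence`
#'   (in \[0, 1\]).
#' @param min_confidence Edges with confidence strictly greater than this are
#'   retained.
#' @param kind Optional named character vector tagging nodes as
#'   `"gene"`, `"protein"` or `"compound"` (untagged nodes default to
#'   `"gene"`).
#' @return An undirected [igraph::igraph] with edge attribute `confidence`
#'   and vertex attribute `kind`; no self-loops, no duplicate edges.
#' @export
interaction_graph <- function(edges, min_confidence = 0.7, kind = NULL) {
  stopifnot(all(c("node_a", "node_b", "confidence") %in% names(edges)))
  if (any(edges$confidence < 0)) abort("negative confidence score")
  if (any(edges$confidence > 1)) abort("confidence must be in [0, 1] (STRING-style scores are rescaled at read time)")
  self <- edges$node_a == edges$node_b
  if (any(self)) {
    warn(sprintf("dropping %d self-loop(s)", sum(self)))
    edges <- edges[!self, , drop = FALSE]
  }
  edges <- edges[edges$confidence > min_confidence, , drop = FALSE]
  # canonical unordered pair, keep max confidence among duplicates
  a <- pmin(edges$node_a, edges$node_b)
  b <- pmax(edges$node_a, edges$node_b)
  ord <- order(a, b, -edges$confidence)
  edges <- tibble(node_a = a[ord], node_b = b[ord], confidence = edges$confidence[ord])
  edges <- edges[!duplicated(edges[c("node_a", "node_b")]), , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = unique(c(edges$node_a, edges$node_b,
                                                         names(kind))))
  node_kind <- rep("gene", igraph::vcount(g))
  if (!is.null(kind)) {
    hit <- match(igraph::V(g)$name, names(kind))
    node_kind[!is.na(hit)] <- kind[hit[!is.na(hit)]]
  }
  igraph::V(g)$kind <- node_kind
  g
}

#' Read a STRING/STITCH-style edge list
#'
#' Tab-separated columns `node_a`, `node_b`, `combined_score`. Scores may be
#' on the \[0, 1\] scale or the STRING \[0, 1000\] scale; the latter is
#' auto-detected (any score > 1) and divided by 1000. Only edges with
#' confidence strictly greater than `min_confidence` are retained, matching
#' the "confidence score > 0.7" convention for association networks.
#'
#' @inheritParams interaction_graph
#' @param path File path.
#' @return An [igraph::igraph]; see [interaction_graph()].
#' @export
read_edge_list <- function(path, min_confidence = 0.7, kind = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("node_a", "node_b", "confidence")
  if (!is.numeric(df$confidence)) abort("combined_score column must be numeric")
  if (any(df$confidence < 0)) abort("negative combined_score")
  if (any(df$confidence > 1)) df$confidence <- df$confidence / 1000
  interaction_graph(df, min_confidence = min_confidence, kind = kind)
}

#' Write an interaction graph as an edge list
#'
#' @param graph An [igraph::igraph] with a `confidence` edge attribute.
#' @param path Output path.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_data_frame(graph, what = "edges")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("node_a\tnode_b\tcombined_score", con)
  if (nrow(el)) {
    writeLines(paste(el$from, el$to,
                     format(el$confidence, digits = 15, trim = TRUE, scientific = FALSE),
                     sep = "\t"), con)
  }
  invisible(path)
}
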