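#' Six-metric topological centrality table
#'
#' Computes, for every node of an unweighted undirected graph:
#' * **Degree** — neighbour count.
#' * **MCC** (maximal clique centrality) — sum of `(|C| - 1)!` over maximal
#'   cliques containing the node (Bron-Kerbosch enumeration); 0 for
#'   isolated nodes.
#' * **MNC** (maximum neighbourhood component) — size of the largest
#'   connected component of the subgraph induced by the node's neighbours.
#' * **EPC** (edge percolation component) — mean fraction of other nodes
#'   still reachable after independently retaining each edge with
#'   probability `epc_retain`, over `epc_trials` seeded Monte-Carlo trials
#'   (`epc_retain = 1` reduces to exact reachability).
#' * **Closeness** — harmonic closeness `sum 1/d(v, w)` (unreachable pairs
#'   contribute 0), well-defined on disconnected graphs.
#' * **Radiality** — `(1/(n-1)) * sum(diam_c + 1 - d(v, w))` over reachable
#'   `w` in the node's component, where `diam_c` is the component diameter.
#'
#' @param graph An [igraph::igraph] (edge weights ignored; the confidence
#'   threshold is applied when the graph is built).
#' @param epc_trials Monte-Carlo trials for EPC.
#' @param epc_retain Edge retention probability for EPC.
#' @param seed Integer seed for the EPC trials.
#' @return Tibble: `node`, the six metrics, per-metric descending ranks
#'   (ties = average rank) and `score` = mean rank (lower = more central).
#' @export
compute_centralities <- function(graph, epc_trials = 1000, epc_retain = 0.5,
                                 seed = 1) {
  n <- igraph::vcount(graph)
  if (n == 0) abort("empty graph")
  nodes <- igraph::V(graph)$name %||% as.character(seq_len(n))

  deg <- igraph::degree(graph)

  mcc <- numeric(n)
  if (igraph::ecount(graph) > 0) {
    for (cl in igraph::max_cliques(graph, min = 2)) {
      mcc[as.integer(cl)] <- mcc[as.integer(cl)] + factorial(length(cl) - 1)
    }
  }

  mnc <- vapply(seq_len(n), function(v) {
    nb <- as.integer(igraph::neighbors(graph, v))
    if (!length(nb)) return(0)
    sub <- igraph::induced_subgraph(graph, nb)
    max(igraph::components(sub)$csize)
  }, numeric(1))

  d <- igraph::distances(graph, weights = NA)  # hop counts; confidence is a filter, not a length
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  closeness <- rowSums(inv)

  comp <- igraph::components(graph)
  radiality <- numeric(n)
  for (c_id in seq_len(comp$no)) {
    memb <- which(comp$membership == c_id)
    if (length(memb) < 2) next
    dc <- d[memb, memb, drop = FALSE]
    diam <- max(dc)
    contrib <- diam + 1 - dc
    diag(contrib) <- 0
    radiality[memb] <- rowSums(contrib) / (n - 1)
  }

  epc <- epc_centrality(graph, trials = epc_trials, retain = epc_retain, seed = seed)

  tab <- tibble(node = nodes, degree = unname(deg), mcc = mcc, mnc = mnc,
                epc = epc, closeness = unname(closeness), radiality = radiality)
  composite_rank(tab)
}

# Monte-Carlo edge-percolation reachability; retain = 1 is computed exactly.
epc_centrality <- function(graph, trials = 1000, retain = 0.5, seed = 1) {
  n <- igraph::vcount(graph)
  m <- igraph::ecount(graph)
  if (n <= 1) return(rep(0, n))
  reach_frac <- function(g) {
    cs <- igraph::components(g)
    (cs$csize[cs$membership] - 1) / (n - 1)
  }
  if (retain >= 1 || m == 0) return(reach_frac(graph))
  set.seed(seed)
  acc <- numeric(n)
  for (t in seq_len(trials)) {
    keep <- which(runif(m) < retain)
    sub <- igraph::subgraph_from_edges(graph, keep, delete.vertices = FALSE)
    acc <- acc + reach_frac(sub)
  }
  acc / trials
}

#' Composite centrality ranking
#'
#' Ranks each metric descending (highest value = rank 1; ties share the
#' average rank), averages the six ranks into a composite score, and sorts
#' ascending by score with node id as tie-break.
#'
#' @param tab Tibble with `node` and the six metric columns.
#' @return The table with per-metric rank columns and `score`, sorted.
#' @export
composite_rank <- function(tab) {
  metrics <- c("degree", "mcc", "mnc", "epc", "closeness", "radiality")
  stopifnot(all(c("node", metrics) %in% names(tab)))
  for (mname in metrics) {
    tab[[paste0("rank_", mname)]] <- rank(-tab[[mname]], ties.method = "average")
  }
  tab$score <- rowMeans(tab[paste0("rank_", metrics)])
  arrange(tab, .data$score, .data$node)
}

#' Select hub genes among candidates
#'
#' The `k` best-scoring nodes (lowest composite rank score) among the
#' candidate genes present in the ranked table.
#'
#' @param ranked Tibble from [compute_centralities()] / [composite_rank()].
#' @param candidate_genes Character vector (e.g. module genes intersected
#'   with upregulated genes); candidates absent from the graph are dropped
#'   with a warning.
#' @param k Number of hubs.
#' @return Character vector of hub gene ids, best first.
#' @export
select_hubs <- function(ranked, candidate_genes, k) {
  present <- intersect(candidate_genes, ranked$node)
  missing <- setdiff(candidate_genes, ranked$node)
  if (length(missing)) {
    warn(sprintf("%d candidate gene(s) not in graph: %s", length(missing),
                 paste(head(missing, 5), collapse = ", ")))
  }
  if (!length(present)) return(character(0))
  if (k > length(present)) {
    warn(sprintf("k = %d exceeds %d candidates in graph; returning all", k, length(present)))
    k <- length(present)
  }
  ranked |>
    filter(.data$node %in% present) |>
    slice(seq_len(k)) |>
    pull("node")
}

#' Build a compound-target-hub network
#'
#' Union graph of compound-target edges (STITCH-style, confidence
#' threshold applied) and the gene-gene interactions among targets and hub
#' genes; nodes carry `kind` tags. Compounds whose edges all fall below the
#' threshold remain as isolated nodes. The result can be fed back to
#' [compute_centralities()] to rank compounds by interconnection with the
#' hub signature.
#'
#' @param compound_target_edges Data frame `node_a` (compound), `node_b`
#'   (target protein), `confidence`.
#' @param target_gene_graph An [igraph::igraph] of gene/protein
#'   interactions (already thresholded).
#' @param hub_genes Character vector of hub genes to retain.
#' @param min_confidence Confidence cutoff for compound-target edges.
#' @return An [igraph::igraph] with vertex attribute `kind`.
#' @export
build_compound_network <- function(compound_target_edges, target_gene_graph,
                                   hub_genes, min_confidence = 0.7) {
  ce <- as_tibble(compound_target_edges)
  compounds <- unique(ce$node_a)
  ce <- ce[ce$confidence > min_confidence, , drop = FALSE]
  gene_edges <- igraph::as_data_frame(target_gene_graph, what = "edges")
  keep_nodes <- union(hub_genes, unique(c(ce$node_b, gene_edges$from, gene_edges$to)))
  ge <- tibble(node_a = gene_edges$from, node_b = gene_edges$to,
               confidence = gene_edges$confidence %||% rep(1, nrow(gene_edges)))
  all_edges <- bind_rows(ce[c("node_a", "node_b", "confidence")], ge)
  kind <- c(setNames(rep("compound", length(compounds)), compounds),
            setNames(rep("gene", length(keep_nodes)), keep_nodes))
  interaction_graph(all_edges, min_confidence = 0, kind = kind)
}
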