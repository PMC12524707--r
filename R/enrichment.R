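#' Single-sample gene-set enrichment scores
#'
#' Rank-based single-sample enrichment (the ssGSEA statistic). For each
#' sample, genes are ranked descending by expression (ties broken by gene id
#' so the ranking is deterministic); position `i` of `N` carries weight
#' `(N - i + 1)^alpha`. The enrichment score for set S is the sum over
#' positions of the difference between the weighted in-set cumulative
#' fraction and the unweighted out-of-set cumulative fraction:
#' `ES = sum_i [P_in(i) - P_out(i)]`.
#'
#' Because the statistic depends only on within-sample ranks, it is invariant
#' under any strictly monotone transform of a sample's expression vector.
#'
#' @param expr Genes x samples expression matrix (rownames upper-cased for
#'   matching).
#' @param sets Named list of gene sets (e.g. from [read_gene_sets()]). Each
#'   set must share >= 2 genes with the matrix and must not cover all matrix
#'   genes.
#' @param alpha Rank-weighting exponent (0 = unweighted); 0.25 is the
#'   conventional single-sample default.
#' @param rescale If `TRUE`, divide all scores by the range (max - min) over
#'   all samples and sets, putting cohorts on a comparable scale.
#' @return Tibble with columns `sample_id`, `set`, `score`.
#' @export
ssgsea_scores <- function(expr, sets, alpha = 0.25, rescale = FALSE) {
  genes <- toupper(rownames(expr))
  n <- length(genes)
  sets <- lapply(sets, toupper)
  member <- matrix(FALSE, n, length(sets), dimnames = list(genes, names(sets)))
  for (s in names(sets)) {
    hit <- genes %in% sets[[s]]
    if (sum(hit) < 2) {
      abort(sprintf("set '%s' shares fewer than 2 genes with the matrix (missing: %s)",
                    s, paste(head(setdiff(sets[[s]], genes), 5), collapse = ", ")))
    }
    if (all(hit)) {
      abort(sprintf("set '%s' covers every matrix gene; out-of-set fraction undefined", s))
    }
    member[, s] <- hit
  }
  m <- colSums(member)
  res <- matrix(NA_real_, ncol(expr), length(sets),
                dimnames = list(colnames(expr), names(sets)))
  w_pos <- (n - seq_len(n) + 1)^alpha
  for (j in seq_len(ncol(expr))) {
    ord <- order(-expr[, j], genes)
    ind <- member[ord, , drop = FALSE]
    w_in <- apply(ind * w_pos, 2, cumsum)
    tot_in <- colSums(ind * w_pos)
    p_in <- sweep(w_in, 2, tot_in, "/")
    p_out <- sweep(apply(!ind, 2, cumsum), 2, n - m, "/")
    res[j, ] <- colSums(p_in - p_out)
  }
  if (rescale) {
    rng <- max(res) - min(res)
    if (rng > 0) res <- res / rng
  }
  as_tibble(res, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "set", values_to = "score")
}

#' Per-sample GMT (glial-mesenchymal transition) score
#'
#' The GMT score of a sample is its mesenchymal single-sample enrichment
#' score minus its proneural score; positive values mark a mesenchymal-like
#' transcriptional state.
#'
#' @inheritParams ssgsea_scores
#' @param mes_set Character vector, mesenchymal signature genes.
#' @param pn_set Character vector, proneural signature genes.
#' @return Tibble with columns `sample_id`, `score`.
#' @export
gmt_score <- function(expr, mes_set, pn_set, alpha = 0.25, rescale = FALSE) {
  sc <- ssgsea_scores(expr, list(mes = mes_set, pn = pn_set),
                      alpha = alpha, rescale = rescale)
  sc |>
    tidyr::pivot_wider(names_from = "set", values_from = "score") |>
    mutate(score = .data$mes - .data$pn) |>
    select("sample_id", "score")
}

#' Stratify samples at the median score
#'
#' Samples strictly above the median are labelled `"high"`, the rest
#' `"low"` (ties at the median go to `"low"`).
#'
#' @param scores Tibble with `sample_id` and `score` columns.
#' @return Input tibble with an added `group` column.
#' @export
stratify_by_median <- function(scores) {
  if (nrow(scores) < 2) abort("need at least 2 samples to stratify")
  med <- median(scores$score)
  if (all(scores$score == scores$score[1])) {
    abort("degenerate stratification: all scores identical")
  }
  mutate(scores, group = ifelse(.data$score > med, "high", "low"))
}

#' Immune cell-type enrichment
#'
#' Scores a collection of immune cell-type signatures per sample with the
#' single-sample enrichment engine. (No spillover compensation between
#' related cell types is applied.)
#'
#' @inheritParams ssgsea_scores
#' @param immune_sets Named list of immune cell-type gene sets.
#' @return Tibble `sample_id`, `cell_type`, `score`.
#' @export
immune_enrichment <- function(expr, immune_sets, alpha = 0.25) {
  ssgsea_scores(expr, immune_sets, alpha = alpha) |>
    rename(cell_type = "set")
}
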