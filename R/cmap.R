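#' Weighted Kolmogorov-Smirnov enrichment score of a query set in a ranked
#' signature
#'
#' Genes are ranked by z-score descending (ties broken by gene id); walking
#' down the list, a query hit adds `|z|^p` normalized over the query hits
#' and a miss subtracts `1/(N - m)`. The ES is the running sum's signed
#' maximum deviation from zero.
#'
#' @param zscores Named numeric vector: one differential-expression z-score
#'   per gene for one perturbagen.
#' @param query_set Character vector of query genes (case-insensitive); must
#'   intersect the signature and must not cover all genes.
#' @param weight_p Weight exponent (1 = connectivity-map default).
#' @return ES in \[-1, 1\].
#' @export
weighted_ks_es <- function(zscores, query_set, weight_p = 1) {
  genes <- toupper(names(zscores))
  hit <- genes %in% toupper(query_set)
  if (!any(hit)) abort("query set does not intersect the signature genes")
  if (all(hit)) abort("query set covers every signature gene")
  ord <- order(-zscores, genes)
  hit <- hit[ord]
  w <- abs(zscores[ord])^weight_p
  tot <- sum(w[hit])
  inc <- if (tot > 0) w * hit / tot else hit / sum(hit)
  dec <- (!hit) / (length(genes) - sum(hit))
  run <- cumsum(inc - dec)
  unname(run[which.max(abs(run))])
}

#' Weighted two-sided connectivity score (WTCS)
#'
#' With an up and a down query set: `(ES_up - ES_down) / 2` when the two
#' enrichment scores disagree in sign, else 0. With an up-only query (the
#' usual hub-signature case) the WTCS is just `ES_up`.
#'
#' @param zscores Named per-gene z-scores for one perturbagen.
#' @param up_set Up-regulated query genes.
#' @param down_set Optional down-regulated query genes (must not overlap
#'   `up_set`).
#' @inheritParams weighted_ks_es
#' @return WTCS in \[-1, 1\].
#' @export
wtcs <- function(zscores, up_set, down_set = NULL, weight_p = 1) {
  if (!is.null(down_set) && length(intersect(toupper(up_set), toupper(down_set)))) {
    abort("up and down query sets overlap")
  }
  es_up <- weighted_ks_es(zscores, up_set, weight_p)
  if (is.null(down_set)) return(es_up)
  es_down <- weighted_ks_es(zscores, down_set, weight_p)
  if (sign(es_up) != sign(es_down)) (es_up - es_down) / 2 else 0
}

#' Normalize connectivity scores within (cell line, perturbagen type) groups
#'
#' `NCS = w / mean(|w'|)` over same-sign scores `w'` in the same group;
#' zero scores stay zero, and a degenerate group yields `sign(w)`.
#'
#' @param results Tibble with columns `wtcs`, `cell_line`, `type`.
#' @return Input with an added `ncs` column.
#' @export
normalize_ncs <- function(results) {
  results |>
    group_by(.data$cell_line, .data$type) |>
    mutate(ncs = {
      w <- .data$wtcs
      pos_m <- mean(abs(w[w > 0])); neg_m <- mean(abs(w[w < 0]))
      out <- numeric(length(w))
      out[w > 0] <- if (is.nan(pos_m) || pos_m == 0) 1 else w[w > 0] / pos_m
      out[w < 0] <- if (is.nan(neg_m) || neg_m == 0) -1 else w[w < 0] / neg_m
      out
    }) |>
    ungroup()
}

#' Signed tau percentile against a reference score distribution
#'
#' `tau = sign(ncs) * 100 * fraction of reference |NCS| values strictly
#' below |ncs|`.
#'
#' @param ncs Numeric vector of query normalized connectivity scores.
#' @param reference Numeric vector of reference NCS values (non-empty).
#' @return tau values in \[-100, 100\].
#' @export
tau_percentile <- function(ncs, reference) {
  if (!length(reference)) abort("empty reference distribution")
  aref <- abs(reference)
  frac <- vapply(abs(ncs), function(x) sum(aref < x), numeric(1)) / length(aref)
  sign(ncs) * 100 * frac
}

#' Summarize per-cell-line taus into one score per compound
#'
#' The maximum-quantile rule: the summary is whichever of the 67th and 33rd
#' percentiles of a compound's taus has the larger absolute value (ties go
#' to the 67th).
#'
#' @param taus Numeric vector of per-cell-line tau values.
#' @return Single summary tau.
#' @export
summarize_across_cells <- function(taus) {
  if (!length(taus)) abort("no tau values to summarize")
  q_hi <- unname(quantile(taus, 0.67))
  q_lo <- unname(quantile(taus, 0.33))
  if (abs(q_hi) >= abs(q_lo)) q_hi else q_lo
}

#' Score a query signature against a perturbagen library
#'
#' Runs the full connectivity-map chain per perturbagen — weighted-KS
#' enrichment, WTCS, group-wise NCS, tau percentile against the library's
#' own NCS distribution — and summarizes taus across cell lines per
#' compound.
#'
#' @param lib Library from [perturbagen_library()].
#' @param up_set Up query genes (e.g. the hub signature).
#' @param down_set Optional down query genes.
#' @inheritParams weighted_ks_es
#' @return List with `perturbagen` (per-perturbagen tibble incl. `wtcs`,
#'   `ncs`, `tau`) and `compound` (per-compound tibble with `summary_tau`).
#' @export
connectivity_scores <- function(lib, up_set, down_set = NULL, weight_p = 1) {
  res <- lib$meta |>
    mutate(wtcs = map_dbl(.data$perturbagen_id, function(pid) {
      wtcs(lib$zscores[pid, ], up_set, down_set, weight_p)
    })) |>
    normalize_ncs()
  res$tau <- tau_percentile(res$ncs, res$ncs)
  summary <- res |>
    group_by(.data$compound, .data$type) |>
    summarise(summary_tau = summarize_across_cells(.data$tau),
              n_cell_lines = dplyr::n(), .groups = "drop") |>
    arrange(.data$summary_tau)
  list(perturbagen = res, compound = summary)
}

#' Select signature-reversing compounds
#'
#' Compounds whose summary tau falls at or below the threshold (strong
#' dissimilarity to the query signature), sorted most-negative first.
#'
#' @param compound_summary Tibble with `compound` and `summary_tau` (the
#'   `$compound` element of [connectivity_scores()]).
#' @param threshold Summary-tau cutoff (default -90).
#' @return Character vector of compound ids.
#' @export
select_reversers <- function(compound_summary, threshold = -90) {
  compound_summary |>
    filter(.data$summary_tau <= threshold) |>
    arrange(.data$summary_tau, .data$compound) |>
    pull("compound")
}
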