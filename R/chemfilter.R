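#' Tanimoto similarity between two fingerprints
#'
#' `|a AND b| / |a OR b|` over equal-length bit vectors; two all-zero
#' fingerprints are defined to have similarity 0 (with a warning).
#'
#' @param a,b Logical/0-1 vectors of equal length, or bitstrings like
#'   `"1100"`.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  a <- as_bits(a); b <- as_bits(b)
  if (length(a) != length(b)) abort("fingerprint length mismatch")
  un <- sum(a | b)
  if (un == 0) {
    warn("both fingerprints empty; similarity defined as 0")
    return(0)
  }
  sum(a & b) / un
}

as_bits <- function(x) {
  if (is.character(x) && length(x) == 1) {
    x <- as.integer(strsplit(x, "")[[1]])
  }
  if (!all(x %in% c(0, 1, TRUE, FALSE))) abort("fingerprints must be 0/1 bit vectors")
  as.logical(x)
}

#' All-pairs Tanimoto similarity against a reference drug set
#'
#' @param fps Named list of fingerprints (query compounds).
#' @param reference_fps Named list of fingerprints (reference drugs).
#' @param threshold Max-similarity cutoff for the `similar` flag; values
#'   below it mark low/moderate structural similarity.
#' @return List with `matrix` (query x reference similarities) and `flags`
#'   (tibble `compound`, `max_similarity`, `similar`).
#' @export
similarity_matrix <- function(fps, reference_fps, threshold = 0.7) {
  m <- matrix(NA_real_, length(fps), length(reference_fps),
              dimnames = list(names(fps), names(reference_fps)))
  for (i in seq_along(fps)) {
    for (j in seq_along(reference_fps)) {
      m[i, j] <- tanimoto(fps[[i]], reference_fps[[j]])
    }
  }
  flags <- tibble(compound = names(fps),
                  max_similarity = apply(m, 1, max),
                  similar = apply(m, 1, max) >= threshold)
  list(matrix = m, flags = flags)
}

#' Blood-brain-barrier permeability filter
#'
#' Two rules over a table with two per-platform BBB score columns:
#' `"at_least_reference"` keeps compounds scoring at or above the reference
#' compound (temozolomide in the study design) on both platforms;
#' `"top_k_intersection"` keeps compounds in the top k of both platforms
#' (descending scores, ties by average rank then compound id).
#'
#' @param scores Score tibble with `compound` plus two score columns.
#' @param score_cols Names of the two BBB score columns.
#' @param mode `"at_least_reference"` or `"top_k_intersection"`.
#' @param reference_compound Reference compound id (required for
#'   `"at_least_reference"`).
#' @param k Top-k cutoff for the intersection mode.
#' @param tolerance Slack subtracted from the reference scores
#'   ("comparable" permeability); default 0.
#' @return Character vector of passing compound ids.
#' @export
bbb_filter <- function(scores, score_cols = c("bbb_score_a", "bbb_score_b"),
                       mode = c("at_least_reference", "top_k_intersection"),
                       reference_compound = NULL, k = 30, tolerance = 0) {
  mode <- match.arg(mode)
  if (!all(score_cols %in% names(scores))) {
    abort(sprintf("score columns missing: %s",
                  paste(setdiff(score_cols, names(scores)), collapse = ", ")))
  }
  s1 <- scores[[score_cols[1]]]; s2 <- scores[[score_cols[2]]]
  if (mode == "at_least_reference") {
    if (is.null(reference_compound) || !reference_compound %in% scores$compound) {
      abort("reference compound missing from score table")
    }
    ref <- scores[scores$compound == reference_compound, ]
    pass <- s1 >= ref[[score_cols[1]]] - tolerance &
      s2 >= ref[[score_cols[2]]] - tolerance
  } else {
    ord1 <- order(rank(-s1, ties.method = "average"), scores$compound)
    ord2 <- order(rank(-s2, ties.method = "average"), scores$compound)
    top1 <- scores$compound[ord1][seq_len(min(k, nrow(scores)))]
    top2 <- scores$compound[ord2][seq_len(min(k, nrow(scores)))]
    pass <- scores$compound %in% intersect(top1, top2)
  }
  scores$compound[pass]
}

#' P-glycoprotein non-substrate consensus
#'
#' A compound passes only if all three predictor columns call it
#' `"non-substrate"`.
#'
#' @param calls Score tibble with `compound` and three categorical columns.
#' @param call_cols Names of the three predictor columns.
#' @return Character vector of consensus non-substrate compounds.
#' @export
pgp_consensus <- function(calls, call_cols = c("pgp_call_1", "pgp_call_2", "pgp_call_3")) {
  if (!all(call_cols %in% names(calls))) {
    abort(sprintf("P-gp call columns missing: %s",
                  paste(setdiff(call_cols, names(calls)), collapse = ", ")))
  }
  vals <- unlist(calls[call_cols], use.names = FALSE)
  if (anyNA(vals) || !all(vals %in% c("substrate", "non-substrate"))) {
    abort("P-gp calls must be 'substrate' or 'non-substrate'")
  }
  pass <- Reduce(`&`, lapply(call_cols, function(cc) calls[[cc]] == "non-substrate"))
  calls$compound[pass]
}

#' Literature co-occurrence filter
#'
#' Gene mode marks a term related when the article count exceeds 3; drug
#' mode when the sentence count exceeds 5 (both strict inequalities).
#'
#' @param counts Score tibble: `compound` (or `gene`) id column first, one
#'   numeric count column per term.
#' @param entity_kind `"gene"` (articles > 3) or `"drug"` (sentences > 5).
#' @return Tibble of logical flags, same id column, one column per term.
#' @export
cooccurrence_filter <- function(counts, entity_kind = c("gene", "drug")) {
  entity_kind <- match.arg(entity_kind)
  thr <- if (entity_kind == "gene") 3 else 5
  id_col <- names(counts)[1]
  num_cols <- setdiff(names(counts), id_col)
  if (any(vapply(counts[num_cols], function(x) any(x < 0), logical(1)))) {
    abort("negative co-occurrence counts")
  }
  out <- counts[id_col]
  for (cc in num_cols) out[[cc]] <- counts[[cc]] > thr
  as_tibble(out)
}

#' Run the drug-selection funnel
#'
#' Applies the study's selection stages in their fixed order: connectivity
#' reversal (summary tau at or below the threshold), BBB permeability,
#' optional literature co-occurrence annotation, P-gp non-substrate
#' consensus, and Tanimoto similarity annotation against reference drugs.
#' Compounds missing from a required table are carried with stage verdict
#' unknown and excluded from that stage's pass set.
#'
#' @param compound_summary Tibble `compound`, `summary_tau` (from
#'   [connectivity_scores()]).
#' @param bbb_scores BBB score tibble (see [bbb_filter()]).
#' @param pgp_calls P-gp call tibble (see [pgp_consensus()]).
#' @param fingerprints Named list of compound fingerprints.
#' @param reference_fps Named list of reference-drug fingerprints.
#' @param cooc_counts Optional co-occurrence count tibble (drug mode).
#' @param tau_threshold Reversal threshold (default -90).
#' @param bbb_mode,bbb_reference,bbb_k Passed to [bbb_filter()].
#' @param similarity_threshold Tanimoto flag threshold.
#' @return Object of class `drug_funnel`: list with `records` (one row per
#'   compound: verdicts per stage, `stage_reached`, `max_tanimoto`) and
#'   `counts` (survivors per stage).
#' @export
run_funnel <- function(compound_summary, bbb_scores, pgp_calls,
                       fingerprints, reference_fps, cooc_counts = NULL,
                       tau_threshold = -90,
                       bbb_mode = "at_least_reference",
                       bbb_reference = "temozolomide", bbb_k = 30,
                       similarity_threshold = 0.7) {
  records <- as_tibble(compound_summary)[c("compound", "summary_tau")]
  stages <- c("cmap", "bbb", "text", "pgp", "similarity")

  records$pass_cmap <- records$summary_tau <= tau_threshold
  survivors <- records$compound[records$pass_cmap]

  bbb_pass <- bbb_filter(bbb_scores, mode = bbb_mode,
                         reference_compound = bbb_reference, k = bbb_k)
  records$pass_bbb <- records$compound %in% bbb_pass &
    records$compound %in% bbb_scores$compound
  records$pass_bbb[!records$compound %in% bbb_scores$compound] <- NA
  survivors <- intersect(survivors, records$compound[records$pass_bbb %in% TRUE])
  bbb_survivors <- survivors

  if (!is.null(cooc_counts)) {
    flags <- cooccurrence_filter(cooc_counts, "drug")
    any_term <- apply(as.matrix(flags[-1]), 1, any)
    records$text_related <- records$compound %in% flags[[1]][any_term]
    records$text_related[!records$compound %in% flags[[1]]] <- NA
  } else {
    records$text_related <- NA
  }
  # co-occurrence is an annotation stage: it does not shrink the pass set

  pgp_pass <- pgp_consensus(pgp_calls)
  records$pass_pgp <- records$compound %in% pgp_pass
  records$pass_pgp[!records$compound %in% pgp_calls$compound] <- NA
  survivors <- intersect(survivors, records$compound[records$pass_pgp %in% TRUE])
  pgp_survivors <- survivors

  known <- records$compound %in% names(fingerprints)
  records$max_tanimoto <- NA_real_
  if (any(known) && length(reference_fps)) {
    sim <- similarity_matrix(fingerprints[records$compound[known]], reference_fps,
                             threshold = similarity_threshold)
    records$max_tanimoto[known] <- sim$flags$max_similarity
  }
  records$structurally_similar <- records$max_tanimoto >= similarity_threshold

  records$stage_reached <- dplyr::case_when(
    !(records$pass_cmap %in% TRUE) ~ "cmap",
    !(records$pass_bbb %in% TRUE) ~ "bbb",
    !(records$pass_pgp %in% TRUE) ~ "pgp",
    TRUE ~ "similarity")

  counts <- tibble(
    stage = c("input", "cmap", "bbb", "pgp"),
    survivors = c(nrow(records), sum(records$pass_cmap),
                  length(bbb_survivors), length(pgp_survivors)))
  out <- list(records = arrange(records, .data$summary_tau, .data$compound),
              counts = counts)
  class(out) <- "drug_funnel"
  out
}

#' @export
tidy.drug_funnel <- function(x, ...) x$records

#' @export
glance.drug_funnel <- function(x, ...) {
  tidyr::pivot_wider(x$counts, names_from = "stage", values_from = "survivors",
                     names_prefix = "n_")
}

#' @export
print.drug_funnel <- function(x, ...) {
  cat("Drug funnel survivors per stage:\n")
  print.data.frame(as.data.frame(x$counts), row.names = FALSE)
  invisible(x)
}
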