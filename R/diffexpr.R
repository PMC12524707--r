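#' Median-of-ratios size factors
#'
#' For genes expressed in every sample, each sample's factor is the median
#' ratio of its counts to the per-gene geometric mean; factors are rescaled
#' to geometric mean 1.
#'
#' @param cm Count matrix from [count_matrix()] (or a bare counts matrix).
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(cm) {
  counts <- if (is.list(cm)) cm$counts else cm
  expressed <- rowSums(counts > 0) == ncol(counts)
  if (!any(expressed)) {
    abort("no gene expressed in all samples; consider a pseudo-reference fallback")
  }
  ref <- exp(rowMeans(log(counts[expressed, , drop = FALSE])))
  f <- apply(counts[expressed, , drop = FALSE], 2, function(col) median(col / ref))
  f / exp(mean(log(f)))
}

#' Negative-binomial Wald test for two-condition differential expression
#'
#' A deliberately simple NB Wald test: counts are normalized by
#' median-of-ratios size factors; per-gene dispersion comes from a
#' method-of-moments estimate on normalized counts pooled within condition;
#' the log2 fold change uses a +0.5 pseudo-count; the standard error follows
#' the NB delta method
#' `SE^2 = (1/ln2)^2 * [ (1/n_A)(1/mu_A + alpha) + (1/n_B)(1/mu_B + alpha) ]`
#' and the Wald statistic `log2FC / SE` is referred to the standard normal.
#' P-values are Bonferroni-corrected over the tested genes; genes with
#' all-zero counts are excluded from testing and from the correction factor.
#'
#' With few replicates a raw per-gene moment estimate of the dispersion is
#' noisy enough to break Wald tail calibration, so the default moderation
#' takes the elementwise max of the per-gene estimate and the across-gene
#' median (conservative); `dispersion = "per-gene"` gives the raw estimate.
#'
#' @param cm Count matrix from [count_matrix()].
#' @param condition_a Which condition label is the numerator of the fold
#'   change (default: first level alphabetically).
#' @param dispersion `"moderated"` (default) or `"per-gene"`.
#' @param alpha_bounds Dispersion floor and ceiling.
#' @return Tibble: `gene`, `base_mean`, `log2fc`, `se`, `stat`, `p_value`,
#'   `p_adj`, `flag` (`"up"`, `"down"` or `"ns"`), `note`.
#' @export
de_test <- function(cm, condition_a = NULL,
                    dispersion = c("moderated", "per-gene"),
                    alpha_bounds = c(1e-8, 10)) {
  dispersion <- match.arg(dispersion)
  counts <- cm$counts
  cond <- cm$condition
  lv <- sort(unique(cond))
  condition_a <- condition_a %||% lv[1]
  if (!condition_a %in% lv) abort("condition_a not among condition labels")
  is_a <- cond == condition_a
  f <- size_factors(cm)
  norm <- sweep(counts, 2, f, "/")

  tested <- rowSums(counts) > 0
  untested <- rownames(counts)[!tested]
  norm <- norm[tested, , drop = FALSE]

  n_a <- sum(is_a); n_b <- sum(!is_a)
  mu_a <- rowMeans(norm[, is_a, drop = FALSE])
  mu_b <- rowMeans(norm[, !is_a, drop = FALSE])
  v_a <- apply(norm[, is_a, drop = FALSE], 1, var)
  v_b <- apply(norm[, !is_a, drop = FALSE], 1, var)
  # pooled within-condition method-of-moments: var = mu + alpha mu^2
  mom <- function(v, mu) ifelse(mu > 0, (v - mu) / mu^2, NA_real_)
  a_pool <- ((n_a - 1) * mom(v_a, mu_a) + (n_b - 1) * mom(v_b, mu_b)) / (n_a + n_b - 2)
  a_pool[is.na(a_pool)] <- 0
  if (dispersion == "moderated") {
    a_med <- median(a_pool[a_pool > 0])
    if (is.na(a_med)) a_med <- 0
    a_pool <- pmax(a_pool, a_med)
  }
  alpha <- pmin(pmax(a_pool, alpha_bounds[1]), alpha_bounds[2])

  shifted <- mu_a == 0 | mu_b == 0
  log2fc <- log2((mu_a + 0.5) / (mu_b + 0.5))
  se <- sqrt((1 / log(2))^2 *
               ((1 / n_a) * (1 / (mu_a + 0.5) + alpha) +
                (1 / n_b) * (1 / (mu_b + 0.5) + alpha)))
  stat <- log2fc / se
  p <- 2 * pnorm(-abs(stat))
  m <- sum(tested)
  padj <- pmin(1, m * p)
  res <- tibble(
    gene = rownames(norm),
    base_mean = unname((mu_a + mu_b) / 2),
    log2fc = unname(log2fc), se = unname(se), stat = unname(stat),
    p_value = unname(p), p_adj = unname(padj),
    flag = unname(dplyr::case_when(padj < 0.05 & log2fc >= 1 ~ "up",
                                   padj < 0.05 & log2fc <= -1 ~ "down",
                                   TRUE ~ "ns")),
    note = unname(ifelse(shifted, "half-shifted", ""))
  )
  attr(res, "untested") <- untested
  attr(res, "condition_a") <- condition_a
  res
}

#' Select significantly upregulated genes
#'
#' Genes with Bonferroni-adjusted p < 0.05 and log2 fold change >= 1,
#' ordered by adjusted p then gene id.
#'
#' @param results Tibble from [de_test()].
#' @param p_adj_max Adjusted-p threshold.
#' @param log2fc_min Fold-change threshold (log2 scale).
#' @return Character vector of gene ids.
#' @export
select_upregulated <- function(results, p_adj_max = 0.05, log2fc_min = 1) {
  results |>
    filter(.data$p_adj < p_adj_max, .data$log2fc >= log2fc_min) |>
    arrange(.data$p_adj, .data$gene) |>
    pull("gene")
}
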