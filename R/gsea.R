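# Signal-to-noise ratio per gene between two groups, with the classic
# GSEA standard-deviation floor: sd is bounded below by 0.2 * |mean|
# (0.2 when the mean is zero) so near-constant genes do not dominate.
signal_to_noise <- function(expr, is_a) {
  mu_a <- rowMeans(expr[, is_a, drop = FALSE])
  mu_b <- rowMeans(expr[, !is_a, drop = FALSE])
  sd_a <- apply(expr[, is_a, drop = FALSE], 1, sd)
  sd_b <- apply(expr[, !is_a, drop = FALSE], 1, sd)
  floor_sd <- function(s, mu) pmax(s, ifelse(mu == 0, 0.2, 0.2 * abs(mu)))
  (mu_a - mu_b) / (floor_sd(sd_a, mu_a) + floor_sd(sd_b, mu_b))
}

# Weighted Kolmogorov-Smirnov enrichment score for many sets at once.
# metric: named per-gene statistic; member: genes x sets logical matrix
# aligned to names(metric). Returns one signed maximum-deviation ES per set.
weighted_ks_many <- function(metric, member, weight_p = 1) {
  ord <- order(-metric, names(metric))
  w <- abs(metric[ord])^weight_p
  ind <- member[ord, , drop = FALSE]
  n <- length(metric)
  m <- colSums(ind)
  hit_w <- ind * w
  tot <- colSums(hit_w)
  tot[tot == 0] <- 1  # all-zero weights: hits contribute equally below
  hit_cum <- apply(hit_w, 2, cumsum)
  hit_cum <- sweep(hit_cum, 2, tot, "/")
  zero_tot <- colSums(ind * w) == 0
  if (any(zero_tot)) {
    eq <- sweep(apply(ind[, zero_tot, drop = FALSE], 2, cumsum), 2, m[zero_tot], "/")
    hit_cum[, zero_tot] <- eq
  }
  miss_cum <- sweep(apply(!ind, 2, cumsum), 2, n - m, "/")
  dev <- hit_cum - miss_cum
  apply(dev, 2, function(d) d[which.max(abs(d))])
}

#' Two-group gene set enrichment analysis with a permutation null
#'
#' Genes are ranked by the signal-to-noise ratio between the two sample
#' groups; each set's enrichment score (ES) is the signed maximum deviation
#' of the weighted Kolmogorov-Smirnov running sum (hit increments
#' proportional to `|metric|^weight_p` normalized over the set, miss
#' decrements `1/(N - m)`). Significance comes from a seeded permutation
#' null: phenotype (label) permutation when both groups have >= 3 samples,
#' gene-set permutation otherwise. NES divides ES by the mean same-sign
#' permutation ES; the nominal p-value is the same-sign permutation tail
#' fraction; FDR q follows the standard same-sign NES ratio procedure.
#'
#' @param expr Genes x samples expression matrix.
#' @param labels Character/factor vector, one of two group labels per sample
#'   (named by sample or in column order).
#' @param sets Named list of gene sets.
#' @param n_perm Number of permutations (>= 10).
#' @param seed Integer seed; fully determines the permutation stream.
#' @param weight_p Hit-weight exponent (1 = classic weighted statistic).
#' @return Tibble: `set`, `size`, `es`, `nes`, `p_value`, `fdr_q`,
#'   `direction` (the group label the set is enriched in).
#' @export
gsea_two_group <- function(expr, labels, sets, n_perm = 1000, seed = 1,
                           weight_p = 1) {
  if (n_perm < 10) abort("n_perm must be at least 10")
  if (!is.null(names(labels))) labels <- labels[colnames(expr)]
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2) abort("labels must contain exactly two groups")
  is_a <- labels == lv[1]
  if (all(apply(expr, 1, sd) == 0)) abort("all genes have zero variance")
  genes <- toupper(rownames(expr))
  rn <- rownames(expr); rownames(expr) <- genes
  member <- vapply(sets, function(s) genes %in% toupper(s),
                   logical(length(genes)))
  member <- matrix(member, ncol = length(sets),
                   dimnames = list(genes, names(sets)))
  if (any(colSums(member) < 2)) {
    abort("every set must share >= 2 genes with the matrix")
  }

  metric <- signal_to_noise(expr, is_a)
  names(metric) <- genes
  es_obs <- weighted_ks_many(metric, member, weight_p)

  set.seed(seed)
  phenotype_perm <- sum(is_a) >= 3 && sum(!is_a) >= 3
  es_perm <- matrix(NA_real_, n_perm, length(sets),
                    dimnames = list(NULL, names(sets)))
  if (phenotype_perm) {
    for (t in seq_len(n_perm)) {
      perm_a <- seq_len(ncol(expr)) %in% sample(ncol(expr), sum(is_a))
      pm <- signal_to_noise(expr, perm_a)
      names(pm) <- genes
      es_perm[t, ] <- weighted_ks_many(pm, member, weight_p)
    }
  } else {
    for (t in seq_len(n_perm)) {
      shuffled <- member[sample(nrow(member)), , drop = FALSE]
      rownames(shuffled) <- genes
      es_perm[t, ] <- weighted_ks_many(metric, shuffled, weight_p)
    }
  }

  norm_one <- function(es, perms) {
    same <- perms[sign(perms) == sign(es) & perms != 0]
    if (sign(es) == 0 || length(same) == 0) return(c(nes = 0, p = 1))
    nes <- es / mean(abs(same))
    p <- (sum(abs(same) >= abs(es)) + 1) / (length(same) + 1)
    c(nes = nes, p = p)
  }
  np <- t(vapply(seq_along(es_obs),
                 function(k) norm_one(es_obs[k], es_perm[, k]),
                 c(nes = 0, p = 0)))
  nes <- np[, "nes"]; pval <- np[, "p"]

  # permutation NES pool for the FDR ratio
  nes_perm <- es_perm
  for (k in seq_along(es_obs)) {
    pos <- es_perm[, k] > 0; neg <- es_perm[, k] < 0
    mp <- mean(es_perm[pos, k]); mn <- mean(abs(es_perm[neg, k]))
    nes_perm[pos, k] <- es_perm[pos, k] / ifelse(is.nan(mp), 1, mp)
    nes_perm[neg, k] <- es_perm[neg, k] / ifelse(is.nan(mn), 1, mn)
  }
  pool <- as.vector(nes_perm)
  fdr <- vapply(nes, function(v) {
    if (v == 0) return(1)
    if (v > 0) {
      num <- if (any(pool > 0)) mean(pool[pool > 0] >= v) else 0
      den <- sum(nes >= v) / max(sum(nes > 0), 1)
    } else {
      num <- if (any(pool < 0)) mean(pool[pool < 0] <= v) else 0
      den <- sum(nes <= v) / max(sum(nes < 0), 1)
    }
    min(1, num / max(den, 1e-12))
  }, numeric(1))

  tibble(set = names(sets),
         size = colSums(member),
         es = unname(es_obs),
         nes = unname(nes),
         p_value = unname(pval),
         fdr_q = unname(fdr),
         direction = unname(ifelse(es_obs >= 0, lv[1], lv[2])))
}
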