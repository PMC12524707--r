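# Unsigned weighted adjacency: |Pearson cor|^beta with zero diagonal.
adjacency_matrix <- function(expr, beta) {
  sds <- apply(expr, 1, sd)
  if (any(sds == 0)) {
    abort(sprintf("constant-expression gene(s): %s",
                  paste(head(rownames(expr)[sds == 0], 5), collapse = ", ")))
  }
  a <- abs(cor(t(expr)))^beta
  diag(a) <- 0
  a
}

#' Soft-threshold selection for approximate scale-free topology
#'
#' For each candidate power, builds the unsigned weighted adjacency
#' `|cor|^beta`, computes per-gene connectivity `k`, and regresses
#' `log10(frequency)` on `log10(k)` over 10 connectivity bins. The selected
#' power is the smallest whose scale-free fit R-squared reaches `target_r2`;
#' if none does, the argmax is returned with a warning.
#'
#' @param expr Genes x samples expression matrix (>= 20 genes).
#' @param betas Candidate powers.
#' @param target_r2 Scale-free fit threshold.
#' @return List with `report` (tibble: `beta`, `r_squared`,
#'   `mean_connectivity`) and `beta` (the selected power).
#' @export
pick_soft_threshold <- function(expr, betas = c(1:10, 12, 14, 16, 18, 20),
                                target_r2 = 0.8) {
  if (nrow(expr) < 20) abort("need at least 20 genes to assess scale-free fit")
  fit_one <- function(beta) {
    a <- adjacency_matrix(expr, beta)
    k <- rowSums(a)
    brk <- seq(min(k), max(k), length.out = 11)
    bin <- cut(k, breaks = brk, include.lowest = TRUE)
    freq <- tabulate(bin, nbins = 10)
    centers <- (brk[-11] + brk[-1]) / 2
    keep <- freq > 0 & centers > 0
    r2 <- if (sum(keep) >= 3) {
      cor(log10(freq[keep]), log10(centers[keep]))^2
    } else NA_real_
    c(r2 = r2, meank = mean(k))
  }
  stats <- t(vapply(betas, fit_one, c(r2 = 0, meank = 0)))
  report <- tibble(beta = betas, r_squared = stats[, "r2"],
                   mean_connectivity = stats[, "meank"])
  ok <- which(!is.na(report$r_squared) & report$r_squared >= target_r2)
  if (length(ok)) {
    sel <- report$beta[ok[1]]
  } else {
    sel <- report$beta[which.max(report$r_squared)]
    warn(sprintf("no candidate power reaches scale-free R^2 %.2f; using argmax (beta = %g)",
                 target_r2, sel))
  }
  list(report = report, beta = sel)
}

#' Topological overlap matrix
#'
#' From the unsigned adjacency `a = |cor|^beta`, the topological overlap of
#' genes i and j is `(l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `l_ij = sum_u a_iu a_uj` counts shared neighbourhood weight and `k` is
#' connectivity; the diagonal is 1. Returned as the overlap matrix; the
#' clustering input is its dissimilarity `1 - tom`.
#'
#' @param expr Genes x samples expression matrix.
#' @param beta Soft-threshold power.
#' @return Symmetric genes x genes matrix in \[0, 1\] with unit diagonal.
#' @export
compute_tom <- function(expr, beta = 12) {
  a <- adjacency_matrix(expr, beta)
  k <- rowSums(a)
  l <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- list(rownames(expr), rownames(expr))
  tom
}

#' Detect co-expression modules by static tree cut
#'
#' Average-linkage hierarchical clustering of the topological-overlap
#' dissimilarity, cut at a fixed height; clusters smaller than
#' `min_module_size` are left unassigned (module 0). Modules are numbered by
#' decreasing size.
#'
#' @param dissim Square symmetric dissimilarity matrix (e.g.
#'   `1 - compute_tom(...)`).
#' @param min_module_size Minimum genes per module.
#' @param cut_height Tree cut height.
#' @return Tibble `gene`, `module` (integer, 0 = unassigned).
#' @export
detect_modules <- function(dissim, min_module_size = 30, cut_height = 0.995) {
  if (!isTRUE(all.equal(dissim, t(dissim), tolerance = 1e-8))) {
    abort("dissimilarity must be symmetric")
  }
  hc <- hclust(as.dist(dissim), method = "average")
  raw <- cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  lab <- integer(length(raw))
  if (length(keep)) {
    kept_sizes <- sizes[as.character(keep)]
    ord <- keep[order(-kept_sizes, keep)]
    for (i in seq_along(ord)) lab[raw == ord[i]] <- i
  }
  tibble(gene = rownames(dissim), module = lab)
}

#' Module eigengenes
#'
#' Each module's eigengene is the first principal component of its members'
#' standardized expression: one value per sample, scaled to unit variance
#' and sign-oriented so the mean correlation with member genes is positive.
#'
#' @param expr Genes x samples expression matrix.
#' @param assignment Tibble from [detect_modules()] (module 0 ignored).
#' @return Modules x samples matrix (rownames `"ME1"`, `"ME2"`, ...).
#' @export
module_eigengenes <- function(expr, assignment) {
  mods <- sort(unique(assignment$module[assignment$module > 0]))
  if (!length(mods)) abort("no assigned modules")
  me <- matrix(NA_real_, length(mods), ncol(expr),
               dimnames = list(paste0("ME", mods), colnames(expr)))
  for (i in seq_along(mods)) {
    genes <- assignment$gene[assignment$module == mods[i]]
    x <- expr[genes, , drop = FALSE]
    if (nrow(x) == 1) {
      warn(sprintf("module %d has a single gene; eigengene = standardized gene", mods[i]))
      e <- as.vector(scale(x[1, ]))
    } else {
      xs <- t(scale(t(x)))  # standardize each gene across samples
      sv <- svd(xs, nu = 0, nv = 1)
      e <- sv$v[, 1]
      e <- e / sd(e)
    }
    if (mean(cor(e, t(x))) < 0) e <- -e
    me[i, ] <- e
  }
  me
}

#' Merge similar modules by eigengene correlation
#'
#' Average-linkage clustering of eigengene dissimilarity `1 - cor`; clusters
#' closer than `merge_height` are merged and eigengenes recomputed. Raising
#' the merge height never increases the module count.
#'
#' @param expr Genes x samples expression matrix.
#' @param assignment Tibble from [detect_modules()].
#' @param merge_height Eigengene dissimilarity below which modules merge.
#' @return List with `assignment` (tibble) and `eigengenes` (matrix).
#' @export
merge_modules <- function(expr, assignment, merge_height = 0.25) {
  me <- module_eigengenes(expr, assignment)
  if (nrow(me) < 2) {
    return(list(assignment = assignment, eigengenes = me))
  }
  d <- 1 - cor(t(me))
  hc <- hclust(as.dist(d), method = "average")
  grp <- cutree(hc, h = merge_height)
  mods <- as.integer(sub("^ME", "", rownames(me)))
  new_lab <- assignment$module
  # merged groups renumbered by total size, largest first
  sizes <- vapply(unique(grp), function(g) {
    sum(assignment$module %in% mods[grp == g])
  }, numeric(1))
  ord <- unique(grp)[order(-sizes, unique(grp))]
  for (i in seq_along(ord)) {
    new_lab[assignment$module %in% mods[grp == ord[i]]] <- i
  }
  out <- tibble(gene = assignment$gene, module = new_lab)
  list(assignment = out, eigengenes = module_eigengenes(expr, out))
}

#' Module-trait correlation
#'
#' Pearson correlation between each module eigengene and each trait, with
#' two-sided p-values from the t distribution on n - 2 degrees of freedom.
#' Supports picking the module most positively correlated with a trait (the
#' GMT-associated module selection step).
#'
#' @param eigengenes Modules x samples matrix from [module_eigengenes()].
#' @param traits Tibble with `sample_id` plus one column per trait, or a
#'   named list of per-sample score tibbles (`sample_id`, `score`).
#' @return Tibble `module`, `trait`, `r`, `p_value`.
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  if (is.list(traits) && !is.data.frame(traits)) {
    traits <- purrr::reduce(
      imap(traits, ~ setNames(.x[c("sample_id", "score")], c("sample_id", .y))),
      dplyr::full_join, by = "sample_id")
  }
  traits <- as_tibble(traits)
  common <- intersect(colnames(eigengenes), traits$sample_id)
  if (length(common) < 3) abort("fewer than 3 overlapping samples")
  tm <- as.matrix(traits[match(common, traits$sample_id), -1, drop = FALSE])
  em <- eigengenes[, common, drop = FALSE]
  n <- length(common)
  out <- tidyr::expand_grid(module = rownames(eigengenes),
                            trait = colnames(tm))
  out$r <- purrr::map2_dbl(out$module, out$trait,
                           ~ cor(em[.x, ], tm[, .y]))
  tstat <- out$r * sqrt((n - 2) / pmax(1 - out$r^2, 1e-300))
  out$p_value <- 2 * stats::pt(-abs(tstat), df = n - 2)
  out
}
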