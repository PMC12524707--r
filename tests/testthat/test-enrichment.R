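make_expr <- function(n_genes = 20, n_samples = 6, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
         dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                         sprintf("s%d", seq_len(n_samples))))
}

test_that("ssGSEA matches the hand-evaluated running sum on the 4-gene toy", {
  expr <- matrix(c(4, 3, 2, 1), 4, 2,
                 dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
  # set containing the top two genes at alpha 0: symmetric around the
  # single-gene hand example; checked against the brute-force oracle
  sc <- ssgsea_scores(expr, list(top = c("A", "B"), bottom = c("C", "D")),
                      alpha = 0)
  expect_equal(sc$score[sc$set == "top"], c(2, 2))
  expect_equal(sc$score[sc$set == "bottom"], c(-2, -2))
})

test_that("ssGSEA equals the brute-force oracle on random data", {
  expr <- make_expr(30, 5)
  sets <- list(S1 = rownames(expr)[c(1, 5, 9, 20)],
               S2 = rownames(expr)[25:30])
  for (alpha in c(0, 0.25, 1)) {
    sc <- ssgsea_scores(expr, sets, alpha = alpha)
    for (j in colnames(expr)) {
      for (s in names(sets)) {
        expect_equal(sc$score[sc$sample_id == j & sc$set == s],
                     oracle_ssgsea(expr[, j], rownames(expr), sets[[s]], alpha),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("ssGSEA is rank-based: invariant to monotone transforms, deterministic on ties", {
  expr <- make_expr(25, 4)
  sets <- list(S = rownames(expr)[3:9])
  base <- ssgsea_scores(expr, sets, alpha = 0.25)
  warped <- ssgsea_scores(exp(expr / 2), sets, alpha = 0.25)
  expect_equal(base$score, warped$score, tolerance = 1e-12)
  # identical samples get identical scores
  expr2 <- cbind(expr, dup = expr[, 1])
  sc2 <- ssgsea_scores(expr2, sets, alpha = 0.25)
  expect_equal(sc2$score[sc2$sample_id == "dup"],
               sc2$score[sc2$sample_id == "s1"])
})

test_that("ssGSEA rejects degenerate sets", {
  expr <- make_expr(10, 3)
  expect_error(ssgsea_scores(expr, list(S = c("G01", "NOPE"))), "fewer than 2")
  expect_error(ssgsea_scores(expr, list(S = rownames(expr))), "every matrix gene")
})

test_that("GMT score is mesenchymal minus proneural and antisymmetric", {
  expr <- make_expr(40, 8)
  mes <- rownames(expr)[1:8]; pn <- rownames(expr)[9:16]
  sc <- ssgsea_scores(expr, list(m = mes, p = pn), alpha = 0.25)
  g <- gmt_score(expr, mes, pn, alpha = 0.25)
  expect_equal(g$score,
               sc$score[sc$set == "m"] - sc$score[sc$set == "p"])
  swapped <- gmt_score(expr, pn, mes, alpha = 0.25)
  expect_equal(swapped$score, -g$score)
  same <- gmt_score(expr, mes, mes, alpha = 0.25)
  expect_equal(same$score, rep(0, 8))
})

test_that("GMT score separates planted mesenchymal and proneural programs", {
  sim <- gen_bulk_cohort(n_samples = 100, n_genes = 400, n_sig = 40,
                         module_size = 40, lambda = 1, sigma = 0.5, seed = 7)
  g <- gmt_score(sim$expr, sim$mes_set, sim$pn_set)
  expect_gt(cor(g$score, sim$truth$g), 0.8)
})

test_that("median stratification follows the tie-to-low rule", {
  sc <- tibble::tibble(sample_id = paste0("s", 1:4), score = c(1, 2, 2, 4))
  out <- stratify_by_median(sc)
  expect_identical(out$group, c("low", "low", "low", "high"))
  even <- stratify_by_median(tibble::tibble(sample_id = paste0("s", 1:4),
                                            score = c(1, 2, 3, 4)))
  expect_identical(even$group, c("low", "low", "high", "high"))
  expect_error(stratify_by_median(tibble::tibble(sample_id = "a", score = 1)),
               "at least 2")
  expect_error(stratify_by_median(tibble::tibble(sample_id = c("a", "b"),
                                                 score = c(1, 1))), "degenerate")
})

test_that("immune enrichment recovers a planted immune program", {
  set.seed(11)
  expr <- make_expr(60, 10, seed = 11)
  immune_sets <- list(Tcell = rownames(expr)[1:10],
                      Bcell = rownames(expr)[11:20],
                      NK = rownames(expr)[21:30])
  # samples 1-5 overexpress the T-cell program
  expr[1:10, 1:5] <- expr[1:10, 1:5] + 3
  sc <- immune_enrichment(expr, immune_sets)
  mean_by_type <- tapply(sc$score[sc$sample_id %in% paste0("s", 1:5)],
                         sc$cell_type[sc$sample_id %in% paste0("s", 1:5)], mean)
  expect_identical(names(which.max(mean_by_type)), "Tcell")
})
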