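# cohort with two independent planted co-expression blocks and noise genes
two_block_expr <- function(n_per_block = 50, n_noise = 60, n_samples = 80,
                           within_cor = 0.8, seed = 1) {
  set.seed(seed)
  rho <- sqrt(within_cor / (1 - within_cor))  # factor loading giving the target cor
  f1 <- rnorm(n_samples); f2 <- rnorm(n_samples)
  block <- function(f, prefix) {
    m <- t(sapply(seq_len(n_per_block), function(i) rho * f + rnorm(n_samples)))
    rownames(m) <- sprintf("%s%03d", prefix, seq_len(n_per_block))
    m
  }
  noise <- matrix(rnorm(n_noise * n_samples), n_noise,
                  dimnames = list(sprintf("NSE%03d", seq_len(n_noise)), NULL))
  expr <- rbind(block(f1, "BLKA"), block(f2, "BLKB"), noise)
  colnames(expr) <- sprintf("s%03d", seq_len(n_samples))
  expr
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

test_that("TOM matches the triple-loop oracle and stays within bounds", {
  set.seed(2)
  expr <- matrix(rnorm(20 * 15), 20, 15,
                 dimnames = list(sprintf("G%02d", 1:20), sprintf("s%d", 1:15)))
  tom <- compute_tom(expr, beta = 6)
  expect_lt(max(abs(tom - oracle_tom(expr, 6))), 1e-10)
  expect_equal(tom, t(tom))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_equal(unname(diag(tom)), rep(1, 20))
})

test_that("perfectly correlated genes have unit adjacency and TOM", {
  s <- seq_len(10)
  expr <- rbind(g1 = s, g2 = 2 * s + 3, g3 = 0.5 * s - 1)
  colnames(expr) <- paste0("x", s)
  tom <- compute_tom(expr, beta = 12)
  expect_equal(unname(tom), matrix(1, 3, 3))
  expect_error(compute_tom(rbind(expr, g4 = rep(1, 10)), 12), "constant")
})

test_that("soft-threshold selection finds structure but warns on iid data", {
  blocks <- two_block_expr(seed = 3)
  # structured data may still miss the strict 0.8 bar at this size; either
  # branch must return a well-formed report with the selected power
  sel <- suppressWarnings(pick_soft_threshold(blocks, betas = c(1, 2, 4, 6, 8, 12)))
  expect_true(sel$beta %in% c(1, 2, 4, 6, 8, 12))
  expect_true(all(sel$report$r_squared <= 1, na.rm = TRUE))

  set.seed(4)
  iid <- matrix(rnorm(40 * 30), 40, 30,
                dimnames = list(sprintf("G%02d", 1:40), sprintf("s%d", 1:30)))
  expect_warning(pick_soft_threshold(iid, betas = c(1, 2), target_r2 = 0.995),
                 "argmax")
})

test_that("planted modules are recovered and noise genes left unassigned", {
  expr <- two_block_expr(seed = 5)
  tom <- compute_tom(expr, beta = 6)
  mods <- detect_modules(1 - tom, min_module_size = 30, cut_height = 0.995)
  expect_identical(sort(unique(mods$module)), c(0L, 1L, 2L))
  for (prefix in c("BLKA", "BLKB")) {
    planted <- grep(prefix, mods$gene, value = TRUE)
    lab <- mods$module[mods$gene %in% planted]
    main <- as.integer(names(which.max(table(lab))))
    detected <- mods$gene[mods$module == main]
    expect_gte(jaccard(planted, detected), 0.9)
  }
  noise_labels <- mods$module[grepl("NSE", mods$gene)]
  expect_gte(mean(noise_labels == 0), 0.9)
})

test_that("oversized minimum module size leaves everything unassigned", {
  expr <- two_block_expr(n_per_block = 20, n_noise = 10, seed = 6)
  tom <- compute_tom(expr, beta = 6)
  mods <- detect_modules(1 - tom, min_module_size = 1000)
  expect_true(all(mods$module == 0))
  expect_error(detect_modules(matrix(c(0, 1, 0.5, 0), 2, 2,
                                     dimnames = list(c("a", "b"), c("a", "b")))),
               "symmetric")
})

test_that("eigengenes are unit-variance, sign-oriented, PC-optimal", {
  expr <- two_block_expr(seed = 7)
  tom <- compute_tom(expr, beta = 6)
  mods <- detect_modules(1 - tom, min_module_size = 30)
  me <- module_eigengenes(expr, mods)
  expect_equal(unname(apply(me, 1, sd)), rep(1, nrow(me)), tolerance = 1e-8)
  for (i in seq_len(nrow(me))) {
    members <- mods$gene[mods$module == i]
    cors <- cor(me[i, ], t(expr[members, ]))
    expect_gt(mean(cors), 0)
    # eigengene explains at least as much member variance as any single member
    r2_eig <- mean(cors^2)
    r2_best_gene <- max(vapply(members, function(g) {
      mean(cor(expr[g, ], t(expr[members, ]))^2)
    }, numeric(1)))
    expect_gte(r2_eig + 1e-8, r2_best_gene)
  }
  # flipping all member genes changes nothing after sign orientation
  flipped <- expr
  flipped[mods$gene[mods$module == 1], ] <- -flipped[mods$gene[mods$module == 1], ]
  me_f <- module_eigengenes(flipped, mods)
  expect_equal(abs(cor(me_f[1, ], me[1, ])), 1, tolerance = 1e-8)
})

test_that("module merging follows the eigengene-correlation rule and is idempotent", {
  set.seed(8)
  n <- 60
  f <- rnorm(n)
  mk <- function(prefix, loading, k = 35) {
    m <- t(sapply(seq_len(k), function(i) loading * f + rnorm(n, sd = 0.4)))
    rownames(m) <- sprintf("%s%03d", prefix, seq_len(k))
    m
  }
  # two modules sharing one driver (eigengene cor ~ 0.9) and one independent
  g <- rnorm(n)
  expr <- rbind(mk("MA", 2), mk("MB", 2),
                t(sapply(1:35, function(i) 2 * g + rnorm(n, sd = 0.4))))
  rownames(expr)[71:105] <- sprintf("MC%03d", 1:35)
  colnames(expr) <- sprintf("s%d", seq_len(n))
  assignment <- tibble::tibble(gene = rownames(expr),
                               module = rep(1:3, each = 35))
  merged <- merge_modules(expr, assignment, merge_height = 0.25)
  expect_identical(length(unique(merged$assignment$module)), 2L)
  again <- merge_modules(expr, merged$assignment, merge_height = 0.25)
  expect_identical(again$assignment$module, merged$assignment$module)
  # raising merge height never increases module count
  high <- merge_modules(expr, assignment, merge_height = 0.8)
  expect_lte(length(unique(high$assignment$module)),
             length(unique(merged$assignment$module)))
})

test_that("module-trait correlation has exact r = 1 self-test and planted recovery", {
  expr <- two_block_expr(seed = 9)
  tom <- compute_tom(expr, beta = 6)
  mods <- detect_modules(1 - tom, min_module_size = 30)
  me <- module_eigengenes(expr, mods)
  self <- tibble::tibble(sample_id = colnames(expr), score = me[1, ])
  mtc <- module_trait_correlation(me, self)
  expect_equal(mtc$r[mtc$module == "ME1"], 1, tolerance = 1e-10)
  expect_lt(mtc$p_value[mtc$module == "ME1"], 1e-12)
  expect_error(module_trait_correlation(me[, 1:2],
                                        self[1:2, ]), "3 overlapping")
})
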