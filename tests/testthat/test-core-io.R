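test_that("TSV and GCT expression round-trips preserve values and order", {
  expr <- matrix(rnorm(12), 3, 4,
                 dimnames = list(c("TP53", "EGFR", "VIM"), paste0("s", 1:4)))
  for (fmt in c("tsv", "gct")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_expression_matrix(expr, path, format = fmt)
    back <- read_expression_matrix(path, format = fmt)
    expect_identical(rownames(back), rownames(expr))
    expect_identical(colnames(back), colnames(expr))
    expect_lt(max(abs(back - expr)), 1e-12)
  }
})

test_that("GCT header/body dimension mismatch is a format error", {
  path <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.2", "5\t2", "Name\tDescription\ts1\ts2",
               paste0("g", 1:4, "\tg\t1\t2")), path)
  expect_error(read_expression_matrix(path, "gct"), "dimension mismatch")
})

test_that("matrix validation drops NA genes, collapses duplicates, enforces minima", {
  m <- matrix(1:8, 4, 2, dimnames = list(c("A", "B", "B", "C"), c("s1", "s2")))
  m["A", 1] <- NA
  expect_warning(expect_warning(out <- as_expression_matrix(m),
                                "missing"), "duplicate")
  expect_setequal(rownames(out), c("B", "C"))
  expect_equal(out["B", ], colMeans(matrix(c(2, 3, 6, 7), 2, byrow = FALSE)),
               ignore_attr = TRUE)
  expect_error(as_expression_matrix(matrix(1, 1, 2, dimnames = list("A", c("x", "y")))),
               "at least 2 genes")
})

test_that("gene-set reader canonicalizes case, rejects short lines, round-trips", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SET1\tfirst\ta2m\tA2m\tTP53", "SET2\tsecond\tVIM\tFN1"), path)
  sets <- read_gene_sets(path)
  expect_length(sets, 2)
  expect_identical(sets$SET1, c("A2M", "TP53"))
  out <- withr::local_tempfile(fileext = ".gmt")
  write_gene_sets(sets, out)
  expect_identical(read_gene_sets(out)[], sets[])

  bad <- withr::local_tempfile()
  writeLines("SETX\tdesc", bad)
  expect_error(read_gene_sets(bad), "line 1")
})

test_that("edge list reader filters strictly, rescales STRING scores, drops self-loops", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("node_a\tnode_b\tcombined_score",
               "A\tB\t900", "B\tC\t700", "C\tD\t500", "A\tA\t990"), path)
  g <- suppressWarnings(read_edge_list(path, min_confidence = 0.7))
  el <- igraph::as_data_frame(g)
  expect_equal(nrow(el), 1)  # only 0.9 is strictly > 0.7
  expect_equal(el$confidence, 0.9)

  # raising the threshold never adds edges (monotone)
  counts <- vapply(c(0, 0.4, 0.6, 0.85),
                   function(th) igraph::ecount(suppressWarnings(
                     read_edge_list(path, min_confidence = th))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("survival/score table validation enforces typing", {
  path <- withr::local_tempfile()
  writeLines(c("sample_id\ttime\tevent", "s1\t-1\t1"), path)
  expect_error(read_survival_table(path), "positive")
  path2 <- withr::local_tempfile()
  writeLines(c("compound\tbbb_score_a", "x\t1", "x\t2"), path2)
  expect_error(read_score_table(path2), "duplicate")
})

test_that("signature library round-trips and checks metadata coverage", {
  set.seed(1)
  z <- matrix(rnorm(30), 3, 10,
              dimnames = list(paste0("p", 1:3), paste0("G", 1:10)))
  meta <- tibble::tibble(perturbagen_id = paste0("p", 1:3),
                         compound = c("a", "a", "b"),
                         cell_line = c("c1", "c2", "c1"), type = "compound")
  lib <- perturbagen_library(z, meta)
  gct <- withr::local_tempfile(fileext = ".gct")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_signature_library(lib, gct, tsv)
  back <- read_signature_library(gct, tsv)
  expect_lt(max(abs(back$zscores - lib$zscores)), 1e-12)
  expect_identical(back$meta$compound, lib$meta$compound)
  expect_error(perturbagen_library(z, meta[1:2, ]), "rows")
})

test_that("log-CPM normalization matches its formula and is scale invariant", {
  counts <- matrix(c(999999, 1, 50, 50, 0, 0), 3, 2, byrow = TRUE,
                   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  ln <- lognorm_counts(counts)
  expect_equal(ln["g1", "s1"], log2(1e6 * 999999 / 1000049 + 1))
  expect_equal(unname(ln["g3", ]), c(0, 0))
  # doubling a sample's counts leaves its log-CPM unchanged
  doubled <- counts; doubled[, 1] <- doubled[, 1] * 2
  expect_equal(lognorm_counts(doubled)[, 1], ln[, 1])
  bad <- counts; bad[, 2] <- 0
  expect_error(lognorm_counts(bad), "s2")
})
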