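graph_from_edges <- function(...) {
  igraph::graph_from_data_frame(
    as.data.frame(matrix(c(...), ncol = 2, byrow = TRUE)), directed = FALSE)
}

test_that("triangle and path centralities match the hand-computed values", {
  k3 <- graph_from_edges("a", "b", "b", "c", "a", "c")
  tab <- compute_centralities(k3, epc_retain = 1)
  expect_equal(tab$degree, rep(2, 3))
  expect_equal(tab$mcc, rep(2, 3))       # (3-1)! per node
  expect_equal(tab$mnc, rep(2, 3))
  expect_equal(tab$closeness, rep(2, 3)) # 1/1 + 1/1
  expect_equal(tab$radiality, rep(1, 3)) # (1+1-1)*2 / 2
  expect_equal(tab$epc, rep(1, 3))       # fully reachable at retain 1
  expect_equal(tab$score, rep(2, 3))     # every metric fully tied -> average rank 2

  path <- graph_from_edges("a", "b", "b", "c")
  tab2 <- compute_centralities(path, epc_retain = 1)
  b <- tab2[tab2$node == "b", ]
  expect_equal(b$degree, 2)
  expect_equal(b$mcc, 2)   # two maximal cliques {a,b}, {b,c}: 1! + 1!
  expect_equal(b$mnc, 1)   # neighbours a and c are disconnected
  expect_identical(tab2$node[1], "b")
  # automorphic endpoints share a composite score
  expect_equal(tab2$score[tab2$node == "a"], tab2$score[tab2$node == "c"])
})

test_that("isolated nodes score zero on every metric", {
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(c("x", "y", "z")) + igraph::edges(c("x", "y"))
  tab <- compute_centralities(g, epc_retain = 1)
  z <- tab[tab$node == "z", ]
  expect_equal(unlist(z[c("degree", "mcc", "mnc", "epc", "closeness", "radiality")]),
               rep(0, 6), ignore_attr = TRUE)
  expect_error(compute_centralities(igraph::make_empty_graph(0, directed = FALSE)),
               "empty")
})

test_that("all metrics match brute-force oracles on random graphs", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:7, 1)
    adj <- random_graph(n, p = runif(1, 0.2, 0.8))
    tab <- compute_centralities(adj_to_graph(adj), epc_retain = 1)
    oracle <- oracle_centralities(adj, epc_retain = 1)
    ord <- match(rownames(adj), tab$node)
    for (mt in c("degree", "mcc", "mnc", "epc", "closeness", "radiality")) {
      expect_lt(max(abs(tab[[mt]][ord] - oracle[[mt]])), 1e-10)
    }
  }
})

test_that("Monte-Carlo EPC approaches the exact subset-enumeration expectation", {
  set.seed(32)
  adj <- random_graph(5, p = 0.5)
  exact <- oracle_centralities(adj, epc_retain = 0.5)$epc
  tab <- compute_centralities(adj_to_graph(adj), epc_trials = 4000,
                              epc_retain = 0.5, seed = 7)
  ord <- match(rownames(adj), tab$node)
  expect_lt(max(abs(tab$epc[ord] - exact)), 0.05)
  # determinism under a fixed seed
  tab2 <- compute_centralities(adj_to_graph(adj), epc_trials = 4000,
                               epc_retain = 0.5, seed = 7)
  expect_identical(tab$epc, tab2$epc)
})

test_that("composite ranking equals an independent recomputation on a 5-node toy", {
  adj <- random_graph(5, p = 0)
  adj["v01", "v02"] <- adj["v02", "v01"] <- 1
  adj["v02", "v03"] <- adj["v03", "v02"] <- 1
  adj["v03", "v04"] <- adj["v04", "v03"] <- 1
  adj["v03", "v05"] <- adj["v05", "v03"] <- 1
  tab <- compute_centralities(adj_to_graph(adj), epc_retain = 1)
  oracle <- oracle_centralities(adj, epc_retain = 1)
  oracle_score <- rowMeans(sapply(oracle, function(v) rank(-v)))
  expect_identical(tab$node,
                   rownames(adj)[order(oracle_score, rownames(adj))])
})

test_that("hub selection respects candidates, k, and planted-hub recovery", {
  net <- gen_network(n_nodes = 150, n_hubs = 10, hub_degree = 25, seed = 33)
  ranked <- compute_centralities(net$graph, epc_trials = 200, seed = 1)
  expect_warning(none <- select_hubs(ranked, c("ZZZ1", "ZZZ2"), 2), "not in graph")
  expect_identical(none, character(0))
  candidates <- c(net$hubs, igraph::V(net$graph)$name[1:30])
  expect_warning(all_back <- select_hubs(ranked, candidates, k = 1000), "exceeds")
  expect_setequal(all_back, unique(intersect(candidates, ranked$node)))
  hubs <- select_hubs(ranked, igraph::V(net$graph)$name, k = 10)
  recall <- length(intersect(hubs, net$hubs)) / length(net$hubs)
  expect_gte(recall, 0.8)
})

test_that("compound network keeps sub-threshold compounds as isolated nodes", {
  gene_g <- interaction_graph(tibble::tibble(
    node_a = c("H1", "H2", "T1"), node_b = c("H2", "T1", "H3"),
    confidence = c(0.9, 0.95, 0.8)), min_confidence = 0.7)
  ce <- tibble::tibble(node_a = c("drugX", "drugX", "drugX", "drugY", "drugZ"),
                       node_b = c("T1", "H1", "H2", "T1", "H3"),
                       confidence = c(0.9, 0.8, 0.95, 0.9, 0.65))
  g <- build_compound_network(ce, gene_g, hub_genes = c("H1", "H2", "H3"))
  expect_true(all(c("drugX", "drugY", "drugZ") %in% igraph::V(g)$name))
  expect_equal(igraph::degree(g, "drugZ"), 0, ignore_attr = TRUE)
  kinds <- igraph::V(g)$kind
  expect_identical(kinds[match("drugX", igraph::V(g)$name)], "compound")
  # more hub-connected compound ranks above the less connected one
  ranked <- compute_centralities(g, epc_retain = 1)
  expect_lt(which(ranked$node == "drugX"), which(ranked$node == "drugY"))
})
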