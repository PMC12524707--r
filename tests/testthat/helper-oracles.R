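# Independent brute-force oracles. These re-derive each statistic from its
# definition with naive loops, sharing no code with the package internals.

# ssGSEA running-sum ES, one sample, one set.
oracle_ssgsea <- function(values, gene_ids, set, alpha) {
  ord <- order(-values, gene_ids)
  genes <- gene_ids[ord]
  n <- length(genes)
  w <- (n - seq_len(n) + 1)^alpha
  in_set <- genes %in% set
  tot_in <- sum(w[in_set])
  es <- 0
  for (i in seq_len(n)) {
    p_in <- sum(w[seq_len(i)][in_set[seq_len(i)]]) / tot_in
    p_out <- sum(!in_set[seq_len(i)]) / (n - sum(in_set))
    es <- es + (p_in - p_out)
  }
  es
}

# Topological overlap by triple loop.
oracle_tom <- function(expr, beta) {
  a <- abs(cor(t(expr)))^beta
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# --- graph oracles operate on a 0/1 adjacency matrix -------------------

oracle_bfs_dist <- function(adj, v) {
  n <- nrow(adj)
  dist <- rep(Inf, n)
  dist[v] <- 0
  frontier <- v
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- integer(0)
    for (u in frontier) {
      nb <- which(adj[u, ] == 1)
      nb <- nb[dist[nb] == Inf]
      dist[nb] <- d
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  dist
}

# all maximal cliques by subset enumeration (n small)
oracle_max_cliques <- function(adj) {
  n <- nrow(adj)
  subsets <- list()
  for (mask in seq_len(2^n - 1)) {
    verts <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(verts) < 2) next
    pairs <- utils::combn(verts, 2)
    if (all(adj[t(pairs)] == 1)) subsets[[length(subsets) + 1]] <- verts
  }
  is_maximal <- vapply(subsets, function(cl) {
    !any(vapply(setdiff(seq_len(n), cl),
                function(v) all(adj[v, cl] == 1), logical(1)))
  }, logical(1))
  subsets[is_maximal]
}

oracle_centralities <- function(adj, epc_retain = 1) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  cliques <- oracle_max_cliques(adj)
  mcc <- numeric(n)
  for (cl in cliques) for (v in cl) mcc[v] <- mcc[v] + factorial(length(cl) - 1)
  mnc <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] == 1)
    if (!length(nb)) return(0)
    sub <- adj[nb, nb, drop = FALSE]
    seen <- rep(FALSE, length(nb))
    best <- 0
    for (s in seq_along(nb)) {
      if (seen[s]) next
      comp <- which(is.finite(oracle_bfs_dist(sub, s)))
      seen[comp] <- TRUE
      best <- max(best, length(comp))
    }
    best
  }, numeric(1))
  dmat <- t(vapply(seq_len(n), function(v) oracle_bfs_dist(adj, v), numeric(n)))
  closeness <- vapply(seq_len(n), function(v) {
    dd <- dmat[v, -v]
    sum(1 / dd[is.finite(dd)])
  }, numeric(1))
  radiality <- vapply(seq_len(n), function(v) {
    reach <- setdiff(which(is.finite(dmat[v, ])), v)
    if (!length(reach)) return(0)
    comp <- c(v, reach)
    diam <- max(dmat[comp, comp][is.finite(dmat[comp, comp])])
    sum(diam + 1 - dmat[v, reach]) / (n - 1)
  }, numeric(1))
  # exact EPC by expectation over edge subsets (direct reachability at retain 1)
  edges <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  m <- nrow(edges)
  epc <- numeric(n)
  if (n > 1) {
    if (m == 0) {
      epc <- rep(0, n)
    } else if (epc_retain == 1) {
      epc <- vapply(seq_len(n), function(v) {
        (sum(is.finite(oracle_bfs_dist(adj, v))) - 1) / (n - 1)
      }, numeric(1))
    } else {
      for (mask in 0:(2^m - 1)) {
        keep <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
        sub <- matrix(0, n, n)
        if (length(keep)) {
          for (e in keep) {
            sub[edges[e, 1], edges[e, 2]] <- 1
            sub[edges[e, 2], edges[e, 1]] <- 1
          }
        }
        prob <- epc_retain^length(keep) * (1 - epc_retain)^(m - length(keep))
        for (v in seq_len(n)) {
          reach <- sum(is.finite(oracle_bfs_dist(sub, v))) - 1
          epc[v] <- epc[v] + prob * reach / (n - 1)
        }
      }
    }
  }
  data.frame(degree = deg, mcc = mcc, mnc = mnc, epc = epc,
             closeness = closeness, radiality = radiality)
}

# weighted-KS ES by explicit walk
oracle_weighted_ks <- function(z, query, p = 1) {
  ord <- order(-z, names(z))
  z <- z[ord]
  hit <- toupper(names(z)) %in% toupper(query)
  nr <- sum(abs(z[hit])^p)
  run <- 0; best <- 0
  for (i in seq_along(z)) {
    run <- run + if (hit[i]) abs(z[i])^p / nr else -1 / (length(z) - sum(hit))
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# Cox partial log-likelihood (Efron ties) for a single covariate
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in unique(time[event == 1])) {
    d_set <- which(time == t & event == 1)
    r_set <- which(time >= t)
    d <- length(d_set)
    ll <- ll + sum(beta * x[d_set])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum(exp(beta * x[r_set])) -
                       (l / d) * sum(exp(beta * x[d_set])))
    }
  }
  ll
}

oracle_cox_beta <- function(time, event, x) {
  stats::optimize(function(b) -oracle_cox_loglik(b, time, event, x),
                  c(-10, 10), tol = 1e-8)$minimum
}

# random labelled graph as igraph + adjacency
random_graph <- function(n, p = 0.4) {
  adj <- matrix(0, n, n)
  up <- which(upper.tri(adj))
  on <- up[runif(length(up)) < p]
  adj[on] <- 1
  adj <- adj + t(adj)
  dimnames(adj) <- list(sprintf("v%02d", 1:n), sprintf("v%02d", 1:n))
  adj
}

adj_to_graph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}
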