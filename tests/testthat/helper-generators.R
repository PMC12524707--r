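# Shared simulation builders for module-recovery tests.

# expression with one planted co-expressed block (target within-block
# correlation) on top of iid noise genes
planted_module_expr <- function(n_module = 50, n_noise = 80, n_samples = 80,
                                within_cor = 0.8, seed = 1) {
  set.seed(seed)
  rho <- sqrt(within_cor / (1 - within_cor))
  f <- rnorm(n_samples)
  mod <- t(sapply(seq_len(n_module), function(i) rho * f + rnorm(n_samples)))
  rownames(mod) <- sprintf("MOD%03d", seq_len(n_module))
  noise <- matrix(rnorm(n_noise * n_samples), n_noise,
                  dimnames = list(sprintf("NSE%03d", seq_len(n_noise)), NULL))
  expr <- rbind(mod, noise)
  colnames(expr) <- sprintf("s%03d", seq_len(n_samples))
  expr
}

jaccard_index <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# largest detected module vs the planted block
module_recovery_jaccard <- function(seed, within_cor = 0.8, n_module = 50) {
  expr <- planted_module_expr(n_module = n_module, within_cor = within_cor,
                              seed = seed)
  tom <- compute_tom(expr, beta = 6)
  mods <- detect_modules(1 - tom, min_module_size = 30)
  if (!any(mods$module > 0)) return(0)
  detected <- mods$gene[mods$module == 1]
  jaccard_index(detected, grep("MOD", rownames(expr), value = TRUE))
}
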