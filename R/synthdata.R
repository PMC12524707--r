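#' Generate a bulk expression cohort with a latent GMT axis
#'
#' Each sample carries a standard-normal latent mesenchymal-proneural axis
#' `g`. Mesenchymal signature genes load `+lambda * g`, proneural genes
#' `-lambda * g`, and a planted co-expressed module loads `lambda * g` plus
#' a shared module factor; all genes receive independent Gaussian noise and
#' background genes are pure noise. Survival times are exponential with
#' hazard `h0 * exp(surv_beta * g)` under independent exponential censoring,
#' so a Cox fit on the axis has a known truth.
#'
#' @param n_samples,n_genes Cohort dimensions.
#' @param n_sig Genes per (mesenchymal / proneural) signature.
#' @param module_size Genes in the planted co-expressed module.
#' @param lambda Axis loading.
#' @param sigma Noise standard deviation.
#' @param surv_beta Log-hazard slope on the axis.
#' @param h0 Baseline hazard (per day).
#' @param censor_rate Exponential censoring rate (per day).
#' @param seed Integer seed; same seed reproduces identical output.
#' @return List: `expr` (matrix), `survival` (tibble), `mes_set`, `pn_set`,
#'   `module_genes`, `truth` (tibble `sample_id`, `g`), `params`.
#' @export
gen_bulk_cohort <- function(n_samples = 168, n_genes = 1000, n_sig = 50,
                            module_size = 60, lambda = 1, sigma = 0.5,
                            surv_beta = 0.5, h0 = 0.001, censor_rate = 5e-4,
                            seed = 1) {
  if (module_size + 2 * n_sig > n_genes) {
    abort("module_size + 2 * n_sig must not exceed n_genes")
  }
  set.seed(seed)
  g <- rnorm(n_samples)
  samples <- sprintf("S%03d", seq_len(n_samples))
  mes <- sprintf("MESG%03d", seq_len(n_sig))
  pn <- sprintf("PNG%03d", seq_len(n_sig))
  mod <- sprintf("MODG%03d", seq_len(module_size))
  bg <- sprintf("BGG%04d", seq_len(n_genes - 2 * n_sig - module_size))
  genes <- c(mes, pn, mod, bg)

  noise <- matrix(rnorm(n_genes * n_samples, sd = sigma), n_genes, n_samples)
  module_factor <- rnorm(n_samples)
  loading <- rbind(
    matrix(rep(lambda * g, each = length(mes)), length(mes)),
    matrix(rep(-lambda * g, each = length(pn)), length(pn)),
    matrix(rep(lambda * g + module_factor, each = length(mod)), length(mod)),
    matrix(0, length(bg), n_samples))
  expr <- loading + noise
  dimnames(expr) <- list(genes, samples)

  death <- rexp(n_samples, rate = h0 * exp(surv_beta * g))
  cens <- rexp(n_samples, rate = censor_rate)
  surv <- tibble(sample_id = samples,
                 time = pmin(death, cens),
                 event = as.integer(death <= cens))

  list(expr = expr, survival = surv,
       mes_set = mes, pn_set = pn, module_genes = mod,
       truth = tibble(sample_id = samples, g = g, module_factor = module_factor),
       params = list(n_samples = n_samples, n_genes = n_genes, n_sig = n_sig,
                     module_size = module_size, lambda = lambda, sigma = sigma,
                     surv_beta = surv_beta, h0 = h0, censor_rate = censor_rate,
                     seed = seed))
}

#' Generate a two-condition negative-binomial count experiment
#'
#' All genes share a baseline mean and dispersion; a planted fraction is
#' fold-changed upward in condition A.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Samples per condition.
#' @param frac_de Fraction of genes with a planted effect.
#' @param log2fc Planted log2 fold change (condition A over B).
#' @param mean_mu Baseline NB mean.
#' @param dispersion NB dispersion alpha (variance `mu + alpha mu^2`).
#' @param seed Integer seed.
#' @return List: `cm` (see [count_matrix()]), `de_genes`, `truth`, `params`.
#' @export
gen_counts <- function(n_genes = 2000, n_per_group = 5, frac_de = 0.05,
                       log2fc = 2, mean_mu = 100, dispersion = 0.1, seed = 1) {
  set.seed(seed)
  n_de <- round(frac_de * n_genes)
  genes <- sprintf("G%05d", seq_len(n_genes))
  de_genes <- if (n_de > 0) genes[seq_len(n_de)] else character(0)
  samples <- c(sprintf("A%02d", seq_len(n_per_group)),
               sprintf("B%02d", seq_len(n_per_group)))
  cond <- rep(c("A", "B"), each = n_per_group)
  mu <- matrix(mean_mu, n_genes, 2 * n_per_group)
  if (n_de > 0) mu[seq_len(n_de), cond == "A"] <- mean_mu * 2^log2fc
  size <- 1 / dispersion
  counts <- matrix(rnbinom(length(mu), mu = mu, size = size),
                   n_genes, 2 * n_per_group, dimnames = list(genes, samples))
  list(cm = count_matrix(counts, cond), de_genes = de_genes,
       truth = tibble(gene = genes,
                      true_log2fc = ifelse(genes %in% de_genes, log2fc, 0)),
       params = list(n_genes = n_genes, n_per_group = n_per_group,
                     frac_de = frac_de, log2fc = log2fc, mean_mu = mean_mu,
                     dispersion = dispersion, seed = seed))
}

#' Generate an interaction network with planted hubs
#'
#' A preferential-attachment background graph plus `n_hubs` planted hub
#' nodes, each wired to `hub_degree` random nodes, with an inter-hub clique;
#' edge confidences are drawn above the usual 0.7 threshold.
#'
#' @param n_nodes Background nodes.
#' @param n_hubs Planted hubs.
#' @param hub_degree Random attachments per hub.
#' @param m Preferential-attachment edges per background node.
#' @param node_names Optional names for the background nodes (first
#'   `n_hubs` of them become the hubs); defaults to `N0001...`.
#' @param seed Integer seed.
#' @return List: `graph` (igraph), `hubs`, `params`.
#' @export
gen_network <- function(n_nodes = 300, n_hubs = 20, hub_degree = 30, m = 2,
                        node_names = NULL, seed = 1) {
  if (n_hubs >= n_nodes) abort("n_hubs must be smaller than n_nodes")
  set.seed(seed)
  node_names <- node_names %||% sprintf("N%04d", seq_len(n_nodes))
  stopifnot(length(node_names) == n_nodes)
  hubs <- node_names[seq_len(n_hubs)]
  others <- node_names[-seq_len(n_hubs)]
  bg <- igraph::sample_pa(length(others), m = m, directed = FALSE)
  bg_edges <- igraph::as_edgelist(bg)
  edges <- tibble(node_a = others[bg_edges[, 1]], node_b = others[bg_edges[, 2]])
  hub_edges <- purrr::map(hubs, function(h) {
    tibble(node_a = h, node_b = sample(others, min(hub_degree, length(others))))
  }) |> bind_rows()
  clique_pairs <- t(utils::combn(hubs, 2))
  clique_edges <- tibble(node_a = clique_pairs[, 1], node_b = clique_pairs[, 2])
  all_edges <- bind_rows(edges, hub_edges, clique_edges)
  all_edges$confidence <- runif(nrow(all_edges), 0.71, 1)
  g <- interaction_graph(all_edges, min_confidence = 0.7)
  list(graph = g, hubs = hubs,
       params = list(n_nodes = n_nodes, n_hubs = n_hubs,
                     hub_degree = hub_degree, m = m, seed = seed))
}

#' Generate a perturbagen signature library with planted reversers
#'
#' Inert compounds have standard-normal z-scores everywhere; planted
#' reversers are shifted by `-effect` on the signature genes in every cell
#' line (optional mimics by `+effect`).
#'
#' @param n_compounds Total compounds.
#' @param n_reversers Planted reversers.
#' @param n_mimics Planted mimics.
#' @param n_genes Library gene space.
#' @param signature_genes Genes carrying the planted shift (default: first
#'   31 library genes, mirroring a hub signature query).
#' @param background_genes Optional extra gene names to include in the
#'   library gene space (unshifted); generic filler names complete the
#'   space up to `n_genes`.
#' @param effect Shift magnitude on signature genes.
#' @param noise Z-score standard deviation.
#' @param n_cell_lines Cell lines per compound.
#' @param seed Integer seed.
#' @return List: `lib` (see [perturbagen_library()]), `reversers`, `mimics`,
#'   `params`.
#' @export
gen_signature_library <- function(n_compounds = 100, n_reversers = 5,
                                  n_mimics = 0, n_genes = 500,
                                  signature_genes = NULL, effect = 3,
                                  noise = 1, n_cell_lines = 9, seed = 1,
                                  background_genes = NULL) {
  set.seed(seed)
  sig <- toupper(signature_genes %||% sprintf("LG%04d", seq_len(31)))
  bg <- setdiff(toupper(background_genes %||% character(0)), sig)
  if (length(sig) + length(bg) > n_genes) {
    abort("more signature plus background genes than library genes")
  }
  # deterministic layout: signature genes first, named background, filler
  all_genes <- c(sig, bg,
                 sprintf("BLG%04d", seq_len(n_genes - length(sig) - length(bg))))
  compounds <- sprintf("CPD%03d", seq_len(n_compounds))
  reversers <- compounds[seq_len(n_reversers)]
  mimics <- if (n_mimics > 0) compounds[n_reversers + seq_len(n_mimics)] else character(0)
  cells <- sprintf("CL%d", seq_len(n_cell_lines))
  meta <- tidyr::expand_grid(compound = compounds, cell_line = cells) |>
    mutate(perturbagen_id = paste(.data$compound, .data$cell_line, sep = "_"),
           type = "compound") |>
    select("perturbagen_id", "compound", "cell_line", "type")
  z <- matrix(rnorm(nrow(meta) * length(all_genes), sd = noise),
              nrow(meta), length(all_genes),
              dimnames = list(meta$perturbagen_id, all_genes))
  sig_idx <- match(sig, all_genes)
  z[meta$compound %in% reversers, sig_idx] <-
    z[meta$compound %in% reversers, sig_idx] - effect
  if (length(mimics)) {
    z[meta$compound %in% mimics, sig_idx] <-
      z[meta$compound %in% mimics, sig_idx] + effect
  }
  list(lib = perturbagen_library(z, meta), reversers = reversers,
       mimics = mimics, signature_genes = sig,
       params = list(n_compounds = n_compounds, n_reversers = n_reversers,
                     n_mimics = n_mimics, n_genes = n_genes, effect = effect,
                     noise = noise, n_cell_lines = n_cell_lines, seed = seed))
}

#' Generate compound score tables and fingerprints for the funnel
#'
#' BBB scores on two synthetic platforms, three P-gp substrate calls,
#' literature co-occurrence sentence counts, 128-bit fingerprints and a
#' temozolomide-like reference row, with a configurable pass pattern so
#' funnel survivor counts can be enumerated by hand.
#'
#' @param compounds Character vector of compound ids.
#' @param bbb_pass,pgp_pass,text_pass Character vectors naming the
#'   compounds that should pass each stage (defaults: all).
#' @param n_bits Fingerprint length.
#' @param seed Integer seed.
#' @return List: `bbb` (tibble incl. the `temozolomide` reference row),
#'   `pgp` (tibble), `cooc` (tibble), `fingerprints`, `reference_fps`,
#'   `params`.
#' @export
gen_chem_tables <- function(compounds, bbb_pass = compounds,
                            pgp_pass = compounds, text_pass = compounds,
                            n_bits = 128, seed = 1) {
  set.seed(seed)
  ref_score <- c(a = 0.7, b = 0.7)
  bbb <- tibble(
    compound = c(compounds, "temozolomide"),
    bbb_score_a = c(ifelse(compounds %in% bbb_pass,
                           runif(length(compounds), 0.7, 1),
                           runif(length(compounds), 0, 0.69)), ref_score["a"]),
    bbb_score_b = c(ifelse(compounds %in% bbb_pass,
                           runif(length(compounds), 0.7, 1),
                           runif(length(compounds), 0, 0.69)), ref_score["b"]))
  call_of <- function(pass) ifelse(pass, "non-substrate", "substrate")
  pgp <- tibble(compound = compounds,
                pgp_call_1 = call_of(compounds %in% pgp_pass),
                pgp_call_2 = call_of(compounds %in% pgp_pass),
                pgp_call_3 = call_of(compounds %in% pgp_pass))
  cooc <- tibble(compound = compounds,
                 invasion = ifelse(compounds %in% text_pass,
                                   6 + stats::rpois(length(compounds), 4), 0),
                 metastasis = ifelse(compounds %in% text_pass,
                                     6 + stats::rpois(length(compounds), 4), 0))
  fps <- lapply(compounds, function(x) rbinom(n_bits, 1, 0.3))
  names(fps) <- compounds
  reference_fps <- list(temozolomide = rbinom(n_bits, 1, 0.3),
                        doxorubicin = rbinom(n_bits, 1, 0.3))
  list(bbb = bbb, pgp = pgp, cooc = cooc,
       fingerprints = fps, reference_fps = reference_fps,
       params = list(n_bits = n_bits, seed = seed))
}
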