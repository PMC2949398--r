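# Synthetic-data generators: every input the pipeline consumes, with
# planted, recoverable structure. The generators state a simple world —
# independent per-gene baseline mutation, latent shared drivers for
# co-occurring pairs, latent exclusive drivers for anti pairs, an i.i.d.
# per-cell sequencing mask — so that downstream inference has an exact
# ground truth to recover.

#' Simulation configuration for a mutation matrix
#'
#' @param n_samples number of tumour samples.
#' @param n_genes number of genes.
#' @param baseline_freqs per-gene baseline mutation probability; a single
#'   value is recycled; `NULL` draws log-uniform from \[0.01, 0.3\],
#'   emulating the wide spread of real per-gene frequencies (a hub tumour
#'   suppressor can approach 0.9 while most genes sit below 0.1).
#' @param co_pairs data.frame `gene_a`, `gene_b`, `q` — per sample a
#'   shared latent driver event with probability `q` mutates both genes.
#' @param anti_pairs data.frame `gene_a`, `gene_b`, `e` — per sample an
#'   exclusive latent event with probability `e` mutates exactly one of
#'   the two (fair coin) and suppresses the pair's baselines there.
#' @param coverage per-cell sequencing probability in (0, 1].
#' @param seed integer RNG seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples, n_genes, baseline_freqs = NULL,
                       co_pairs = NULL, anti_pairs = NULL,
                       coverage = 1, seed = 1L) {
  stopifnot(n_samples >= 1, n_genes >= 1, coverage > 0, coverage <= 1)
  genes <- sprintf("g%03d", seq_len(n_genes))
  if (is.null(baseline_freqs)) {
    set.seed(seed + 1000L)
    baseline_freqs <- exp(stats::runif(n_genes, log(0.01), log(0.3)))
  }
  if (length(baseline_freqs) == 1)
    baseline_freqs <- rep(baseline_freqs, n_genes)
  stopifnot(length(baseline_freqs) == n_genes,
            all(baseline_freqs >= 0), all(baseline_freqs < 1))
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      effect = numeric())
  norm_pairs <- function(p, effcol) {
    if (is.null(p) || nrow(p) == 0) return(empty)
    stopifnot(all(c("gene_a", "gene_b", effcol) %in% names(p)))
    stopifnot(all(p[[effcol]] > 0), all(p[[effcol]] <= 1))
    data.frame(gene_a = p$gene_a, gene_b = p$gene_b,
               effect = p[[effcol]], stringsAsFactors = FALSE)
  }
  co <- norm_pairs(co_pairs, "q")
  anti <- norm_pairs(anti_pairs, "e")
  pg <- c(co$gene_a, co$gene_b, anti$gene_a, anti$gene_b)
  if (anyDuplicated(pg))
    stop("gene appears in more than one planted pair: ",
         pg[duplicated(pg)][1])
  if (!all(pg %in% genes)) stop("planted pair gene not among genes")
  structure(list(n_samples = n_samples, n_genes = n_genes, genes = genes,
                 baseline_freqs = stats::setNames(baseline_freqs, genes),
                 co_pairs = co, anti_pairs = anti,
                 coverage = coverage, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a mutation matrix with planted pair structure
#'
#' Per sample each gene mutates independently at its baseline frequency.
#' For each planted co-occurring pair, a shared latent event (probability
#' `q`) sets both genes mutated. For each planted anti pair, an exclusive
#' latent event (probability `e`) sets exactly one of the two mutated
#' (fair coin) and suppresses both baselines in that sample, so planted
#' exclusivity is exact rather than merely discouraged. Finally an i.i.d.
#' per-cell sequencing mask with probability `coverage` is applied.
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (a [mutation_matrix()]) and `truth`
#'   (planted pairs with direction and effect; realized per-gene marginal
#'   frequencies).
#' @export
simulate_mutation_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  genes <- config$genes
  p <- config$baseline_freqs
  st <- matrix(stats::rbinom(n * length(genes), 1L, rep(p, each = n)),
               nrow = n,
               dimnames = list(sprintf("s%04d", seq_len(n)), genes))
  co <- config$co_pairs
  for (i in seq_len(nrow(co))) {
    ev <- stats::rbinom(n, 1L, co$effect[i]) == 1L
    st[ev, co$gene_a[i]] <- 1L
    st[ev, co$gene_b[i]] <- 1L
  }
  anti <- config$anti_pairs
  for (i in seq_len(nrow(anti))) {
    ev <- stats::rbinom(n, 1L, anti$effect[i]) == 1L
    pick_a <- stats::rbinom(n, 1L, 0.5) == 1L
    st[ev, anti$gene_a[i]] <- ifelse(pick_a[ev], 1L, 0L)
    st[ev, anti$gene_b[i]] <- ifelse(pick_a[ev], 0L, 1L)
  }
  if (config$coverage < 1) {
    mask <- matrix(stats::runif(length(st)) > config$coverage,
                   nrow = n)
    st[mask] <- NA_integer_
  }
  mm <- mutation_matrix(st)
  realized <- colMeans(st == 1L, na.rm = TRUE)
  truth <- list(
    pairs = rbind(
      if (nrow(co)) cbind(co, relation = "co"),
      if (nrow(anti)) cbind(anti, relation = "anti")),
    realized_freq = realized)
  list(matrix = mm, truth = truth)
}

#' Simulate a typed signaling network
#'
#' Draws `n_links` distinct unordered node pairs uniformly; link types are
#' multinomial over (activation, repression, physical, unknown). The
#' directed types get a random orientation.
#'
#' @param n_nodes number of nodes.
#' @param n_links number of links; must not exceed `n_nodes (n_nodes-1)/2`.
#' @param type_proportions length-4 numeric summing to 1, order
#'   activation / repression / physical / unknown.
#' @param seed RNG seed.
#' @return a [signaling_network()].
#' @export
simulate_signaling_network <- function(n_nodes, n_links,
                                       type_proportions = c(0.472, 0.146,
                                                            0.376, 0.006),
                                       seed = 1L) {
  stopifnot(length(type_proportions) == 4,
            abs(sum(type_proportions) - 1) < 1e-8,
            all(type_proportions >= 0))
  cap <- n_nodes * (n_nodes - 1) / 2
  if (n_links > cap)
    stop(sprintf("n_links (%d) exceeds simple-graph capacity (%d)",
                 n_links, cap))
  set.seed(seed)
  nodes <- sprintf("sg%04d", seq_len(n_nodes))
  pair_idx <- sample.int(cap, n_links)
  # unrank the unordered pair index
  b <- ceiling((1 + sqrt(1 + 8 * pair_idx)) / 2)
  a <- pair_idx - (b - 1) * (b - 2) / 2
  types <- c("activation", "repression", "physical", "unknown")
  tp <- sample(types, n_links, replace = TRUE, prob = type_proportions)
  flip <- stats::runif(n_links) < 0.5
  src <- ifelse(flip, nodes[a], nodes[b])
  tgt <- ifelse(flip, nodes[b], nodes[a])
  signaling_network(data.frame(source = src, target = tgt, type = tp,
                               stringsAsFactors = FALSE))
}

#' Simulate expression profiles decaying with network distance
#'
#' Each connected component gets a root latent profile (standard normal
#' over tissues); a gene at distance `d` from its component root receives
#' `decay_alpha^d * latent + noise`. Expected absolute Pearson similarity
#' between genes therefore decreases with their network distance — the
#' property the distance-similarity analysis assumes.
#'
#' @param network a [cca_network()].
#' @param decay_alpha signal retention per network hop, in (0, 1).
#' @param n_tissues number of tissue columns (>= 3).
#' @param noise_sd Gaussian noise standard deviation.
#' @param latent_sd standard deviation of the root latent profile
#'   (default 3): tissue expression atlases have a dynamic range well
#'   above measurement noise, so the root signal is drawn several-fold
#'   wider than the per-gene noise.
#' @param seed RNG seed.
#' @return an [expression_matrix()] over the network's genes.
#' @export
simulate_expression <- function(network, decay_alpha = 0.7, n_tissues = 79,
                                noise_sd = 1, latent_sd = 3, seed = 1L) {
  stopifnot(decay_alpha > 0, decay_alpha < 1, latent_sd > 0)
  if (n_tissues < 3) stop("n_tissues must be >= 3")
  set.seed(seed)
  comp <- connected_components(network)
  D <- shortest_path_distances(network)
  genes <- network$nodes$gene
  expr <- matrix(NA_real_, length(genes), n_tissues,
                 dimnames = list(genes, sprintf("t%02d", seq_len(n_tissues))))
  for (set in comp$components) {
    root <- set[1]
    latent <- stats::rnorm(n_tissues, sd = latent_sd)
    for (g in set) {
      d <- D[root, g]
      expr[g, ] <- decay_alpha^d * latent +
        stats::rnorm(n_tissues, sd = noise_sd)
    }
  }
  expression_matrix(expr)
}

#' Simulate annotations: pathways, methylation, module labels, metadata
#'
#' Pathway sets are sampled from the gene universe, optionally enriched
#' for network-adjacent genes (`network` + `adjacency_boost`): a boosted
#' set seeds on a random edge and grows along neighbours, planting the
#' same-pathway co-membership signal. Methylation labels are Bernoulli
#' per gene at the rate of its module. Gene lengths are log-uniform on
#' \[1 kb, 100 kb\], exon counts 1-50, locations uniform over the four
#' cellular compartments.
#'
#' @param genes character vector of gene ids.
#' @param n_pathways number of gene sets.
#' @param set_size_range integer length-2, inclusive sizes.
#' @param methylation_rate_by_module named numeric vector, one rate per
#'   module label.
#' @param module_split named list of character vectors partitioning
#'   `genes` into modules.
#' @param seed RNG seed.
#' @param network optional [cca_network()] for adjacency-enriched sets.
#' @param adjacency_boost fraction of pathways grown along network edges
#'   (default 0 = uniform sampling).
#' @return list with `pathways`, `methylated` (character vector),
#'   `module_labels` (named vector), `metadata` (data.frame).
#' @export
simulate_annotations <- function(genes, n_pathways = 20,
                                 set_size_range = c(5, 25),
                                 methylation_rate_by_module = NULL,
                                 module_split = NULL, seed = 1L,
                                 network = NULL, adjacency_boost = 0) {
  set.seed(seed)
  if (is.null(module_split)) {
    half <- ceiling(length(genes) / 2)
    module_split <- list(M1 = genes[seq_len(half)],
                         M2 = genes[-seq_len(half)])
  }
  if (any(vapply(module_split, length, integer(1)) == 0))
    stop("empty module in module_split")
  if (!setequal(unlist(module_split), genes))
    stop("module_split must partition the gene list")
  labels <- stats::setNames(
    rep(names(module_split), lengths(module_split)),
    unlist(module_split))
  labels <- labels[genes]
  if (is.null(methylation_rate_by_module))
    methylation_rate_by_module <- stats::setNames(
      rep(0.05, length(module_split)), names(module_split))
  rates <- methylation_rate_by_module[labels]
  methylated <- genes[stats::runif(length(genes)) < rates]
  size_choices <- seq(set_size_range[1], set_size_range[2])
  sizes <- size_choices[sample.int(length(size_choices), n_pathways,
                                   replace = TRUE)]
  sizes <- pmin(sizes, length(genes))
  pathways <- vector("list", n_pathways)
  names(pathways) <- sprintf("pw%03d", seq_len(n_pathways))
  boosted <- stats::runif(n_pathways) < adjacency_boost
  for (i in seq_len(n_pathways)) {
    if (boosted[i] && !is.null(network) && n_edges(network) > 0) {
      ei <- sample.int(n_edges(network), 1)
      members <- c(network$edges$from[ei], network$edges$to[ei])
      adj <- .adjacency_list(network)
      while (length(members) < sizes[i]) {
        nb <- setdiff(unique(unlist(adj[members])), members)
        if (!length(nb)) nb <- setdiff(genes, members)
        if (!length(nb)) break
        members <- c(members, sample(nb, 1))
      }
      pathways[[i]] <- members
    } else {
      pathways[[i]] <- sample(genes, sizes[i])
    }
  }
  metadata <- data.frame(
    gene_id = genes,
    length_bp = round(exp(stats::runif(length(genes), log(1e3), log(1e5)))),
    exon_count = sample.int(50, length(genes), replace = TRUE),
    location = sample(c("extracellular", "membrane", "cytoplasm",
                        "nucleus"), length(genes), replace = TRUE),
    stringsAsFactors = FALSE)
  list(pathways = structure(pathways, class = "pathway_collection"),
       methylated = methylated, module_labels = labels,
       metadata = metadata)
}
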