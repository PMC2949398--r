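# CCA network construction and topology metrics. Degree and clustering
# coefficient use the standard local definitions: k = number of incident
# edges, C = 2 * (links among neighbours) / (k (k - 1)). Distances use
# breadth-first search, which on unit edge weights coincides with
# Dijkstra's algorithm (asserted against igraph in the test suite).

#' Build the CCA network from pair test results
#'
#' Links every pair with `p_value <= cutoff` and a directional odds ratio;
#' the edge carries the pair's relation (co / anti). Genes incident to no
#' significant pair are excluded — the network contains only genes with at
#' least one significant partner.
#'
#' @param pair_results output of [all_pair_tests()] (any data.frame with
#'   `gene_a`, `gene_b`, `p_value`, `odds_ratio`).
#' @param cutoff p-value cutoff (default 0.02).
#' @param frequencies optional data.frame from [mutation_frequencies()]
#'   merged onto nodes.
#' @param metadata optional gene metadata merged onto nodes.
#' @return a [cca_network()] with degree and clustering coefficient
#'   pre-computed as node attributes.
#' @export
build_cca_network <- function(pair_results, cutoff = 0.02,
                              frequencies = NULL, metadata = NULL) {
  rel <- vapply(seq_len(nrow(pair_results)), function(i)
    classify_relation(pair_results$p_value[i], pair_results$odds_ratio[i],
                      cutoff), character(1))
  sig <- rel != "none"
  edges <- data.frame(from = pair_results$gene_a[sig],
                      to = pair_results$gene_b[sig],
                      relation = rel[sig], stringsAsFactors = FALSE)
  genes <- sort(unique(c(edges$from, edges$to)))
  nodes <- data.frame(gene = genes, stringsAsFactors = FALSE)
  if (!is.null(frequencies)) {
    i <- match(genes, frequencies$gene)
    nodes$raw_freq <- frequencies$raw_freq[i]
    nodes$corrected_freq <- frequencies$corrected_freq[i]
  }
  if (!is.null(metadata)) {
    i <- match(genes, metadata$gene_id)
    nodes$length_bp <- metadata$length_bp[i]
    nodes$exon_count <- metadata$exon_count[i]
    nodes$location <- metadata$location[i]
  }
  net <- cca_network(nodes, edges)
  net$nodes$degree <- node_degrees(net)
  net$nodes$cc <- vapply(net$nodes$gene, function(g)
    clustering_coefficient(net, g), numeric(1))
  net
}

.adjacency_list <- function(network) {
  genes <- network$nodes$gene
  adj <- stats::setNames(vector("list", length(genes)), genes)
  for (g in genes) adj[[g]] <- character(0)
  e <- network$edges
  for (i in seq_len(nrow(e))) {
    adj[[e$from[i]]] <- c(adj[[e$from[i]]], e$to[i])
    adj[[e$to[i]]] <- c(adj[[e$to[i]]], e$from[i])
  }
  adj
}

#' Node degrees
#' @param network a [cca_network()].
#' @param relation count only edges of this relation (`"co"`, `"anti"`)
#'   or `NULL` (default) for all edges.
#' @return named integer vector over nodes.
#' @export
node_degrees <- function(network, relation = NULL) {
  e <- network$edges
  if (!is.null(relation)) e <- e[e$relation == relation, , drop = FALSE]
  tab <- table(factor(c(e$from, e$to), levels = network$nodes$gene))
  stats::setNames(as.integer(tab), network$nodes$gene)
}

#' Clustering coefficient of a node
#'
#' `C = 2 E_nb / (k (k - 1))` where `E_nb` is the number of edges among
#' the node's `k` neighbours. Nodes with `k < 2` have no neighbour pair;
#' their C is defined as 0 by default or can be excluded from averages via
#' [mean_clustering_coefficient()]. Relation types are ignored — co and
#' anti edges both count.
#'
#' @param network a [cca_network()].
#' @param node gene id.
#' @return C in \[0, 1\].
#' @export
clustering_coefficient <- function(network, node) {
  if (!node %in% network$nodes$gene) stop("node not in network: ", node)
  e <- network$edges
  nb <- c(e$to[e$from == node], e$from[e$to == node])
  k <- length(nb)
  if (k < 2) return(0)
  in_nb <- e$from %in% nb & e$to %in% nb
  2 * sum(in_nb) / (k * (k - 1))
}

#' Mean clustering coefficient of a network
#' @param network a [cca_network()].
#' @param drop_low_degree exclude nodes with k < 2 from the mean rather
#'   than counting them as 0 (default FALSE).
#' @return mean C.
#' @export
mean_clustering_coefficient <- function(network, drop_low_degree = FALSE) {
  cc <- vapply(network$nodes$gene, function(g)
    clustering_coefficient(network, g), numeric(1))
  if (drop_low_degree) {
    k <- node_degrees(network)
    cc <- cc[k >= 2]
  }
  if (length(cc) == 0) return(NA_real_)
  mean(cc)
}

#' Connected components of the network
#'
#' @param network a [cca_network()].
#' @return list with `components` (list of node-id character vectors,
#'   largest first), `n_components`, and `giant_fraction` (share of nodes
#'   in the largest component; `NA` for an empty network).
#' @export
connected_components <- function(network) {
  if (n_nodes(network) == 0)
    return(list(components = list(), n_components = 0L,
                giant_fraction = NA_real_))
  g <- as_igraph(network)
  comp <- igraph::components(g)
  sets <- split(names(comp$membership), comp$membership)
  sets <- sets[order(-vapply(sets, length, integer(1)))]
  names(sets) <- NULL
  list(components = sets, n_components = comp$no,
       giant_fraction = max(comp$csize) / n_nodes(network))
}

#' All-pairs shortest-path distances (unit edge weights)
#'
#' Breadth-first search from every node; on unweighted graphs this equals
#' Dijkstra's algorithm. Unreachable pairs get `Inf` and are excluded from
#' downstream distance correlations.
#'
#' @param network a [cca_network()].
#' @return numeric matrix of distances (Inf = unreachable).
#' @export
shortest_path_distances <- function(network) {
  genes <- network$nodes$gene
  n <- length(genes)
  adj_idx <- lapply(.adjacency_list(network), function(nb) match(nb, genes))
  D <- matrix(Inf, n, n, dimnames = list(genes, genes))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(adj_idx[frontier], use.names = FALSE))
      nxt <- nxt[is.infinite(dist[nxt])]
      dist[nxt] <- d
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  D
}

#' Degree distribution
#'
#' Exact counts per observed degree plus a log2-binned summary. No
#' power-law fitting is attempted; the histogram itself is the output.
#'
#' @param network a [cca_network()] with >= 1 node.
#' @return list with `histogram` (data.frame degree / count) and
#'   `log_binned` (data.frame bin_lo / bin_hi / count).
#' @export
degree_distribution <- function(network) {
  if (n_nodes(network) < 1) stop("empty network")
  k <- node_degrees(network)
  tab <- table(k)
  hist <- data.frame(degree = as.integer(names(tab)),
                     count = as.integer(tab))
  kmax <- max(k)
  breaks <- unique(c(0, 2^(0:ceiling(log2(max(1, kmax) + 1)))))
  bin <- cut(k, breaks = breaks, right = FALSE,
             include.lowest = TRUE)
  lb <- data.frame(bin_lo = breaks[-length(breaks)],
                   bin_hi = breaks[-1],
                   count = as.integer(table(bin)))
  list(histogram = hist, log_binned = lb)
}

#' Attach module labels to network nodes
#'
#' Labels are attached verbatim; a label for a gene absent from the
#' network is an error. Nodes without a label get `NA`.
#'
#' @param network a [cca_network()].
#' @param labels named character vector (names = genes).
#' @return the network with a `module` node column.
#' @export
assign_modules <- function(network, labels) {
  unknown <- setdiff(names(labels), network$nodes$gene)
  if (length(unknown))
    stop("label(s) for gene(s) not in network: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  network$nodes$module <- unname(labels[network$nodes$gene])
  network
}

#' Greedy modularity module detection (experimental convenience)
#'
#' Runs fast-greedy modularity-maximization agglomeration. The published
#' analysis this package mirrors delineated its two modules manually, so
#' detected labels are a convenience for exploration, never a substitute
#' for supplied labels in module-level statistics.
#'
#' @param network a connected-or-not [cca_network()].
#' @param seed RNG seed (the greedy algorithm itself is deterministic; the
#'   seed guards any tie-breaking).
#' @return named character vector of module labels ("M1", "M2", ...).
#' @export
detect_modules <- function(network, seed = 1L) {
  g <- as_igraph(network)
  set.seed(seed)
  cl <- igraph::cluster_fast_greedy(igraph::simplify(g))
  mem <- igraph::membership(cl)
  stats::setNames(paste0("M", as.integer(mem)), names(mem))
}

#' Export node metrics as TSV (gene, frequency, degree, CC)
#' @param network a [cca_network()] built with frequencies.
#' @param path output path.
#' @export
write_node_metrics <- function(network, path) {
  nd <- network$nodes
  cols <- intersect(c("gene", "raw_freq", "corrected_freq", "degree",
                      "cc", "module", "location", "exon_count",
                      "length_bp"), names(nd))
  utils::write.table(nd[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
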