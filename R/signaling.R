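# Where co-occurring pairs sit in pathways and the signaling network, and
# which signal types they use. Null models: uniform edge rewiring (same
# node set, same link count, degree NOT preserved) for pathway
# co-membership; uniform typed-link resampling for signal-type usage.

#' Count co-occurring edges whose endpoints share a pathway
#'
#' Each co-occurring network edge counts once no matter how many pathways
#' its endpoints share; anti edges are excluded.
#'
#' @param network a [cca_network()].
#' @param pathways a `pathway_collection` (named list of gene vectors).
#' @return integer count.
#' @export
same_pathway_pair_count <- function(network, pathways) {
  e <- network$edges[network$edges$relation == "co", , drop = FALSE]
  if (nrow(e) == 0) return(0L)
  .count_comember_pairs(e$from, e$to, pathways)
}

.count_comember_pairs <- function(from, to, pathways) {
  shared <- logical(length(from))
  for (set in pathways) {
    shared <- shared | (from %in% set & to %in% set)
  }
  sum(shared)
}

#' Uniform random rewiring of a network
#'
#' Redraws the same number of links uniformly without replacement from
#' all unordered node pairs over the same node set: no self-loops, no
#' duplicate edges, degree sequence not preserved. Edge relations are
#' carried over in order (they do not matter to co-membership counting,
#' which is done on the rewired edge list as a whole).
#'
#' @param network a [cca_network()].
#' @return a rewired [cca_network()].
#' @export
rewire_random <- function(network) {
  genes <- network$nodes$gene
  n <- length(genes)
  m <- n_edges(network)
  cap <- n * (n - 1) / 2
  if (m > cap) stop("link count exceeds simple-graph capacity")
  idx <- sample.int(cap, m)
  b <- ceiling((1 + sqrt(1 + 8 * idx)) / 2)
  a <- idx - (b - 1) * (b - 2) / 2
  rel <- if (m) network$edges$relation else character(0)
  cca_network(network$nodes,
              data.frame(from = genes[a], to = genes[b], relation = rel,
                         stringsAsFactors = FALSE))
}

#' Degree-preserving rewiring (sensitivity-analysis alternative)
#'
#' Double-edge swaps via igraph's `keeping_degseq` rewiring. Offered as a
#' stricter null than [rewire_random()]; relations are reassigned in
#' original order.
#'
#' @param network a [cca_network()].
#' @param n_swaps number of attempted swaps (default 10 x edges).
#' @return a rewired [cca_network()].
#' @export
rewire_degree_preserving <- function(network, n_swaps = 10 * n_edges(network)) {
  g <- as_igraph(network)
  g2 <- igraph::rewire(g, igraph::keeping_degseq(niter = n_swaps))
  el <- igraph::as_edgelist(g2)
  cca_network(network$nodes,
              data.frame(from = el[, 1], to = el[, 2],
                         relation = network$edges$relation,
                         stringsAsFactors = FALSE))
}

#' Randomization test for pathway co-membership of co-occurring pairs
#'
#' Observed statistic: [same_pathway_pair_count()]. Null: the same count
#' on `R` uniformly rewired networks. p = (T + 1)/(R + 1) with T the
#' number of null counts >= observed.
#'
#' @param network a [cca_network()].
#' @param pathways a `pathway_collection`.
#' @param R replicates (default 5000).
#' @param seed RNG seed.
#' @param degree_preserving use degree-preserving swaps instead of uniform
#'   rewiring (default FALSE).
#' @return a [randomization_p()] result.
#' @export
pathway_comembership_test <- function(network, pathways, R = 5000,
                                      seed = 1L, degree_preserving = FALSE) {
  stopifnot(R >= 1)
  obs <- same_pathway_pair_count(network, pathways)
  set.seed(seed)
  nulls <- vapply(seq_len(R), function(i) {
    rw <- if (degree_preserving) rewire_degree_preserving(network)
          else rewire_random(network)
    stopifnot(n_nodes(rw) == n_nodes(network),
              n_edges(rw) == n_edges(network))
    # on the rewired graph every drawn edge is a candidate co pair
    .count_comember_pairs(rw$edges$from, rw$edges$to, pathways)
  }, numeric(1))
  randomization_p(obs, nulls, tail = "ge")
}

.direct_link_keys <- function(sn, typed_only = FALSE) {
  l <- sn$links
  if (typed_only) l <- l[l$type != "unknown", , drop = FALSE]
  unique(paste(pmin(l$source, l$target), pmax(l$source, l$target),
               sep = "\r"))
}

#' Enrichment of direct signaling links among co-occurring pairs
#'
#' Universe: unordered pairs of network genes mappable to the signaling
#' network. Rows of the 2x2 table: pair is / is not a co-occurring edge;
#' columns: pair has / lacks a direct signaling link (any type, direction
#' ignored). Fisher test via [fisher_exact_two_sided()].
#'
#' @param network a [cca_network()].
#' @param signaling a [signaling_network()].
#' @return list with `table` (2x2), `p_value`, `odds_ratio`,
#'   `frac_linked_co`, `frac_linked_other`, `n_mapped`.
#' @export
direct_interaction_enrichment <- function(network, signaling) {
  sig_nodes <- unique(c(signaling$links$source, signaling$links$target))
  mapped <- intersect(network$nodes$gene, sig_nodes)
  if (length(mapped) < 2)
    stop("fewer than 2 network genes map to the signaling network")
  pairs <- utils::combn(sort(mapped), 2)
  key <- paste(pairs[1, ], pairs[2, ], sep = "\r")
  e <- network$edges[network$edges$relation == "co", , drop = FALSE]
  co_keys <- paste(pmin(e$from, e$to), pmax(e$from, e$to), sep = "\r")
  is_co <- key %in% co_keys
  linked <- key %in% .direct_link_keys(signaling)
  tab <- matrix(c(sum(is_co & linked), sum(is_co & !linked),
                  sum(!is_co & linked), sum(!is_co & !linked)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("co_edge", "not_co_edge"),
                                c("linked", "not_linked")))
  ft <- fisher_exact_two_sided(c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
  list(table = tab, p_value = ft$p_value, odds_ratio = ft$odds_ratio,
       frac_linked_co = if (sum(is_co)) mean(linked[is_co]) else NA_real_,
       frac_linked_other = if (sum(!is_co)) mean(linked[!is_co]) else NA_real_,
       n_mapped = length(mapped))
}

#' Signal-type usage of directly linked co-occurring pairs
#'
#' Over co-occurring pairs that have at least one direct typed signaling
#' link, counts typed links by category (a pair with several typed links
#' contributes each once). Unknown-type links are excluded from all
#' denominators; expected fractions come from the whole signaling
#' network's typed-link composition.
#'
#' @param network a [cca_network()].
#' @param signaling a [signaling_network()].
#' @return list of class `signal_usage`: `counts`, `fractions`,
#'   `expected_fractions`, `n_links`.
#' @export
signal_type_usage <- function(network, signaling) {
  e <- network$edges[network$edges$relation == "co", , drop = FALSE]
  co_keys <- paste(pmin(e$from, e$to), pmax(e$from, e$to), sep = "\r")
  l <- signaling$links[signaling$links$type != "unknown", , drop = FALSE]
  lk <- paste(pmin(l$source, l$target), pmax(l$source, l$target),
              sep = "\r")
  # each distinct (pair, type) link counts once
  hit <- lk %in% co_keys
  hits <- unique(data.frame(key = lk[hit], type = l$type[hit]))
  cats <- c("activation", "repression", "physical")
  counts <- vapply(cats, function(t) sum(hits$type == t), integer(1))
  n <- sum(counts)
  fr <- if (n > 0) counts / n else stats::setNames(rep(NA_real_, 3), cats)
  structure(list(counts = counts, fractions = fr,
                 expected_fractions = signaling_type_fractions(signaling),
                 n_links = n),
            class = "signal_usage")
}

#' Significance tests for signal-type usage
#'
#' Chi-square goodness of fit of the observed typed-link category counts
#' against the signaling network's expected proportions (df = categories
#' with positive expectation minus 1), plus a link-resampling
#' randomization: each replicate draws the same number of links uniformly
#' from the signaling network's typed links and counts activation and
#' repression links; `p_activation` tests preference (null >= observed),
#' `p_repression` avoidance (null <= observed). The joint (activation,
#' repression) null grid is returned for heat-map plotting.
#'
#' @param usage a `signal_usage` from [signal_type_usage()].
#' @param signaling the [signaling_network()].
#' @param R randomization replicates (default 5000).
#' @param seed RNG seed.
#' @return list with `chisq_stat`, `chisq_df`, `chisq_p`,
#'   `p_activation`, `p_repression` ([randomization_p()] results), and
#'   `null_grid` (data.frame n_activation / n_repression / count).
#' @export
signal_usage_tests <- function(usage, signaling, R = 5000, seed = 1L) {
  counts <- usage$counts
  n <- sum(counts)
  if (n < 1) stop("no typed links among co-occurring pairs")
  expp <- usage$expected_fractions
  if (any(expp == 0 & counts > 0))
    stop("observed count in a category with zero expected proportion")
  keep <- expp > 0
  exp_cnt <- n * expp[keep]
  stat <- sum((counts[keep] - exp_cnt)^2 / exp_cnt)
  df <- sum(keep) - 1
  chisq_p <- stats::pchisq(stat, df, lower.tail = FALSE)
  l <- signaling$links[signaling$links$type != "unknown", , drop = FALSE]
  set.seed(seed)
  null_act <- integer(R); null_rep <- integer(R)
  for (i in seq_len(R)) {
    tp <- l$type[sample.int(nrow(l), n)]
    null_act[i] <- sum(tp == "activation")
    null_rep[i] <- sum(tp == "repression")
  }
  grid <- as.data.frame(table(n_activation = null_act,
                              n_repression = null_rep),
                        stringsAsFactors = FALSE)
  grid$n_activation <- as.integer(grid$n_activation)
  grid$n_repression <- as.integer(grid$n_repression)
  names(grid)[3] <- "count"
  list(chisq_stat = stat, chisq_df = df, chisq_p = chisq_p,
       p_activation = randomization_p(counts[["activation"]], null_act,
                                      tail = "ge"),
       p_repression = randomization_p(counts[["repression"]], null_rep,
                                      tail = "le"),
       null_grid = grid)
}
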