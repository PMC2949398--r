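# Randomization engine, AD statistic, expression-similarity-vs-distance
# analysis, attribute correlations and the rank-sum test.

#' Absolute difference of mutation frequency (AD)
#'
#' `AD = |freq_a - freq_b|` for two network-adjacent genes; symmetric,
#' non-negative. Co-occurring pairs are expected to have small AD (shared
#' driver events mutate both genes together), anti pairs large AD.
#'
#' @param freq_a,freq_b mutation frequencies (>= 0).
#' @return the absolute difference.
#' @export
ad_statistic <- function(freq_a, freq_b) {
  stopifnot(all(freq_a >= 0), all(freq_b >= 0))
  abs(freq_a - freq_b)
}

#' Two-sided rank-sum (Mann-Whitney / Wilcoxon) test
#'
#' Exact enumeration of all group assignments for combined n <= 12 (with
#' ties handled by mid-ranks), normal approximation with tie correction
#' and continuity correction otherwise.
#'
#' @param sample_a,sample_b nonempty numeric vectors.
#' @return two-sided p-value.
#' @export
rank_sum_test <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) stop("empty sample")
  na <- length(sample_a); nb <- length(sample_b)
  pooled <- c(sample_a, sample_b)
  r <- rank(pooled)
  W <- sum(r[seq_len(na)])          # rank sum of group A
  if (na + nb <= 12) {
    combs <- utils::combn(na + nb, na)
    allW <- colSums(matrix(r[combs], nrow = na))
    mu <- na * (na + nb + 1) / 2
    p <- mean(abs(allW - mu) >= abs(W - mu) - 1e-9)
    return(min(1, p))
  }
  mu <- na * (na + nb + 1) / 2
  n <- na + nb
  ties <- table(pooled)
  tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_corr)
  if (sigma2 <= 0) return(1)  # all values tied
  z <- (abs(W - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
}

.edge_ad <- function(edges, freq) {
  fa <- freq[edges$from]; fb <- freq[edges$to]
  unname(ad_statistic(fa, fb))
}

#' Compare AD of co-occurring, anti-co-occurring and random pairs
#'
#' Three comparisons: (1) co vs anti AD by the two-sided rank-sum test;
#' (2) co median AD against the median AD of `R` random groups, each the
#' same number of unordered node pairs drawn uniformly from the network's
#' nodes, tail `le` (co pairs should sit below the null); (3) the same
#' for anti pairs with tail `ge`.
#'
#' @param network a [cca_network()].
#' @param frequencies named numeric vector of per-gene mutation
#'   frequencies covering the network genes (raw frequencies by default
#'   usage; pass corrected values to switch).
#' @param R random groups (default 5000).
#' @param seed RNG seed.
#' @return list with `ad_co`, `ad_anti` (numeric vectors),
#'   `co_vs_anti_p`, `co_vs_random` and `anti_vs_random`
#'   ([randomization_p()] results, NULL when the edge class is empty).
#' @export
ad_comparison <- function(network, frequencies, R = 5000, seed = 1L) {
  genes <- network$nodes$gene
  if (!all(genes %in% names(frequencies)))
    stop("frequencies missing for some network genes")
  freq <- frequencies[genes]
  e <- network$edges
  ad_co <- .edge_ad(e[e$relation == "co", , drop = FALSE], freq)
  ad_anti <- .edge_ad(e[e$relation == "anti", , drop = FALSE], freq)
  co_vs_anti_p <- if (length(ad_co) && length(ad_anti))
    rank_sum_test(ad_co, ad_anti) else NA_real_
  set.seed(seed)
  random_group_medians <- function(k) {
    vapply(seq_len(R), function(i) {
      ia <- sample.int(length(genes), k, replace = TRUE)
      ib <- sample.int(length(genes) - 1L, k, replace = TRUE)
      ib <- ib + (ib >= ia)          # uniform pair with distinct endpoints
      stats::median(ad_statistic(freq[ia], freq[ib]))
    }, numeric(1))
  }
  co_vs_random <- NULL
  if (length(ad_co))
    co_vs_random <- randomization_p(stats::median(ad_co),
                                    random_group_medians(length(ad_co)),
                                    tail = "le")
  anti_vs_random <- NULL
  if (length(ad_anti)) {
    anti_vs_random <- randomization_p(stats::median(ad_anti),
                                      random_group_medians(length(ad_anti)),
                                      tail = "ge")
  } else {
    message("no anti-co-occurring edges; anti-vs-random comparison skipped")
  }
  list(ad_co = ad_co, ad_anti = ad_anti, co_vs_anti_p = co_vs_anti_p,
       co_vs_random = co_vs_random, anti_vs_random = anti_vs_random)
}

#' Expression similarity of two genes
#'
#' Absolute Pearson correlation of the two expression profiles across
#' tissues. Constant profiles have undefined correlation; such pairs are
#' flagged `NA` and excluded downstream.
#'
#' @param expr an [expression_matrix()].
#' @param gene_a,gene_b gene ids (rows of `expr`).
#' @return |r| in \[0, 1\], or `NA` for a constant profile.
#' @export
expression_similarity <- function(expr, gene_a, gene_b) {
  for (g in c(gene_a, gene_b))
    if (!g %in% rownames(expr)) stop("gene not in expression matrix: ", g)
  if (ncol(expr) < 3) stop("need >= 3 tissues")
  a <- expr[gene_a, ]; b <- expr[gene_b, ]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  abs(stats::cor(a, b))
}

#' Spearman rank correlation with a p-value
#'
#' Tie-corrected: rho is the Pearson correlation of mid-ranks; p from the
#' t approximation (the convention of standard statistical software for
#' tied data).
#'
#' @param x,y numeric vectors.
#' @return list with `rho` and `p`.
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE))
}

#' Network distance versus expression similarity
#'
#' Pairwise: Spearman correlation between shortest-path distance and
#' absolute-Pearson expression similarity over all finite-distance,
#' defined-similarity gene pairs. Grouped: pairs binned by integer
#' distance, group mean similarity correlated with distance (removes the
#' bias from many pairs sharing one distance value).
#'
#' @param network a [cca_network()].
#' @param expr an [expression_matrix()] covering the network genes.
#' @return list with `pairwise` (rho, p, n_pairs) and `grouped`
#'   (data.frame distance / mean_similarity / n plus rho, p; NULL when
#'   fewer than 2 distance groups exist).
#' @export
distance_similarity_analysis <- function(network, expr) {
  genes <- intersect(network$nodes$gene, rownames(expr))
  if (length(genes) < 2) stop("fewer than 2 network genes have expression")
  D <- shortest_path_distances(network)[genes, genes, drop = FALSE]
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[pairs]
  sim <- vapply(seq_len(nrow(pairs)), function(i)
    expression_similarity(expr, genes[pairs[i, 1]], genes[pairs[i, 2]]),
    numeric(1))
  ok <- is.finite(d) & !is.na(sim)
  d <- d[ok]; sim <- sim[ok]
  if (length(d) < 2) stop("fewer than 2 usable pairs")
  pw <- spearman_cor(d, sim)
  grouped <- NULL
  gm <- tapply(sim, d, mean)
  if (length(gm) >= 2) {
    gd <- as.numeric(names(gm))
    gc <- spearman_cor(gd, as.numeric(gm))
    grouped <- list(table = data.frame(distance = gd,
                                       mean_similarity = as.numeric(gm),
                                       n = as.integer(table(d))),
                    rho = gc$rho, p = gc$p)
  }
  list(pairwise = list(rho = pw$rho, p = pw$p, n_pairs = length(d)),
       grouped = grouped)
}

#' Spearman correlations between network and gene attributes
#'
#' Computes rank correlations for the standard attribute pairs: degree
#' against exon count, gene length and mutation frequency; clustering
#' coefficient against frequency and degree; frequency against length.
#' Pairwise-complete observations; constant attributes yield `NA` rows.
#'
#' @param network a [cca_network()] whose nodes carry `degree`, `cc` and
#'   (after building with frequencies/metadata) `raw_freq`, `exon_count`,
#'   `length_bp`.
#' @return data.frame with columns `var_a`, `var_b`, `rho`, `p`, `n`.
#' @export
attribute_correlations <- function(network) {
  nd <- network$nodes
  specs <- list(c("degree", "exon_count"), c("degree", "length_bp"),
                c("degree", "raw_freq"), c("cc", "raw_freq"),
                c("cc", "degree"), c("raw_freq", "length_bp"))
  rows <- lapply(specs, function(sp) {
    if (!all(sp %in% names(nd)))
      return(data.frame(var_a = sp[1], var_b = sp[2], rho = NA_real_,
                        p = NA_real_, n = 0L))
    x <- nd[[sp[1]]]; y <- nd[[sp[2]]]
    ok <- stats::complete.cases(x, y)
    sc <- spearman_cor(x[ok], y[ok])
    data.frame(var_a = sp[1], var_b = sp[2], rho = sc$rho, p = sc$p,
               n = sum(ok))
  })
  do.call(rbind, rows)
}

#' Median degree and clustering coefficient per cellular location
#'
#' Medians ordered along the signaling axis extracellular -> membrane ->
#' cytoplasm -> nucleus; unknown-location nodes are excluded. A
#' non-strict monotone-trend flag is attached for each metric.
#'
#' @param network a [cca_network()] with `location` node attribute.
#' @return data.frame location / n / median_degree / median_cc with
#'   attributes `monotone_degree`, `monotone_cc`.
#' @export
location_gradient <- function(network) {
  nd <- network$nodes
  if (!"location" %in% names(nd)) stop("network nodes lack 'location'")
  order_loc <- c("extracellular", "membrane", "cytoplasm", "nucleus")
  rows <- lapply(order_loc, function(loc) {
    sel <- !is.na(nd$location) & nd$location == loc
    data.frame(location = loc, n = sum(sel),
               median_degree = if (any(sel))
                 stats::median(nd$degree[sel]) else NA_real_,
               median_cc = if (any(sel))
                 stats::median(nd$cc[sel]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  mono <- function(v) { v <- v[!is.na(v)]; length(v) < 2 || all(diff(v) >= 0) }
  attr(out, "monotone_degree") <- mono(out$median_degree)
  attr(out, "monotone_cc") <- mono(out$median_cc)
  out
}
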