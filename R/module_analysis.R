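# Two-module functional and mutational contrasts: gene-set enrichment,
# methylation enrichment, per-sample module hit distribution with its
# mutation-count-preserving null, and the module frequency comparison.

#' Hypergeometric over-representation of gene sets in a module
#'
#' One-sided hypergeometric p per set: the probability of drawing at
#' least the observed overlap when `|module|` genes are sampled from the
#' background without replacement. Genes outside the background are
#' ignored. Sets with `p <= alpha` are flagged enriched.
#'
#' @param module_genes character vector, subset of `background`.
#' @param background character vector (the gene universe, e.g. all genes
#'   of both modules).
#' @param gene_sets named list of character vectors.
#' @param alpha significance level (default 0.05).
#' @return data.frame set / set_size / overlap / p / enriched, ordered by p.
#' @export
geneset_enrichment <- function(module_genes, background, gene_sets,
                               alpha = 0.05) {
  background <- unique(background)
  if (!length(background)) stop("empty background")
  if (!all(module_genes %in% background))
    stop("module_genes must be a subset of background")
  module_genes <- unique(module_genes)
  N <- length(background); n <- length(module_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), background)
    K <- length(set)
    x <- length(intersect(set, module_genes))
    p <- if (K == 0) 1 else
      stats::phyper(x - 1, n, N - n, K, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = x, p = p)
  })
  out <- do.call(rbind, rows)
  out$enriched <- out$p <= alpha
  out[order(out$p, out$set), , drop = FALSE]
}

#' Fisher test for methylation enrichment between two modules
#'
#' 2x2 table: rows = the two modules, columns = methylated / not
#' methylated; two-sided Fisher via [fisher_exact_two_sided()].
#'
#' @param module_labels named character vector over genes with exactly
#'   two distinct labels.
#' @param methylated_genes character vector of methylated gene ids.
#' @return list with `table`, `p_value`, `odds_ratio`, `fractions`
#'   (methylated share per module).
#' @export
methylation_enrichment <- function(module_labels, methylated_genes) {
  mods <- sort(unique(module_labels))
  if (length(mods) != 2) stop("need exactly two modules, got ",
                              length(mods))
  g1 <- names(module_labels)[module_labels == mods[1]]
  g2 <- names(module_labels)[module_labels == mods[2]]
  m1 <- sum(g1 %in% methylated_genes); m2 <- sum(g2 %in% methylated_genes)
  tab <- matrix(c(m1, length(g1) - m1, m2, length(g2) - m2),
                nrow = 2, byrow = TRUE,
                dimnames = list(mods, c("methylated", "not_methylated")))
  ft <- fisher_exact_two_sided(c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
  list(table = tab, p_value = ft$p_value, odds_ratio = ft$odds_ratio,
       fractions = stats::setNames(c(m1 / length(g1), m2 / length(g2)),
                                   mods))
}

#' Distribution of sample mutations over two modules, with null model
#'
#' Classifies each sample of an independent cohort by where its mutated
#' module genes fall: both modules, only Module One, only Module Two, or
#' neither (no mutated module gene; counted and logged). The null keeps
#' each sample's number of mutated module genes fixed and reassigns those
#' mutations to module genes uniformly at random, then reclassifies. Two
#' outputs beyond the counts: the joint null grid over (M, N) — M =
#' samples with >= 1 mutation in Module Two, N = samples mutated only in
#' Module Two — and the randomization p that at least the observed number
#' of samples carry a Module One mutation.
#'
#' @param sample_mutations named list: per sample, character vector of
#'   mutated genes.
#' @param module_labels named character vector with exactly two labels;
#'   the first label sorted is "Module One".
#' @param R null replicates (default 5000).
#' @param seed RNG seed.
#' @return list with `n_both`, `n_only1`, `n_only2`, `n_neither`,
#'   `module_one_coverage` ([randomization_p()], tail ge on the count of
#'   samples hitting Module One), `p_both_random` (null share of samples
#'   hitting both modules), `null_grid` (data.frame M / N / count).
#' @export
sample_module_distribution <- function(sample_mutations, module_labels,
                                       R = 5000, seed = 1L) {
  mods <- sort(unique(module_labels))
  if (length(mods) != 2) stop("need exactly two modules")
  mod_genes <- names(module_labels)
  lab <- unname(module_labels)
  classify <- function(k1, k2) {
    # vectors of per-sample counts of mutated genes in module 1 / 2
    c(both = sum(k1 > 0 & k2 > 0), only1 = sum(k1 > 0 & k2 == 0),
      only2 = sum(k1 == 0 & k2 > 0), neither = sum(k1 == 0 & k2 == 0))
  }
  counts1 <- vapply(sample_mutations, function(g)
    sum(g %in% mod_genes[lab == mods[1]]), integer(1))
  counts2 <- vapply(sample_mutations, function(g)
    sum(g %in% mod_genes[lab == mods[2]]), integer(1))
  obs <- classify(counts1, counts2)
  if (obs["neither"] > 0)
    message(obs["neither"], " sample(s) with no mutated module gene")
  ktot <- counts1 + counts2
  n_mod <- length(mod_genes)
  n1 <- sum(lab == mods[1])
  set.seed(seed)
  null_M <- integer(R); null_N <- integer(R); null_hit1 <- integer(R)
  null_both <- integer(R)
  for (r in seq_len(R)) {
    r1 <- vapply(ktot, function(k)
      if (k == 0) 0L else sum(sample.int(n_mod, k) <= n1), integer(1))
    r2 <- ktot - r1
    cl <- classify(r1, r2)
    null_M[r] <- cl[["both"]] + cl[["only2"]]
    null_N[r] <- cl[["only2"]]
    null_hit1[r] <- cl[["both"]] + cl[["only1"]]
    null_both[r] <- cl[["both"]]
  }
  grid <- as.data.frame(table(M = null_M, N = null_N),
                        stringsAsFactors = FALSE)
  grid$M <- as.integer(grid$M); grid$N <- as.integer(grid$N)
  names(grid)[3] <- "count"
  obs_hit1 <- obs[["both"]] + obs[["only1"]]
  list(n_both = obs[["both"]], n_only1 = obs[["only1"]],
       n_only2 = obs[["only2"]], n_neither = obs[["neither"]],
       module_one_coverage = randomization_p(obs_hit1, null_hit1,
                                             tail = "ge"),
       p_both_random = mean(null_both) / length(sample_mutations),
       null_grid = grid)
}

#' Rank-sum comparison of mutation frequencies between two modules
#'
#' @param module_labels named character vector with two labels.
#' @param frequencies named numeric vector of per-gene frequencies.
#' @return list with `p` (two-sided rank-sum), `median_1`, `median_2`.
#' @export
module_frequency_comparison <- function(module_labels, frequencies) {
  mods <- sort(unique(module_labels))
  if (length(mods) != 2) stop("need exactly two modules")
  f1 <- frequencies[names(module_labels)[module_labels == mods[1]]]
  f2 <- frequencies[names(module_labels)[module_labels == mods[2]]]
  f1 <- f1[!is.na(f1)]; f2 <- f2[!is.na(f2)]
  if (!length(f1) || !length(f2)) stop("a module has no frequency data")
  list(p = rank_sum_test(f1, f2),
       median_1 = stats::median(f1), median_2 = stats::median(f2))
}
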