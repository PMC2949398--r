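# Shared fixture builders. Everything is constructed in code; no binary
# files ship with the package.

# small mutation matrix from a 0/1/NA matrix literal
mm_from <- function(m, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(ncol(m)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(nrow(m)))
  dimnames(m) <- list(samples, genes)
  mutation_matrix(m)
}

# triangle a-b-c plus helper shapes
net_triangle <- function() {
  cca_network(c("a", "b", "c"),
              data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
                         relation = "co"))
}

net_path <- function(n = 3, relation = "co") {
  genes <- letters[seq_len(n)]
  cca_network(genes,
              data.frame(from = genes[-n], to = genes[-1],
                         relation = relation))
}

net_star <- function(k = 3) {
  leaves <- paste0("l", seq_len(k))
  cca_network(c("hub", leaves),
              data.frame(from = "hub", to = leaves, relation = "co"))
}

# Erdos-Renyi random cca_network
net_random <- function(n, p, seed) {
  set.seed(seed)
  genes <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(genes, 2))
  keep <- stats::runif(nrow(pairs)) < p
  cca_network(genes,
              data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                         relation = "co"))
}

# independent oracle: two-sided Fisher p by explicit enumeration of all
# tables with the observed margins, using factorial arithmetic only
fisher_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  if (n == 0) return(1)
  r1 <- a + b; c1 <- a + c
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  prob_of <- function(x) {
    exp(lfactorial(r1) + lfactorial(n - r1) + lfactorial(c1) +
          lfactorial(n - c1) - lfactorial(n) - lfactorial(x) -
          lfactorial(r1 - x) - lfactorial(c1 - x) -
          lfactorial(n - r1 - c1 + x))
  }
  p_obs <- prob_of(a)
  ps <- vapply(lo:hi, prob_of, numeric(1))
  min(1, sum(ps[ps <= p_obs * (1 + 1e-7)]))
}

# independent oracle: clustering coefficient by brute-force neighbour-pair
# counting on the raw edge list
cc_oracle <- function(network, node) {
  e <- network$edges
  nb <- unique(c(e$to[e$from == node], e$from[e$to == node]))
  k <- length(nb)
  if (k < 2) return(0)
  cnt <- 0
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    u <- nb[i]; v <- nb[j]
    if (any((e$from == u & e$to == v) | (e$from == v & e$to == u)))
      cnt <- cnt + 1
  }
  2 * cnt / (k * (k - 1))
}
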