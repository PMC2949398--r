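# Per-gene mutation frequency and per-pair co-occurrence inference.
#
# The per-pair test conditions on the samples sequenced for BOTH genes:
# panels differ between studies, so a sample screened for only one gene of
# a pair is uninformative and must not enter any of the four counts.

#' Contingency counts for a gene pair
#'
#' Over the samples sequenced for both genes, counts samples mutated in
#' both (`n_ab`), in A only (`n_a_only`), in B only (`n_b_only`) and in
#' neither (`n_neither`). The four counts always sum to the number of
#' co-sequenced samples.
#'
#' @param mm a [mutation_matrix()].
#' @param gene_a,gene_b gene ids present in the matrix.
#' @return list of class `pair_contingency`.
#' @export
pair_contingency <- function(mm, gene_a, gene_b) {
  st <- mm$status
  for (g in c(gene_a, gene_b))
    if (!g %in% colnames(st)) stop("gene not in matrix: ", g)
  a <- st[, gene_a]; b <- st[, gene_b]
  both <- !is.na(a) & !is.na(b)
  if (!any(both))
    stop(sprintf("no sample sequenced for both '%s' and '%s'",
                 gene_a, gene_b))
  a <- a[both]; b <- b[both]
  structure(list(gene_a = gene_a, gene_b = gene_b,
                 n_ab = sum(a == 1L & b == 1L),
                 n_a_only = sum(a == 1L & b == 0L),
                 n_b_only = sum(a == 0L & b == 1L),
                 n_neither = sum(a == 0L & b == 0L)),
            class = "pair_contingency")
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' The two-sided p-value sums the hypergeometric probabilities of all
#' tables with the observed margins whose point probability does not
#' exceed that of the observed table (point-probability method). The odds
#' ratio is the sample odds ratio `(n_ab * n_neither) / (n_a_only *
#' n_b_only)`; when any cell is zero, 0.5 is added to every cell first so
#' that mutually exclusive pairs with `n_ab = 0` still yield a directional
#' (finite, < 1) estimate.
#'
#' @param ct a `pair_contingency`, 2x2 matrix, or length-4 vector
#'   `(n_ab, n_a_only, n_b_only, n_neither)`.
#' @return list with `p_value` and `odds_ratio` (`NA` for the all-zero
#'   degenerate table, where `p_value = 1`).
#' @export
fisher_exact_two_sided <- function(ct) {
  cnt <- .as_counts(ct)
  a <- cnt[1]; b <- cnt[2]; c <- cnt[3]; d <- cnt[4]
  n <- a + b + c + d
  if (n == 0) return(list(p_value = 1, odds_ratio = NA_real_))
  m1 <- a + b     # margin: mutated in A
  n1 <- c + d
  k <- a + c      # margin: mutated in B
  lo <- max(0L, k - n1); hi <- min(k, m1)
  support <- lo:hi
  logp <- stats::dhyper(support, m1, n1, k, log = TRUE)
  logp_obs <- stats::dhyper(a, m1, n1, k, log = TRUE)
  # relative tolerance guards against log-scale rounding (as fisher.test)
  p <- sum(exp(logp[logp <= logp_obs + 1e-7]))
  p <- min(1, p)
  if (any(cnt == 0)) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    or <- (a * d) / (b * c)
  }
  list(p_value = p, odds_ratio = or)
}

.as_counts <- function(ct) {
  if (inherits(ct, "pair_contingency"))
    cnt <- c(ct$n_ab, ct$n_a_only, ct$n_b_only, ct$n_neither)
  else if (is.matrix(ct)) cnt <- c(ct[1, 1], ct[1, 2], ct[2, 1], ct[2, 2])
  else cnt <- as.numeric(ct)
  if (length(cnt) != 4 || any(cnt < 0) || any(cnt != round(cnt)))
    stop("need four non-negative integer counts")
  as.integer(cnt)
}

#' Classify a tested pair as co-occurring, anti-co-occurring or unlinked
#'
#' Pairs with `p <= cutoff` are linked: odds ratio above 1 means the
#' mutations co-occur, below 1 that they are mutually exclusive. An odds
#' ratio of exactly 1 carries no direction and stays unlinked.
#'
#' @param p_value Fisher p.
#' @param odds_ratio sample odds ratio (continuity-corrected when needed).
#' @param cutoff significance cutoff on the raw p (default 0.02).
#' @return one of `"co"`, `"anti"`, `"none"`.
#' @export
classify_relation <- function(p_value, odds_ratio, cutoff = 0.02) {
  if (is.na(p_value) || is.na(odds_ratio)) return("none")
  if (p_value > cutoff || odds_ratio == 1) return("none")
  if (odds_ratio > 1) "co" else "anti"
}

#' Test every gene pair of a mutation matrix
#'
#' Computes the contingency table, two-sided Fisher p and odds ratio for
#' every unordered gene pair with at least `min_cosequenced` co-sequenced
#' samples, attaches Benjamini-Hochberg q-values over all performed tests,
#' and classifies each pair. Ordering is deterministic (lexicographic pair
#' ids). Pairs below the overlap threshold are skipped and counted in the
#' `n_skipped` attribute.
#'
#' @param mm a [mutation_matrix()] with >= 2 genes.
#' @param cutoff p-value cutoff for the relation call (default 0.02; FDR
#'   q-values are reported but do not gate linking).
#' @param min_cosequenced minimum co-sequenced sample count (default 1).
#' @return data.frame of class `pair_test_results`: `gene_a`, `gene_b`,
#'   the four counts, `p_value`, `odds_ratio`, `fdr_q`, `relation`.
#' @export
all_pair_tests <- function(mm, cutoff = 0.02, min_cosequenced = 1) {
  st <- mm$status
  if (ncol(st) < 2) stop("need at least 2 genes")
  genes <- sort(colnames(st))
  st <- st[, genes, drop = FALSE]
  S <- !is.na(st)                     # sequenced mask
  M <- S & st == 1L; M[is.na(M)] <- FALSE
  Ms <- 1 * M; Ss <- 1 * S
  n_ab <- crossprod(Ms)               # both sequenced because mutated => sequenced
  n_a <- crossprod(Ms, Ss * (1 - Ms)) # A mutated, B sequenced wildtype
  n_coseq <- crossprod(Ss)
  idx <- which(upper.tri(n_ab), arr.ind = TRUE)
  ia <- idx[, 1]; ib <- idx[, 2]
  coseq <- n_coseq[idx]
  keep <- coseq >= max(1, min_cosequenced)
  n_skipped <- sum(!keep)
  ia <- ia[keep]; ib <- ib[keep]
  ab <- n_ab[cbind(ia, ib)]
  aonly <- n_a[cbind(ia, ib)]
  bonly <- n_a[cbind(ib, ia)]
  neither <- coseq[keep] - ab - aonly - bonly
  np <- length(ia)
  pv <- numeric(np); or <- numeric(np)
  for (i in seq_len(np)) {
    ft <- fisher_exact_two_sided(c(ab[i], aonly[i], bonly[i], neither[i]))
    pv[i] <- ft$p_value; or[i] <- ft$odds_ratio
  }
  q <- if (np) stats::p.adjust(pv, method = "BH") else numeric(0)
  rel <- vapply(seq_len(np), function(i)
    classify_relation(pv[i], or[i], cutoff), character(1))
  out <- data.frame(gene_a = genes[ia], gene_b = genes[ib],
                    n_ab = ab, n_a_only = aonly, n_b_only = bonly,
                    n_neither = neither, p_value = pv, odds_ratio = or,
                    fdr_q = q, relation = rel, stringsAsFactors = FALSE)
  o <- order(out$gene_a, out$gene_b)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  attr(out, "cutoff") <- cutoff
  class(out) <- c("pair_test_results", "data.frame")
  out
}

#' Mutation frequency of a gene
#'
#' Raw frequency = mutated samples / sequenced samples; the length-
#' corrected frequency divides the raw frequency by gene length in bp,
#' removing the gene-size confounder on mutation counts.
#'
#' @param mm a [mutation_matrix()].
#' @param gene gene id.
#' @param metadata optional gene metadata (defaults to the matrix's own);
#'   required for the corrected frequency.
#' @return list of class `gene_frequency` with `gene_id`, `n_sequenced`,
#'   `n_mutated`, `raw_freq`, `corrected_freq` (NA without metadata).
#' @export
mutation_frequency <- function(mm, gene, metadata = mm$metadata) {
  st <- mm$status
  if (!gene %in% colnames(st)) stop("gene not in matrix: ", gene)
  v <- st[, gene]
  n_seq <- sum(!is.na(v))
  if (n_seq == 0) stop("gene never sequenced: ", gene)
  n_mut <- sum(v == 1L, na.rm = TRUE)
  raw <- n_mut / n_seq
  corrected <- NA_real_
  if (!is.null(metadata)) {
    i <- match(gene, metadata$gene_id)
    if (!is.na(i)) corrected <- raw / metadata$length_bp[i]
  }
  structure(list(gene_id = gene, n_sequenced = n_seq, n_mutated = n_mut,
                 raw_freq = raw, corrected_freq = corrected),
            class = "gene_frequency")
}

#' Mutation frequencies for all genes of a matrix
#'
#' @param mm a [mutation_matrix()].
#' @param metadata optional metadata for length correction.
#' @return data.frame with one row per gene sequenced in >= 1 sample.
#' @export
mutation_frequencies <- function(mm, metadata = mm$metadata) {
  st <- mm$status
  n_seq <- colSums(!is.na(st))
  n_mut <- colSums(st == 1L, na.rm = TRUE)
  keep <- n_seq > 0
  raw <- n_mut[keep] / n_seq[keep]
  corrected <- rep(NA_real_, sum(keep))
  if (!is.null(metadata)) {
    i <- match(colnames(st)[keep], metadata$gene_id)
    corrected <- raw / metadata$length_bp[i]
  }
  data.frame(gene = colnames(st)[keep], n_sequenced = n_seq[keep],
             n_mutated = n_mut[keep], raw_freq = raw,
             corrected_freq = corrected, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write pair test results as TSV
#' @param results a `pair_test_results` data.frame.
#' @param path output path.
#' @export
write_pair_tests <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
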