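#' @keywords internal
"_PACKAGE"

# Status codes inside a mutation matrix: NA = not sequenced,
# 0 = sequenced wildtype, 1 = sequenced with >=1 mutation.

#' Construct a mutation matrix container
#'
#' A `mutation_matrix` wraps a samples x genes integer status matrix in
#' which `NA` marks a (sample, gene) cell that was never sequenced, `0` a
#' sequenced wildtype cell and `1` a sequenced cell carrying at least one
#' somatic mutation. Optional per-gene metadata (length, exon count,
#' cellular location) rides along for frequency correction and attribute
#' analyses.
#'
#' @param status integer/numeric matrix, samples in rows, genes in columns,
#'   values in \{NA, 0, 1\}; dimnames required.
#' @param metadata optional `data.frame` with columns `gene_id`,
#'   `length_bp`, `exon_count`, `location`.
#' @return an object of class `mutation_matrix`.
#' @export
mutation_matrix <- function(status, metadata = NULL) {
  if (!is.matrix(status)) stop("`status` must be a matrix")
  if (is.null(rownames(status)) || is.null(colnames(status)))
    stop("`status` must have sample rownames and gene colnames")
  bad <- !(is.na(status) | status == 0L | status == 1L)
  if (any(bad)) stop("status values must be NA, 0 or 1")
  storage.mode(status) <- "integer"
  if (!is.null(metadata)) metadata <- validate_gene_metadata(metadata)
  structure(list(status = status, metadata = metadata),
            class = "mutation_matrix")
}

validate_gene_metadata <- function(metadata) {
  needed <- c("gene_id", "length_bp", "exon_count", "location")
  missing_cols <- setdiff(needed, names(metadata))
  if (length(missing_cols))
    stop("gene metadata lacks columns: ", paste(missing_cols, collapse = ", "))
  if (any(metadata$length_bp <= 0)) stop("length_bp must be > 0")
  if (any(metadata$exon_count < 1)) stop("exon_count must be >= 1")
  locs <- c("extracellular", "membrane", "cytoplasm", "nucleus", "unknown")
  if (!all(metadata$location %in% locs))
    stop("location must be one of: ", paste(locs, collapse = ", "))
  if (anyDuplicated(metadata$gene_id)) stop("duplicated gene_id in metadata")
  metadata
}

#' @export
print.mutation_matrix <- function(x, ...) {
  st <- x$status
  cat(sprintf("mutation_matrix: %d samples x %d genes\n", nrow(st), ncol(st)))
  cat(sprintf("  sequenced cells: %d (%.1f%%), mutated cells: %d\n",
              sum(!is.na(st)), 100 * mean(!is.na(st)),
              sum(st == 1L, na.rm = TRUE)))
  if (!is.null(x$metadata)) cat("  gene metadata attached\n")
  invisible(x)
}

#' Construct a co-occurrence/anti-co-occurrence (CCA) network
#'
#' An undirected simple graph whose nodes are genes and whose edges mark
#' statistically significant co-occurrence (`relation = "co"`) or mutual
#' exclusivity (`relation = "anti"`) of their mutations. Node attributes
#' (frequency, degree, clustering coefficient, module, location, ...) are
#' held in a `nodes` data frame, edges in an `edges` data frame.
#'
#' @param nodes data.frame with at least a `gene` column.
#' @param edges data.frame with columns `from`, `to`, `relation`.
#' @return object of class `cca_network`.
#' @export
cca_network <- function(nodes, edges) {
  if (is.character(nodes)) nodes <- data.frame(gene = nodes)
  stopifnot(is.data.frame(nodes), "gene" %in% names(nodes))
  if (nrow(edges) == 0) {
    edges <- data.frame(from = character(), to = character(),
                        relation = character())
  }
  stopifnot(all(c("from", "to", "relation") %in% names(edges)))
  if (anyDuplicated(nodes$gene)) stop("duplicated node ids")
  if (any(edges$from == edges$to)) stop("self-loops are not allowed")
  if (!all(edges$relation %in% c("co", "anti")))
    stop("edge relation must be 'co' or 'anti'")
  miss <- setdiff(c(edges$from, edges$to), nodes$gene)
  if (length(miss)) stop("edge endpoint(s) not in node set: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  # canonical unordered representation, lexicographic within the pair
  a <- pmin(edges$from, edges$to); b <- pmax(edges$from, edges$to)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) stop("parallel edges are not allowed")
  o <- order(a, b)
  edges <- data.frame(from = a[o], to = b[o],
                      relation = edges$relation[o],
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "cca_network")
}

#' @export
print.cca_network <- function(x, ...) {
  cat(sprintf("cca_network: %d nodes, %d edges (%d co, %d anti)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$relation == "co"),
              sum(x$edges$relation == "anti")))
  invisible(x)
}

#' Number of nodes / edges of a CCA network
#' @param network a `cca_network`.
#' @return integer count.
#' @export
n_nodes <- function(network) nrow(network$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(network) nrow(network$edges)

#' Convert a CCA network to an igraph object
#'
#' Used internally for components, community detection and as an
#' independent cross-check of the hand-rolled metrics.
#'
#' @param network a `cca_network`.
#' @return an undirected `igraph` graph with `relation` edge attribute.
#' @export
as_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = network$nodes)
  g
}

#' Construct a typed cellular signaling network
#'
#' Links carry a type: `activation` and `repression` links are directed,
#' `physical` links undirected, and `unknown` links have no usable type.
#' Type composition (counts and fractions over typed links) is queryable
#' via [signaling_type_counts()].
#'
#' @param links data.frame with columns `source`, `target`, `type`.
#' @param dedup drop exactly duplicated rows with a warning (default TRUE).
#' @return object of class `signaling_network`.
#' @export
signaling_network <- function(links, dedup = TRUE) {
  stopifnot(all(c("source", "target", "type") %in% names(links)))
  types <- c("activation", "repression", "physical", "unknown")
  bad <- setdiff(unique(links$type), types)
  if (length(bad)) stop("unknown link type token(s): ",
                        paste(bad, collapse = ", "))
  key <- paste(links$source, links$target, links$type, sep = "\r")
  if (anyDuplicated(key)) {
    if (!dedup) stop("duplicated links present")
    warning(sum(duplicated(key)), " duplicated link(s) removed")
    links <- links[!duplicated(key), , drop = FALSE]
  }
  rownames(links) <- NULL
  structure(list(links = links), class = "signaling_network")
}

#' Per-type link counts of a signaling network
#' @param sn a `signaling_network`.
#' @return named integer vector over activation/repression/physical/unknown.
#' @export
signaling_type_counts <- function(sn) {
  types <- c("activation", "repression", "physical", "unknown")
  out <- vapply(types, function(t) sum(sn$links$type == t), integer(1))
  out
}

#' Fractions of typed links (unknown-type links excluded)
#' @param sn a `signaling_network`.
#' @return named numeric vector over activation/repression/physical, sums to 1.
#' @export
signaling_type_fractions <- function(sn) {
  cnt <- signaling_type_counts(sn)[c("activation", "repression", "physical")]
  if (sum(cnt) == 0) stop("no typed links in the signaling network")
  cnt / sum(cnt)
}

#' @export
print.signaling_network <- function(x, ...) {
  cnt <- signaling_type_counts(x)
  cat(sprintf(
    "signaling_network: %d links (%d activation, %d repression, %d physical, %d unknown)\n",
    nrow(x$links), cnt["activation"], cnt["repression"], cnt["physical"],
    cnt["unknown"]))
  invisible(x)
}

#' Randomization-test result container
#'
#' Holds the observed statistic, the null sample from `R` replicates, the
#' exceedance count `T` and the empirical p-value `(T + 1) / (R + 1)`.
#'
#' @param observed observed statistic (scalar).
#' @param null_values numeric vector of null replicate statistics.
#' @param tail `"ge"` counts null >= observed, `"le"` counts null <= observed.
#' @return object of class `randomization_result` with fields `observed`,
#'   `R`, `T`, `p`, `tail`, `null_sample`.
#' @export
randomization_p <- function(observed, null_values, tail = c("ge", "le")) {
  tail <- match.arg(tail)
  if (length(null_values) < 1) stop("empty null sample")
  if (!is.finite(observed)) stop("observed statistic must be finite")
  T_exceed <- if (tail == "ge") sum(null_values >= observed)
              else sum(null_values <= observed)
  R <- length(null_values)
  structure(list(observed = observed, R = R, T = T_exceed,
                 p = (T_exceed + 1) / (R + 1), tail = tail,
                 null_sample = null_values),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf("randomization test: observed = %g, R = %d, T = %d, p = %.4g (tail %s)\n",
              x$observed, x$R, x$T, x$p, x$tail))
  invisible(x)
}
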