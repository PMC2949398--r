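# Readers/writers for every external representation the pipeline touches:
# long/wide mutation TSV, Pajek NET, GMT gene sets, typed signaling edge
# lists, expression matrices, plain gene lists and two-column label files.

#' Read a mutation table
#'
#' Canonical dialect is long format: a TSV with header columns
#' `sample_id`, `gene_id`, `status` where status is `0` (sequenced
#' wildtype), `1` (sequenced, mutated) or `NA` (not sequenced). A wide
#' dialect (first column sample ids, remaining columns one gene each) is
#' auto-detected from the header. Cells absent from a long file default to
#' not-sequenced unless `assume_sequenced = TRUE`, in which case they
#' become sequenced wildtype — per-mutation exports list only mutated
#' cells, so screening status must be supplied or assumed.
#'
#' @param path TSV file path.
#' @param assume_sequenced treat absent (sample, gene) cells as sequenced
#'   wildtype rather than not sequenced.
#' @param metadata optional gene metadata data.frame to attach.
#' @return a [mutation_matrix()].
#' @export
read_mutation_table <- function(path, assume_sequenced = FALSE,
                                metadata = NULL) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  long <- all(c("sample_id", "gene_id", "status") %in% header)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL)
  if (long) {
    .mutation_from_long(df, assume_sequenced, metadata)
  } else {
    .mutation_from_wide(df, metadata)
  }
}

.parse_status <- function(tok, where) {
  out <- rep(NA_integer_, length(tok))
  tok_trim <- trimws(tok)
  isna <- tok_trim %in% c("NA", "na", "")
  ok0 <- tok_trim == "0"; ok1 <- tok_trim == "1"
  bad <- !(isna | ok0 | ok1)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("unknown status token '%s' at %s %d", tok[i], where, i))
  }
  out[ok0] <- 0L; out[ok1] <- 1L
  out
}

.mutation_from_long <- function(df, assume_sequenced, metadata) {
  status <- .parse_status(df$status, "row")
  key <- paste(df$sample_id, df$gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
    agg <- tapply(status[dup], key[dup], function(v) length(unique(v)))
    if (any(agg > 1)) {
      offender <- names(agg)[agg > 1][1]
      stop("conflicting status for duplicated (sample, gene) pair: ",
           gsub("\r", " / ", offender))
    }
    keep <- !duplicated(key)
    df <- df[keep, , drop = FALSE]; status <- status[keep]
  }
  samples <- unique(df$sample_id); genes <- unique(df$gene_id)
  fill <- if (assume_sequenced) 0L else NA_integer_
  mat <- matrix(fill, nrow = length(samples), ncol = length(genes),
                dimnames = list(samples, genes))
  mat[cbind(match(df$sample_id, samples), match(df$gene_id, genes))] <- status
  mutation_matrix(mat, metadata)
}

.mutation_from_wide <- function(df, metadata) {
  samples <- df[[1]]
  if (anyDuplicated(samples)) stop("duplicated sample_id rows in wide table")
  genes <- names(df)[-1]
  mat <- matrix(NA_integer_, length(samples), length(genes),
                dimnames = list(samples, genes))
  for (j in seq_along(genes)) {
    mat[, j] <- .parse_status(df[[j + 1L]],
                              sprintf("column '%s', row", genes[j]))
  }
  mutation_matrix(mat, metadata)
}

#' Write / read a mutation matrix in long TSV form
#' @param mm a [mutation_matrix()].
#' @param path output path.
#' @return `write_mutation_table` invisibly returns `path`.
#' @export
write_mutation_table <- function(mm, path) {
  st <- mm$status
  df <- data.frame(
    sample_id = rep(rownames(st), times = ncol(st)),
    gene_id = rep(colnames(st), each = nrow(st)),
    status = ifelse(is.na(as.vector(st)), "NA", as.character(as.vector(st))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a CCA network in Pajek NET format
#'
#' Vertices are written 1-based with quoted labels; each edge carries a
#' value encoding its relation (1 = co-occurring, 2 = anti-co-occurring),
#' noted in a header comment because NET has no attribute block.
#'
#' @param network a [cca_network()] with at least one node.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pajek <- function(network, path) {
  if (n_nodes(network) < 1) stop("refusing to write an empty network")
  genes <- network$nodes$gene
  idx <- stats::setNames(seq_along(genes), genes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("% edge value: 1 = co-occurring, 2 = anti-co-occurring",
               sprintf("*Vertices %d", length(genes)),
               sprintf('%d "%s"', seq_along(genes), genes),
               "*Edges"), con)
  if (n_edges(network) > 0) {
    val <- ifelse(network$edges$relation == "co", 1L, 2L)
    writeLines(sprintf("%d %d %d", idx[network$edges$from],
                       idx[network$edges$to], val), con)
  }
  invisible(path)
}

#' Read a Pajek NET file into a CCA network
#'
#' Accepts the common NET subset: a `*Vertices` block with 1-based ids and
#' optionally quoted labels, then `*Edges` (or `*Arcs`, treated as
#' undirected) with optional edge values. Edge value 2 decodes to an
#' anti-co-occurring link; a missing or any other value defaults to
#' co-occurring, since published network files do not always encode the
#' relation.
#'
#' @param path NET file path.
#' @return a [cca_network()].
#' @export
read_pajek <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*%", lines) & nzchar(trimws(lines))]
  vhead <- grep("^\\*[Vv]ertices", lines)
  if (length(vhead) != 1) stop("malformed NET file: need one *Vertices header")
  nv <- suppressWarnings(as.integer(sub("^\\*[Vv]ertices\\s+", "", lines[vhead])))
  if (is.na(nv) || nv < 1) stop("malformed *Vertices count")
  ehead <- grep("^\\*([Ee]dges|[Aa]rcs)", lines)
  vend <- if (length(ehead)) min(ehead) - 1L else length(lines)
  vlines <- lines[seq(vhead + 1L, vend)]
  labels <- character(nv)
  seen <- logical(nv)
  for (ln in vlines) {
    m <- regmatches(ln, regexec('^\\s*(\\d+)\\s+(?:"([^"]*)"|(\\S+))', ln))[[1]]
    if (length(m) == 0) stop("malformed vertex line: ", ln)
    i <- as.integer(m[2])
    if (i < 1 || i > nv) stop("vertex index out of range: ", i)
    labels[i] <- if (nzchar(m[3])) m[3] else m[4]
    seen[i] <- TRUE
  }
  if (!all(seen)) labels[!seen] <- paste0("v", which(!seen))
  edges <- data.frame(from = character(), to = character(),
                      relation = character())
  if (length(ehead)) {
    elines <- lines[seq(min(ehead) + 1L, length(lines))]
    elines <- elines[!grepl("^\\*", elines)]
    if (length(elines)) {
      parts <- strsplit(trimws(elines), "\\s+")
      f <- vapply(parts, function(p) as.integer(p[1]), integer(1))
      t <- vapply(parts, function(p) as.integer(p[2]), integer(1))
      v <- vapply(parts, function(p)
        if (length(p) >= 3) suppressWarnings(as.numeric(p[3])) else NA_real_,
        numeric(1))
      if (any(is.na(f) | is.na(t))) stop("malformed edge line")
      if (any(f < 1 | f > nv | t < 1 | t > nv))
        stop("edge vertex index out of range")
      edges <- data.frame(from = labels[f], to = labels[t],
                          relation = ifelse(!is.na(v) & v == 2, "anti", "co"))
    }
  }
  cca_network(data.frame(gene = labels), edges)
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then member genes, tab-separated.
#' Members are de-duplicated within a set; sets empty after de-duplication
#' are dropped with a warning; blank lines are skipped.
#'
#' @param path GMT file path.
#' @return named list of character vectors (class `pathway_collection`).
#' @export
read_gene_sets_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("GMT line with fewer than 3 fields: ", ln)
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) {
      warning("gene set '", parts[1], "' empty after de-duplication; dropped")
      next
    }
    sets[[parts[1]]] <- genes
  }
  structure(sets, class = "pathway_collection")
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gene_sets_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a typed signaling network edge list
#'
#' TSV with header `source`, `target`, `type`; type must be one of
#' activation, repression, physical, unknown. Exactly duplicated rows are
#' removed with a warning.
#'
#' @param path TSV path.
#' @return a [signaling_network()].
#' @export
read_signaling_network <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  signaling_network(df)
}

#' @rdname read_signaling_network
#' @param sn a `signaling_network`.
#' @export
write_signaling_network <- function(sn, path) {
  utils::write.table(sn$links, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene x tissue expression matrix
#'
#' TSV with genes in rows (first column = gene id) and tissues in columns;
#' body must be numeric. Rows with zero variance are flagged in the
#' `constant` attribute because correlation-based similarity is undefined
#' for them.
#'
#' @param path TSV path.
#' @return numeric matrix with `constant` attribute (logical per gene).
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character")
  genes <- df[[1]]
  body <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                 dimnames = list(genes, colnames(body))))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric expression value at gene '%s', tissue '%s'",
                 genes[idx[1]], colnames(num)[idx[2]]))
  }
  expression_matrix(num)
}

#' Construct an expression matrix object (flags constant rows)
#' @param mat numeric matrix, genes x tissues, with dimnames.
#' @return the matrix with a logical `constant` attribute per gene.
#' @export
expression_matrix <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (is.null(rownames(mat))) stop("expression matrix needs gene rownames")
  attr(mat, "constant") <- apply(mat, 1, function(v) stats::sd(v) == 0)
  mat
}

#' @rdname read_expression_matrix
#' @param expr expression matrix.
#' @export
write_expression_matrix <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain gene list (one id per line)
#' @param path text file path.
#' @return character vector, de-duplicated, blank lines dropped.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}

#' Read / write module label assignments
#'
#' Two-column TSV `gene_id` / `module`; returns a named character vector
#' (names = genes, values = module labels).
#'
#' @param path TSV path.
#' @return named character vector of module labels.
#' @export
read_module_labels <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  stopifnot(all(c("gene_id", "module") %in% names(df)))
  if (anyDuplicated(df$gene_id)) stop("duplicated gene_id in label file")
  stats::setNames(df$module, df$gene_id)
}

#' @rdname read_module_labels
#' @param labels named character vector.
#' @export
write_module_labels <- function(labels, path) {
  utils::write.table(
    data.frame(gene_id = names(labels), module = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene metadata TSV
#'
#' Columns: `gene_id`, `length_bp`, `exon_count`, `location`.
#' @param path TSV path.
#' @return validated metadata data.frame.
#' @export
read_gene_metadata <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "numeric",
                                         "integer", "character"))
  validate_gene_metadata(df)
}

#' @rdname read_gene_metadata
#' @param metadata metadata data.frame.
#' @export
write_gene_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
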