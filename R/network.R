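#' Gene-gene networks as symmetric binary adjacency
#'
#' A `gene_network` holds an undirected, unweighted gene graph: an ordered
#' vector of unique gene symbols, a symmetric binary sparse adjacency matrix
#' with zero diagonal, and the per-gene degree. All edges are collapsed to
#' simple undirected edges; self-loops are dropped on construction.
#'
#' @param edges A data frame whose first two columns give the gene pairs of
#'   the edges (extra columns are ignored). Direction, duplicates and
#'   reciprocal rows are collapsed; self-loops are removed.
#' @return A `gene_network` object with fields `genes` (lexicographically
#'   sorted gene ids), `adjacency` (symmetric `dgCMatrix` of 0/1), and
#'   `degree` (named integer vector).
#' @examples
#' net <- as_gene_network(data.frame(from = c("TF1", "G1"), to = c("G1", "TF1")))
#' net$degree
#' @export
as_gene_network <- function(edges) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2) {
    abort("edge table must have at least two columns")
  }
  from <- as.character(edges[[1]])
  to <- as.character(edges[[2]])
  keep <- from != to
  from <- from[keep]
  to <- to[keep]
  genes <- sort(unique(c(from, to)))
  if (length(genes) == 0) {
    abort("no edges: the edge table is empty after removing self-loops")
  }
  i <- match(pmin(from, to), genes)
  j <- match(pmax(from, to), genes)
  pair_key <- paste(i, j)
  dup <- duplicated(pair_key)
  i <- i[dup == FALSE]
  j <- j[dup == FALSE]
  adj <- Matrix::sparseMatrix(
    i = c(i, j), j = c(j, i), x = 1,
    dims = c(length(genes), length(genes)),
    dimnames = list(genes, genes)
  )
  adj@x[] <- 1 # collapse any residual multiplicities to binary
  new_gene_network(genes, adj)
}

new_gene_network <- function(genes, adjacency) {
  degree <- as.integer(Matrix::rowSums(adjacency != 0))
  names(degree) <- genes
  structure(
    list(genes = genes, adjacency = adjacency, degree = degree),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf(
    "<gene_network> %d genes, %d edges (%d isolated)\n",
    length(x$genes), n_edges(x), sum(x$degree == 0)
  ))
  invisible(x)
}

#' Number of undirected edges in a gene network
#' @param network A `gene_network`.
#' @return Integer edge count.
#' @export
n_edges <- function(network) {
  as.integer(sum(network$adjacency != 0) / 2)
}

#' Edge table of a gene network
#'
#' @param x A `gene_network`.
#' @param ... Unused.
#' @return A tibble with columns `from` and `to`, each row one undirected
#'   edge in canonical order (lexicographically smaller gene first, rows
#'   sorted).
#' @exportS3Method generics::tidy
tidy.gene_network <- function(x, ...) {
  m <- as(Matrix::triu(x$adjacency), "TsparseMatrix")
  from <- x$genes[m@i + 1L]
  to <- x$genes[m@j + 1L]
  tibble(from = pmin(from, to), to = pmax(from, to)) |>
    arrange(.data$from, .data$to)
}

#' @exportS3Method generics::glance
glance.gene_network <- function(x, ...) {
  tibble(
    n_genes = length(x$genes),
    n_edges = n_edges(x),
    n_isolated = sum(x$degree == 0),
    max_degree = if (length(x$degree)) max(x$degree) else 0L
  )
}

header_keywords <- c(
  "source", "target", "gene", "from", "to", "node1", "node2",
  "gene1", "gene2", "tf", "regulator"
)

#' Read a gene-gene edge list
#'
#' Reads a two-or-more-column delimited edge list (one gene pair per line,
#' extra columns ignored) into a [as_gene_network()] object. Directed pairs
#' (such as transcription factor to target) are symmetrized; duplicate and
#' reciprocal rows collapse to one undirected edge; self-loops are dropped.
#' Gene identifiers are matched by exact, case-sensitive string equality;
#' supply `synonyms` to merge aliases before loading.
#'
#' @param path Path to the edge-list file.
#' @param delim Field delimiter, default tab.
#' @param header `"auto"` (skip the first line when it contains a common
#'   header keyword such as "source", "target" or "gene"), `"yes"`, or
#'   `"no"`.
#' @param synonyms Optional data frame with columns `alias` and `gene`; any
#'   occurrence of `alias` is replaced by `gene` before the network is built.
#' @return A `gene_network`.
#' @export
read_edge_list <- function(path, delim = "\t",
                           header = c("auto", "yes", "no"),
                           synonyms = NULL) {
  header <- match.arg(header)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort(sprintf("no edges: '%s' is empty", path))
  }
  tokens <- strsplit(lines, delim, fixed = TRUE)
  skip_first <- switch(header,
    yes = TRUE,
    no = FALSE,
    auto = any(tolower(trimws(tokens[[1]])) %in% header_keywords)
  )
  start <- if (skip_first) 2L else 1L
  if (start > length(tokens)) {
    abort(sprintf("no edges: '%s' contains only a header line", path))
  }
  short <- which(lengths(tokens[start:length(tokens)]) < 2)
  if (length(short) > 0) {
    abort(sprintf(
      "line %d of '%s' has fewer than 2 fields", short[1] + start - 1L, path
    ))
  }
  from <- trimws(vapply(tokens[start:length(tokens)], `[[`, "", 1L))
  to <- trimws(vapply(tokens[start:length(tokens)], `[[`, "", 2L))
  if (!is.null(synonyms)) {
    synonyms <- as.data.frame(synonyms)
    from_idx <- match(from, synonyms[[1]])
    from[!is.na(from_idx)] <- synonyms[[2]][from_idx[!is.na(from_idx)]]
    to_idx <- match(to, synonyms[[1]])
    to[!is.na(to_idx)] <- synonyms[[2]][to_idx[!is.na(to_idx)]]
  }
  edges <- data.frame(from = from, to = to)
  if (all(edges$from == edges$to)) {
    abort(sprintf("no edges: '%s' contains only self-loops", path))
  }
  as_gene_network(edges)
}

#' Write a gene network as a canonical edge list
#'
#' Emits a tab-separated edge list with a `from`/`to` header, the
#' lexicographically smaller gene first on each row and rows sorted, so that
#' write followed by read reproduces an identical edge set.
#'
#' @param network A `gene_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  readr::write_tsv(tidy(network), path)
  invisible(path)
}

#' Threshold a co-expression correlation matrix into a network
#'
#' Genes i and j (i != j) are connected iff their correlation is strictly
#' above `threshold` (default 0.25, the conventional co-expression cut-off).
#'
#' @param correlation A square symmetric numeric matrix with gene ids as
#'   dimnames, or a data frame whose first column holds gene ids and whose
#'   remaining columns are the correlation values (as written by
#'   [read_correlation_matrix()]).
#' @param threshold Correlation cut-off in (-1, 1); edges require
#'   correlation strictly greater than this value.
#' @return A `gene_network` over all genes of the matrix (genes with no
#'   supra-threshold partner become isolated nodes).
#' @export
threshold_coexpression <- function(correlation, threshold = 0.25) {
  if (is.data.frame(correlation)) {
    ids <- as.character(correlation[[1]])
    correlation <- as.matrix(correlation[, -1, drop = FALSE])
    rownames(correlation) <- ids
  }
  if (!is.matrix(correlation) || nrow(correlation) != ncol(correlation)) {
    abort("correlation input must be a square matrix")
  }
  if (is.null(rownames(correlation))) {
    abort("correlation matrix must carry gene ids as dimnames")
  }
  if (max(abs(correlation - Matrix::t(correlation))) > 1e-8) {
    abort("correlation matrix is not symmetric")
  }
  if (!(threshold > -1 && threshold < 1)) {
    abort("threshold must lie in (-1, 1)")
  }
  genes <- sort(rownames(correlation))
  correlation <- correlation[genes, genes]
  hit <- which(correlation > threshold & upper.tri(correlation), arr.ind = TRUE)
  adj <- Matrix::sparseMatrix(
    i = c(hit[, 1], hit[, 2]), j = c(hit[, 2], hit[, 1]), x = 1,
    dims = c(length(genes), length(genes)),
    dimnames = list(genes, genes)
  )
  new_gene_network(genes, adj)
}

#' Read a square correlation matrix
#'
#' @param path TSV with gene ids as the first row and first column.
#' @return A numeric matrix with gene dimnames, suitable for
#'   [threshold_coexpression()].
#' @export
read_correlation_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  m
}

#' Align a network with the measured gene universe
#'
#' Extends the node set of `network` to the union of its own genes and
#' `measured_genes`. Measured genes absent from the network become isolated
#' nodes; network genes that were never measured are retained so no edges
#' are lost. This is the universe on which scores are propagated: unmeasured
#' nodes carry zero seed but still conduct.
#'
#' @param network A `gene_network`.
#' @param measured_genes Character vector of measured (expression) gene ids.
#' @return A `gene_network` over the union, with an attribute
#'   `measured_index` giving the node index of each measured gene.
#' @export
align_universe <- function(network, measured_genes) {
  measured_genes <- unique(as.character(measured_genes))
  genes <- sort(union(network$genes, measured_genes))
  idx <- match(network$genes, genes)
  m <- as(network$adjacency, "TsparseMatrix")
  adj <- Matrix::sparseMatrix(
    i = idx[m@i + 1L], j = idx[m@j + 1L], x = 1,
    dims = c(length(genes), length(genes)),
    dimnames = list(genes, genes)
  )
  out <- new_gene_network(genes, adj)
  attr(out, "measured_index") <- setNames(match(measured_genes, genes), measured_genes)
  out
}
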