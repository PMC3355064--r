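#' Correlation seeding of the gene universe
#'
#' Assigns each network node the absolute correlation of its measured
#' expression with patient survival time, the starting value of the network
#' propagation. Nodes that were not measured, genes failing the filter mask,
#' and zero-variance genes get a seed of exactly 0.
#'
#' @param expr Gene-level expression tibble (first column `gene`, remaining
#'   columns samples) restricted to the samples the seed may see (training
#'   samples during cross-validation).
#' @param survival_months Survival times aligned with the sample columns of
#'   `expr`.
#' @param network A `gene_network` defining the node universe.
#' @param mask Optional filter mask from [compute_filter_mask()]; genes whose
#'   selected probe set failed the filter keep a zero seed.
#' @param method Correlation flavor, `"pearson"` (default) or `"spearman"`.
#' @return A seed tibble with columns `gene` (network node order) and `seed`.
#' @export
correlation_seed <- function(expr, survival_months, network,
                             mask = NULL, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- expr_values(expr)
  if (length(survival_months) != ncol(m)) {
    abort("survival_months must align with the expression samples")
  }
  if (ncol(m) < 3) {
    abort("need at least 3 samples to correlate expression with survival")
  }
  eligible <- rownames(m)
  if (!is.null(mask)) {
    eligible <- intersect(eligible, mask$gene[mask$selected])
  }
  r <- abs_cor_with(m[eligible, , drop = FALSE], survival_months, method)
  seed <- setNames(numeric(length(network$genes)), network$genes)
  hit <- intersect(eligible, network$genes)
  seed[hit] <- r[hit]
  tibble(gene = network$genes, seed = unname(seed))
}

# |cor| of each matrix row with y; zero-variance rows -> 0
abs_cor_with <- function(m, y, method) {
  if (nrow(m) == 0) {
    return(setNames(numeric(0), character(0)))
  }
  r <- suppressWarnings(as.numeric(cor(Matrix::t(m), y, method = method)))
  r[is.na(r)] <- 0
  setNames(abs(r), rownames(m))
}

#' Constant (topology-only) seed
#'
#' Gives every node the same value 1/n, so that running the propagation
#' ranks genes by network topology alone, independent of expression.
#'
#' @param network A `gene_network`.
#' @return A seed tibble with columns `gene` and `seed`.
#' @export
constant_seed <- function(network) {
  n <- length(network$genes)
  tibble(gene = network$genes, seed = rep(1 / n, n))
}

# align a seed (tibble gene/seed, named vector, or plain vector in node
# order) with the network nodes; unknown nodes -> 0
align_seed <- function(seed, network) {
  genes <- network$genes
  if (is.data.frame(seed)) {
    v <- setNames(numeric(length(genes)), genes)
    hit <- intersect(as.character(seed[[1]]), genes)
    v[hit] <- seed[[2]][match(hit, as.character(seed[[1]]))]
  } else if (!is.null(names(seed))) {
    v <- setNames(numeric(length(genes)), genes)
    hit <- intersect(names(seed), genes)
    v[hit] <- seed[hit]
  } else {
    if (length(seed) != length(genes)) {
      abort("unnamed seed vector must match the node count")
    }
    v <- setNames(as.numeric(seed), genes)
  }
  if (any(v < 0)) abort("seed values must be nonnegative")
  v
}

new_netrank_ranking <- function(network, seed_vec, scores, d,
                                iterations, converged, variant) {
  out <- tibble(gene = network$genes, seed = unname(seed_vec), score = unname(scores))
  class(out) <- c("netrank_ranking", class(out))
  attr(out, "d") <- d
  attr(out, "iterations") <- iterations
  attr(out, "converged") <- converged
  attr(out, "variant") <- variant
  out
}

#' @export
print.netrank_ranking <- function(x, ...) {
  cat(sprintf(
    "<netrank ranking> variant=%s d=%s iterations=%s converged=%s\n",
    attr(x, "variant"),
    format(attr(x, "d")), format(attr(x, "iterations")), attr(x, "converged")
  ))
  NextMethod()
}

#' @describeIn netrank_solve Tidy a ranking: genes ordered by decreasing
#'   score (ties lexicographic) with a `rank` column.
#' @param x A `netrank_ranking`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.netrank_ranking <- function(x, ...) {
  out <- as_tibble(x)
  out <- arrange(out, desc(.data$score), .data$gene)
  out$rank <- seq_len(nrow(out))
  out
}

#' @exportS3Method generics::glance
glance.netrank_ranking <- function(x, ...) {
  tibble(
    variant = attr(x, "variant"),
    d = attr(x, "d"),
    iterations = attr(x, "iterations"),
    converged = attr(x, "converged"),
    n_genes = nrow(x)
  )
}

#' Damped network propagation of survival correlations
#'
#' NetRank scores every node of a gene network by mixing its own seed value
#' (the absolute expression-survival correlation) with the degree-normalized
#' scores of its neighbors:
#' \deqn{r_i = (1-d)\,c_i + d \sum_j A_{ij} r_j / \mathrm{deg}_j,}
#' a PageRank-style fixed point. `netrank_solve()` computes it exactly by
#' solving the sparse linear system \eqn{(I - d\,A D^{-1})\,r = (1-d)\,c};
#' `netrank_iterate()` runs the update to convergence and serves as the
#' iterative counterpart (the two agree to solver precision for d < 1).
#' Degree-zero nodes emit nothing and receive \eqn{r_i = (1-d) c_i}. At
#' d = 1 the system is singular and the score is the stationary mass of the
#' simple random walk: within each connected component, proportional to node
#' degree and scaled so the component keeps its total seed mass.
#'
#' @param network A `gene_network`.
#' @param seed Seed values: a tibble from [correlation_seed()] /
#'   [constant_seed()], a named vector, or a plain vector in node order.
#'   Nonnegative; nodes missing from the seed get 0.
#' @param d Damping factor in \[0, 1\]: 0 means no network influence
#'   (scores equal the seeds), 1 means topology only.
#' @param tol Max-norm convergence tolerance for the iteration.
#' @param max_iter Iteration cap; non-convergence is flagged, not an error.
#' @return A `netrank_ranking`: a tibble (`gene`, `seed`, `score`) carrying
#'   the damping factor, iteration count and convergence flag as attributes.
#'   Use [tidy()] for the sorted ranking.
#' @examples
#' net <- as_gene_network(data.frame(from = c("A", "B"), to = c("B", "C")))
#' tidy(netrank_solve(net, c(A = 1, B = 0, C = 0), d = 0.5))
#' @export
netrank_solve <- function(network, seed, d) {
  check_d(d)
  c_vec <- align_seed(seed, network)
  if (d == 1) {
    scores <- stationary_scores(network, c_vec)
    return(new_netrank_ranking(network, c_vec, scores, d, NA_integer_, TRUE, "netrank"))
  }
  solver <- netrank_solver(network, d)
  scores <- solver(c_vec)
  new_netrank_ranking(network, c_vec, scores, d, NA_integer_, TRUE, "netrank")
}

# factory: pre-factorized sparse solve for (I - d A D^-1) r = (1-d) c
netrank_solver <- function(network, d) {
  if (d == 1) {
    st <- stationary_structure(network)
    return(function(c_vec) stationary_scores_from(st, c_vec))
  }
  n <- length(network$genes)
  inv_deg <- ifelse(network$degree > 0, 1 / network$degree, 0)
  M <- Diagonal(n) - d * network$adjacency %*% Diagonal(x = inv_deg)
  fact <- Matrix::lu(M)
  function(c_vec) {
    as.numeric(Matrix::solve(fact, (1 - d) * c_vec))
  }
}

# d = 1 closed form: degree-proportional within each connected component,
# each component keeping its total seed mass; isolated nodes score 0
stationary_scores <- function(network, c_vec) {
  stationary_scores_from(stationary_structure(network), c_vec)
}

stationary_structure <- function(network) {
  g <- igraph::graph_from_adjacency_matrix(network$adjacency, mode = "undirected")
  comp <- igraph::components(g)$membership
  deg <- as.numeric(network$degree)
  degsum <- as.numeric(rowsum(deg, comp))
  list(comp = comp, deg = deg, degsum = degsum)
}

stationary_scores_from <- function(st, c_vec) {
  mass <- as.numeric(rowsum(as.numeric(c_vec), st$comp))
  scores <- mass[st$comp] * st$deg / pmax(st$degsum[st$comp], 1)
  scores[st$deg == 0] <- 0
  scores
}

check_d <- function(d) {
  if (!is.numeric(d) || length(d) != 1 || is.na(d) || d < 0 || d > 1) {
    abort("damping factor d must be a single value in [0, 1]")
  }
}

#' @rdname netrank_solve
#' @export
netrank_iterate <- function(network, seed, d, tol = 1e-9, max_iter = 10000) {
  check_d(d)
  c_vec <- align_seed(seed, network)
  inv_deg <- ifelse(network$degree > 0, 1 / network$degree, 0)
  A <- network$adjacency
  total <- sum(c_vec)
  r <- c_vec
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    r_new <- (1 - d) * c_vec + d * as.numeric(A %*% (r * inv_deg))
    if (d == 1 && total > 0) {
      s <- sum(r_new)
      if (s > 0) r_new <- r_new * (total / s)
    }
    delta <- max(abs(r_new - r))
    r <- r_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
    if (d == 0) { # fixed point after one pass
      converged <- TRUE
      break
    }
  }
  new_netrank_ranking(network, c_vec, setNames(r, NULL), d, iter, converged, "netrank")
}

#' Direct-neighbor ranking
#'
#' Local variant of the network ranking: each node scores the plain average
#' of the seed values of its direct neighbors (degree-zero nodes score 0).
#'
#' @inheritParams netrank_solve
#' @return A `netrank_ranking` with variant `"neighbor"`.
#' @export
direct_neighbor_rank <- function(network, seed) {
  c_vec <- align_seed(seed, network)
  sums <- as.numeric(network$adjacency %*% c_vec)
  scores <- ifelse(network$degree > 0, sums / network$degree, 0)
  new_netrank_ranking(network, c_vec, scores, NA_real_, NA_integer_, TRUE, "neighbor")
}

#' Extract the top-k gene signature from a ranking
#'
#' Only measured, filter-passing genes are eligible for the signature even
#' though unmeasured network nodes carry scores. Ties are broken towards the
#' lexicographically smaller gene id.
#'
#' @param ranking A `netrank_ranking` or any data frame with `gene` and
#'   `score` columns.
#' @param measured_genes Character vector of eligible genes, or `NULL` to
#'   allow every ranked gene.
#' @param k Signature size, between 1 and the number of eligible genes.
#' @return Character vector of the k top-scoring eligible genes, descending.
#' @export
top_k_signature <- function(ranking, measured_genes = NULL, k) {
  df <- as_tibble(ranking)
  if (!is.null(measured_genes)) {
    df <- df[df$gene %in% measured_genes, , drop = FALSE]
  }
  if (k < 1 || k > nrow(df)) {
    abort(sprintf("k must be between 1 and %d eligible genes", nrow(df)))
  }
  ord <- order(-df$score, df$gene)
  df$gene[ord][seq_len(k)]
}
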