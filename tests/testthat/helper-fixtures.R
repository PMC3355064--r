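# small reusable fixtures, all built in code

path_net <- function() {
  as_gene_network(data.frame(from = c("A", "B"), to = c("B", "C")))
}

star_net <- function(leaves = c("L1", "L2", "L3")) {
  as_gene_network(data.frame(from = "HUB", to = leaves))
}

k4_net <- function() {
  g <- c("A", "B", "C", "D")
  as_gene_network(as.data.frame(t(utils::combn(g, 2))))
}

# random Erdos-Renyi gene_network with at least one edge
random_net <- function(n, p = 0.15, seed = 1) {
  genes <- sprintf("n%03d", seq_len(n))
  withr::with_seed(seed, {
    pairs <- t(utils::combn(seq_len(n), 2))
    keep <- runif(nrow(pairs)) < p
    if (!any(keep)) keep[sample(nrow(pairs), 1)] <- TRUE
    as_gene_network(data.frame(
      from = genes[pairs[keep, 1]], to = genes[pairs[keep, 2]]
    ))
  })
}

# dense reference solve of (I - d A D^-1) r = (1-d) c, independent of the
# package's sparse path
dense_netrank <- function(network, c_vec, d) {
  A <- as.matrix(network$adjacency)
  deg <- rowSums(A)
  inv_deg <- ifelse(deg > 0, 1 / deg, 0)
  M <- diag(nrow(A)) - d * A %*% diag(inv_deg, nrow(A))
  as.numeric(solve(M, (1 - d) * c_vec))
}

# expression tibble from a plain matrix
make_expr <- function(m, id = "gene") {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  out <- tibble::as_tibble(as.data.frame(m))
  out <- dplyr::bind_cols(tibble::tibble(!!id := rownames(m)), out)
  out
}

# tiny cohort tibble
make_cohort <- function(survival, samples = sprintf("s%02d", seq_along(survival))) {
  tibble::tibble(
    sample = samples,
    survival_months = survival,
    prognosis = median_split(survival)
  )
}

# small synthetic study used by several evaluation tests
small_sim <- function(n_genes = 300, seed = 5, ...) {
  net <- simulate_network(n_genes, "scale-free", seed = seed)
  sim <- simulate_cohort(net, seed = seed + 1, ...)
  sim$mask <- compute_filter_mask(sim$expr)
  sim
}
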