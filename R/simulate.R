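#' Generate a gene network for simulation
#'
#' Three topologies are available. `"scale-free"` is preferential
#' attachment: a seed clique on `m + 1` nodes, after which every new node
#' attaches to `m` distinct existing nodes drawn with probability
#' proportional to their current degree; the edge count is therefore exactly
#' `choose(m + 1, 2) + m * (n - m - 1)` and the graph is connected.
#' `"erdos-renyi"` draws each pair independently with probability `p`.
#' `"regular"` is a ring lattice in which every node is joined to its
#' `degree / 2` nearest neighbors on each side. Gene ids are `g00001`,
#' `g00002`, ... and generation is deterministic per `seed`.
#'
#' @param n_genes Number of nodes.
#' @param topology `"scale-free"`, `"erdos-renyi"` or `"regular"`.
#' @param m Attachment edges per new node (scale-free).
#' @param p Edge probability (erdos-renyi); default gives expected degree 4.
#' @param degree Even node degree (regular ring lattice).
#' @param seed Integer RNG seed.
#' @return A `gene_network`.
#' @export
simulate_network <- function(n_genes,
                             topology = c("scale-free", "erdos-renyi", "regular"),
                             m = 2, p = NULL, degree = 4, seed = 1) {
  topology <- match.arg(topology)
  if (n_genes < 3) abort("need at least 3 genes")
  genes <- sprintf("g%05d", seq_len(n_genes))
  edges <- withr::with_seed(seed, switch(topology,
    "scale-free" = {
      if (m < 1 || m >= n_genes) abort("need 1 <= m < n_genes")
      deg <- integer(n_genes)
      from <- integer(0)
      to <- integer(0)
      core <- seq_len(m + 1)
      for (a in core) {
        for (b in core[core > a]) {
          from <- c(from, a)
          to <- c(to, b)
        }
      }
      deg[core] <- m
      from <- c(from, integer(m * (n_genes - m - 1)))
      to <- c(to, integer(m * (n_genes - m - 1)))
      k <- m * (m + 1) / 2
      for (v in seq(m + 2, length.out = n_genes - m - 1)) {
        existing <- seq_len(v - 1)
        targets <- sample(existing, m, prob = deg[existing])
        from[k + seq_len(m)] <- v
        to[k + seq_len(m)] <- targets
        k <- k + m
        deg[v] <- m
        deg[targets] <- deg[targets] + 1L
      }
      data.frame(from = genes[from], to = genes[to])
    },
    "erdos-renyi" = {
      if (is.null(p)) p <- min(1, 4 / (n_genes - 1))
      g <- igraph::sample_gnp(n_genes, p)
      e <- igraph::as_edgelist(g, names = FALSE)
      if (nrow(e) == 0) abort("erdos-renyi draw produced no edges; raise p")
      data.frame(from = genes[e[, 1]], to = genes[e[, 2]])
    },
    "regular" = {
      if (degree %% 2 != 0 || degree < 2 || degree >= n_genes) {
        abort("regular ring lattice needs an even degree in [2, n_genes)")
      }
      half <- degree / 2
      pairs <- do.call(rbind, lapply(seq_len(half), function(offset) {
        cbind(seq_len(n_genes), (seq_len(n_genes) + offset - 1) %% n_genes + 1)
      }))
      data.frame(from = genes[pairs[, 1]], to = genes[pairs[, 2]])
    }
  ))
  net <- as_gene_network(edges)
  if (!setequal(net$genes, genes)) {
    net <- align_universe(net, genes)
    attr(net, "measured_index") <- NULL
  }
  net
}

#' Simulate a survival cohort with a planted prognostic module
#'
#' Emulates the statistical design of a small expression-profiling screen:
#' `n_samples` patients, a gene universe partitioned into four strata, and
#' log-normal survival times driven by a small module of network-adjacent
#' driver genes.
#'
#' The driver module is placed on the highest-degree node and its
#' breadth-first neighborhood (or at random with `placement = "random"`).
#' Driver expression (log2 scale, centered at 8) loads on a latent
#' per-sample prognosis factor with loading `driver_loading`; non-driver
#' direct neighbors of the module load with `neighbor_loading`, mimicking a
#' co-regulated regulon. Survival is
#' `exp(mu_log + beta * mean(driver z-scores) + eps)`, `eps ~ N(0, sigma^2)`,
#' so times are positive and right-skewed. Background genes are independent
#' `N(8, 1)`. A `frac_noise` fraction of genes is low-expression noise
#' (`N(4, 1)`, failing the mean filter) and a `frac_uninformative` fraction
#' is high-expression/low-variance (`N(10, 0.3^2)`, failing the variance
#' filter); uninformative genes share a latent "housekeeping" factor
#' (pairwise loading `uninformative_cor`), so the whole stratum can show a
#' common chance correlation with survival in a finite cohort — the failure
#' mode the variance filter protects against.
#'
#' @param network A `gene_network` covering the gene universe.
#' @param n_samples Number of patients (default 30).
#' @param n_drivers Planted driver genes (default 5).
#' @param beta Effect size of the driver module on log-survival.
#' @param sigma Survival noise standard deviation on the log scale (> 0).
#' @param frac_noise,frac_uninformative Fractions of the gene universe in
#'   the noise and uninformative strata.
#' @param driver_loading,neighbor_loading Latent-factor loadings of driver
#'   and neighbor genes.
#' @param uninformative_cor Latent-factor loading within the uninformative
#'   stratum.
#' @param mu_log Location of log-survival; the default puts the median near
#'   17.5 months.
#' @param placement `"hub"` (highest-degree node and neighborhood) or
#'   `"random"`.
#' @param seed Integer RNG seed; the whole cohort is reproducible from it.
#' @return A `synthetic_cohort` list: `expr` (gene-level tibble), `clinical`
#'   (cohort tibble with prognosis from [median_split()]), `network`,
#'   `drivers`, and `strata` (tibble gene/stratum).
#' @export
simulate_cohort <- function(network, n_samples = 30, n_drivers = 5,
                            beta = 1, sigma = 0.5,
                            frac_noise = 0.25, frac_uninformative = 0.25,
                            driver_loading = 0.5, neighbor_loading = 0.35,
                            regulon_size = 20, uninformative_cor = 0.7,
                            mu_log = log(17.5),
                            placement = c("hub", "random"), seed = 1) {
  placement <- match.arg(placement)
  if (sigma <= 0) abort("sigma must be positive")
  if (frac_noise + frac_uninformative > 1) abort("strata fractions must sum to <= 1")
  genes <- network$genes
  n_genes <- length(genes)
  if (n_drivers >= n_genes) abort("n_drivers must be smaller than the gene universe")

  withr::with_seed(seed, {
    drivers <- place_drivers(network, n_drivers, placement)
    # the co-regulated regulon: a bounded set of ordinary direct neighbors
    # of the module (lowest degree first), not every hub that touches it
    nb_all <- neighbor_genes(network, drivers)
    nb <- sort(head(
      nb_all[order(network$degree[nb_all], nb_all)],
      regulon_size
    ))
    pool <- setdiff(genes, c(drivers, nb))
    n_noise <- round(frac_noise * n_genes)
    n_unif <- round(frac_uninformative * n_genes)
    if (n_noise + n_unif > length(pool)) {
      abort("not enough genes outside the planted module for the noise/uninformative strata")
    }
    # uninformative genes emulate highly expressed, heavily annotated
    # (housekeeping-like) genes: curated networks over-cover them, so they
    # occupy the highest-degree nodes outside the planted module; noise
    # (unexpressed) genes sit on the poorly annotated periphery
    unif_genes <- sort(pool[order(-network$degree[pool], pool)][seq_len(n_unif)])
    rest <- setdiff(pool, unif_genes)
    noise_genes <- sort(sample(rest, n_noise))
    background <- setdiff(rest, noise_genes)

    stratum <- setNames(rep("background", n_genes), genes)
    stratum[drivers] <- "driver"
    stratum[nb] <- "neighbor"
    stratum[noise_genes] <- "noise"
    stratum[unif_genes] <- "uninformative"

    f <- rnorm(n_samples) # prognosis factor
    h <- rnorm(n_samples) # housekeeping factor of the uninformative stratum

    z <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
      dimnames = list(genes, sprintf("s%02d", seq_len(n_samples)))
    )
    ld <- driver_loading
    ln <- neighbor_loading
    lu <- uninformative_cor
    z[drivers, ] <- ld * rep(f, each = length(drivers)) +
      sqrt(1 - ld^2) * z[drivers, , drop = FALSE]
    if (length(nb) > 0) {
      z[nb, ] <- ln * rep(f, each = length(nb)) +
        sqrt(1 - ln^2) * z[nb, , drop = FALSE]
    }
    if (length(unif_genes) > 0) {
      z[unif_genes, ] <- lu * rep(h, each = length(unif_genes)) +
        sqrt(1 - lu^2) * z[unif_genes, , drop = FALSE]
    }

    expr_m <- 8 + z
    expr_m[noise_genes, ] <- 4 + z[noise_genes, , drop = FALSE]
    expr_m[unif_genes, ] <- 10 + 0.3 * z[unif_genes, , drop = FALSE]

    log_surv <- mu_log +
      beta * colMeans(z[drivers, , drop = FALSE]) +
      rnorm(n_samples, sd = sigma)
    survival <- exp(log_surv)

    clinical <- tibble(
      sample = colnames(z),
      survival_months = unname(survival),
      prognosis = median_split(survival)
    )
    expr <- matrix_to_expr(expr_m)
    structure(
      list(
        expr = expr, clinical = clinical, network = network,
        drivers = drivers,
        strata = tibble(gene = genes, stratum = unname(stratum[genes]))
      ),
      class = "synthetic_cohort"
    )
  })
}

# driver module: hub (ties lexicographic) plus breadth-first neighborhood
# taking ordinary (lowest-degree) neighbors first, the typical regulated
# targets rather than competing hubs; errors if the component is too small
place_drivers <- function(network, n_drivers, placement) {
  genes <- network$genes
  if (placement == "random") {
    return(sort(sample(genes, n_drivers)))
  }
  deg <- network$degree
  hub <- genes[order(-deg, genes)][1]
  chosen <- hub
  frontier <- hub
  while (length(chosen) < n_drivers) {
    nxt <- sort(setdiff(neighbor_genes(network, frontier), chosen))
    if (length(nxt) == 0) {
      abort("connected component of the hub is smaller than n_drivers")
    }
    take <- head(nxt, n_drivers - length(chosen))
    chosen <- c(chosen, take)
    frontier <- nxt
  }
  sort(chosen)
}

neighbor_genes <- function(network, of) {
  idx <- match(of, network$genes)
  hit <- which(Matrix::rowSums(network$adjacency[, idx, drop = FALSE] != 0) > 0)
  setdiff(network$genes[hit], of)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d genes x %d samples, %d drivers (%s)\n",
    nrow(x$expr), nrow(x$clinical), length(x$drivers),
    paste(x$drivers, collapse = ", ")
  ))
  invisible(x)
}

#' Fraction of planted drivers recovered in the top of a ranking
#'
#' @param ranked_genes Ordered character vector of genes (best first), or a
#'   data frame with `gene` and `score` columns (ordered by [tidy()] rules).
#' @param planted Character vector of planted driver genes.
#' @param k Ranking depth.
#' @return `|top-k intersect planted| / min(k, |planted|)`.
#' @export
recovery_fraction <- function(ranked_genes, planted, k) {
  if (k < 1) abort("k must be at least 1")
  if (is.data.frame(ranked_genes)) {
    df <- as_tibble(ranked_genes)
    ranked_genes <- df$gene[order(-df$score, df$gene)]
  }
  top <- head(ranked_genes, k)
  length(intersect(top, planted)) / min(k, length(planted))
}
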