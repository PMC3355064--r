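test_that("correlation seeding returns |r| for measured genes and 0 elsewhere", {
  surv <- c(5, 12, 18, 26, 40)
  m <- rbind(
    exact = surv, # |r| = 1
    flat = rep(7, 5), # zero variance -> 0
    g1 = c(8.2, 7.1, 7.9, 6.5, 6.0)
  )
  colnames(m) <- sprintf("s%d", 1:5)
  net <- as_gene_network(data.frame(from = c("exact", "g1"), to = c("flat", "ZZZ")))
  seed <- correlation_seed(make_expr(m), surv, net)
  expect_equal(seed$gene, net$genes)
  expect_equal(seed$seed[seed$gene == "exact"], 1)
  expect_equal(seed$seed[seed$gene == "flat"], 0)
  expect_equal(seed$seed[seed$gene == "ZZZ"], 0) # unmeasured node

  # textbook Pearson formula as an independent oracle
  x <- m["g1", ]
  r_hand <- sum((x - mean(x)) * (surv - mean(surv))) /
    sqrt(sum((x - mean(x))^2) * sum((surv - mean(surv))^2))
  expect_equal(seed$seed[seed$gene == "g1"], abs(r_hand))

  expect_error(
    correlation_seed(make_expr(m[, 1:2]), surv[1:2], net),
    "at least 3 samples"
  )
})

test_that("d = 0 returns the seeds unchanged and d in (0,1) mixes them", {
  net <- random_net(12, 0.3, seed = 2)
  c_vec <- withr::with_seed(9, runif(12))
  names(c_vec) <- net$genes
  r0 <- netrank_solve(net, c_vec, d = 0)
  expect_equal(r0$score, unname(c_vec))
  it0 <- netrank_iterate(net, c_vec, d = 0)
  expect_equal(it0$score, unname(c_vec))
})

test_that("path-graph worked example reproduces the closed-form solution", {
  net <- path_net()
  r <- netrank_solve(net, c(A = 1, B = 0, C = 0), d = 0.5)
  expect_equal(r$score, c(7 / 12, 1 / 3, 1 / 12))
  expect_equal(sum(r$score), 1) # mass conserved
  it <- netrank_iterate(net, c(A = 1, B = 0, C = 0), d = 0.5, tol = 1e-12)
  expect_equal(it$score, c(7 / 12, 1 / 3, 1 / 12), tolerance = 1e-9)
  expect_true(attr(it, "converged"))
})

test_that("complete-graph symmetry yields uniform scores", {
  net <- k4_net()
  for (d in c(0.15, 0.5, 0.85)) {
    r <- netrank_solve(net, rep(0.25, 4), d)
    expect_equal(r$score, rep(0.25, 4))
  }
})

test_that("iteration agrees with the exact solve and a dense reference", {
  for (s in 1:25) {
    net <- random_net(sample(5:30, 1), 0.2, seed = s)
    c_vec <- withr::with_seed(s + 500, runif(length(net$genes)))
    d <- sample(seq(0.1, 0.9, by = 0.1), 1)
    exact <- netrank_solve(net, c_vec, d)$score
    iter <- netrank_iterate(net, c_vec, d, tol = 1e-12)$score
    expect_lt(max(abs(exact - iter)), 1e-8)
    expect_equal(exact, dense_netrank(net, c_vec, d), tolerance = 1e-10)
  }
})

test_that("d = 1 gives degree-proportional scores on connected graphs", {
  # triangle with a tail: connected, non-bipartite
  net <- as_gene_network(data.frame(
    from = c("A", "B", "C", "C"), to = c("B", "C", "A", "D")
  ))
  c_vec <- c(A = 0.4, B = 0.1, C = 0.3, D = 0.2)
  r <- netrank_solve(net, c_vec, d = 1)
  deg <- as.numeric(net$degree)
  expect_equal(r$score, sum(c_vec) * deg / sum(deg))
  it <- netrank_iterate(net, c_vec, d = 1, tol = 1e-12)
  expect_equal(it$score, r$score, tolerance = 1e-8)

  # two components: each keeps its own seed mass
  net2 <- as_gene_network(data.frame(from = c("A", "X"), to = c("B", "Y")))
  r2 <- netrank_solve(net2, c(A = 0.6, B = 0.2, X = 0.1, Y = 0.1), d = 1)
  expect_equal(sum(r2$score[r2$gene %in% c("A", "B")]), 0.8)
  expect_equal(sum(r2$score[r2$gene %in% c("X", "Y")]), 0.2)
})

test_that("isolated nodes keep (1-d) of their seed and emit nothing", {
  net <- align_universe(path_net(), c("A", "B", "C", "ISO"))
  r <- netrank_solve(net, c(A = 1, B = 0, C = 0, ISO = 0.8), d = 0.5)
  expect_equal(r$score[r$gene == "ISO"], 0.5 * 0.8)
  # path scores unchanged by the isolated node
  expect_equal(r$score[r$gene %in% c("A", "B", "C")], c(7 / 12, 1 / 3, 1 / 12))
})

test_that("scale invariance, mass conservation, monotonicity, relabeling", {
  for (s in 1:30) {
    net <- random_net(sample(6:25, 1), 0.25, seed = s)
    n <- length(net$genes)
    c_vec <- withr::with_seed(s, runif(n))
    d <- withr::with_seed(s + 50, sample(seq(0.1, 0.9, 0.1), 1))
    r <- netrank_solve(net, c_vec, d)$score

    # positive rescaling scales scores, preserves order
    alpha <- withr::with_seed(s, runif(1, 0.1, 10))
    r2 <- netrank_solve(net, alpha * c_vec, d)$score
    expect_equal(r2, alpha * r, tolerance = 1e-9)

    # mass conservation on isolate-free graphs
    if (all(net$degree > 0)) expect_equal(sum(r), sum(c_vec), tolerance = 1e-9)

    # raising one seed raises that node strictly, no node decreases
    i <- withr::with_seed(s + 99, sample(n, 1))
    c_up <- c_vec
    c_up[i] <- c_up[i] + 0.5
    r_up <- netrank_solve(net, c_up, d)$score
    expect_true(all(r_up - r >= -1e-12))
    expect_gt(r_up[i], r[i])

    # permutation equivariance under node relabeling
    relab <- setNames(sprintf("z%03d", seq_len(n)), net$genes)
    edges <- tidy(net)
    net_p <- as_gene_network(data.frame(
      from = unname(relab[edges$from]), to = unname(relab[edges$to])
    ))
    net_p <- align_universe(net_p, unname(relab)) # keep isolated nodes too
    r_p <- netrank_solve(net_p, setNames(c_vec, relab[net$genes]), d)
    expect_equal(
      r_p$score[match(relab[net$genes], r_p$gene)], r,
      tolerance = 1e-9
    )
  }
})

test_that("seed ranking is recovered as d -> 0", {
  net <- random_net(15, 0.25, seed = 7)
  c_vec <- withr::with_seed(70, runif(15))
  base_order <- order(-c_vec, net$genes)
  r <- netrank_solve(net, c_vec, d = 1e-6)$score
  expect_equal(order(-r, net$genes), base_order)
})

test_that("direct-neighbor variant averages neighbor seeds", {
  star <- star_net()
  r <- direct_neighbor_rank(star, c(L1 = 0.2, L2 = 0.4, L3 = 0.6, HUB = 0.9))
  expect_equal(r$score[r$gene == "HUB"], 0.4)
  expect_equal(r$score[r$gene == "L1"], 0.9)

  path <- path_net()
  rp <- direct_neighbor_rank(path, c(A = 1, B = 0, C = 0))
  expect_equal(rp$score, c(0, 0.5, 0))

  # brute-force neighbor-mean loop oracle on random instances
  for (s in 1:20) {
    net <- random_net(sample(5:20, 1), 0.3, seed = s)
    c_vec <- withr::with_seed(s, runif(length(net$genes)))
    got <- direct_neighbor_rank(net, setNames(c_vec, net$genes))$score
    A <- as.matrix(net$adjacency)
    want <- vapply(seq_len(nrow(A)), function(i) {
      nb <- which(A[i, ] != 0)
      if (length(nb) == 0) 0 else mean(c_vec[nb])
    }, numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("constant seeding ranks by topology", {
  net <- star_net()
  cs <- constant_seed(net)
  expect_equal(cs$seed, rep(0.25, 4))
  r <- netrank_solve(net, cs, d = 0.85)
  expect_equal(tidy(r)$gene[1], "HUB")

  # regular graph: all nodes equivalent -> uniform
  ring <- as_gene_network(data.frame(
    from = c("a", "b", "c", "d"), to = c("b", "c", "d", "a")
  ))
  rr <- netrank_solve(ring, constant_seed(ring), d = 0.85)
  expect_equal(rr$score, rep(0.25, 4))
})

test_that("top-k signatures respect eligibility and break ties lexicographically", {
  sc <- tibble::tibble(gene = c("a", "b", "c"), score = c(0.9, 0.5, 0.1))
  expect_equal(top_k_signature(sc, k = 2), c("a", "b"))

  tie <- tibble::tibble(gene = c("b", "a"), score = c(0.5, 0.5))
  expect_equal(top_k_signature(tie, k = 1), "a")

  expect_equal(top_k_signature(sc, measured_genes = c("b", "c"), k = 2), c("b", "c"))
  expect_error(top_k_signature(sc, k = 4), "between 1 and")
})

test_that("rankings expose tidy/glance metadata", {
  net <- path_net()
  r <- netrank_iterate(net, c(A = 1, B = 0, C = 0), d = 0.3)
  td <- tidy(r)
  expect_equal(names(td), c("gene", "seed", "score", "rank"))
  expect_equal(td$rank, 1:3)
  g <- glance(r)
  expect_equal(g$d, 0.3)
  expect_true(g$converged)
  expect_error(netrank_solve(net, c(A = 1, B = 0, C = 0), d = 1.2), "damping")
})
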