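test_that("balanced splits keep test class counts within one of each other", {
  cohort <- make_cohort(c(seq(2, 30, by = 2), seq(31, 59, by = 2))) # 15 poor / 15 good
  sp <- balanced_split(cohort, train_size = 28, seed = 1)
  test_lab <- cohort$prognosis[match(sp$test, cohort$sample)]
  expect_equal(sum(test_lab == "poor"), 1)
  expect_equal(sum(test_lab == "good"), 1)
  expect_length(sp$train, 28)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), cohort$sample)

  # odd test size: counts {2,1} in one of the two orders
  sp3 <- balanced_split(cohort, train_size = 27, seed = 5)
  counts <- sort(as.integer(table(cohort$prognosis[match(sp3$test, cohort$sample)])))
  expect_equal(counts, c(1L, 2L))

  # reproducible bit-exactly from the recorded seed
  for (s in c(2, 77, 1234)) {
    expect_identical(balanced_split(cohort, 20, s), balanced_split(cohort, 20, s))
  }
  expect_error(balanced_split(cohort, 1, 1), "train_size")
  expect_error(balanced_split(cohort, 29, 1), "train_size")
})

test_that("accuracy is the fraction of correct calls", {
  pred <- c(rep("poor", 5), rep("good", 5))
  true <- c(rep("poor", 3), rep("good", 2), rep("good", 4), "poor")
  expect_equal(accuracy(pred, true), 0.7) # TP=3 TN=4 FP=2 FN=1
  expect_equal(accuracy(pred, pred), 1)
  flip <- ifelse(pred == "poor", "good", "poor")
  expect_equal(accuracy(pred, flip), 0)
  expect_error(accuracy(character(0), character(0)), "non-empty")

  perm <- sample(10)
  expect_equal(accuracy(pred[perm], true[perm]), accuracy(pred, true))
})

test_that("the damping grid defaults to the eleven-step ladder and ties go to 0", {
  expect_equal(formals(inner_select_d)$d_grid, quote(seq(0, 1, by = 0.1)))
  expect_length(seq(0, 1, by = 0.1), 11)

  # one informative gene isolated from the network: every d gives the same
  # signature, so the tie resolves to the smallest damping value
  withr::with_seed(3, {
    outcome <- rep(c(0, 1), 6)
    m <- rbind(
      a_sig = 7 + outcome * 2 + rnorm(12, sd = 0.05),
      b_zzz = rnorm(12, 7),
      c_zzz = rnorm(12, 7)
    )
  })
  colnames(m) <- sprintf("s%02d", 1:12)
  cohort <- make_cohort(10 + outcome * 20 + seq(0.1, 1.2, by = 0.1),
    samples = colnames(m)
  )
  net <- as_gene_network(data.frame(from = "x_off1", to = "x_off2"))
  res <- inner_select_d(make_expr(m), cohort, net, k = 1, n_holdouts = 4, seed = 9)
  expect_equal(res$d, 0)
  expect_equal(res$inner$d, seq(0, 1, by = 0.1))
  expect_equal(length(unique(res$inner$mean_accuracy)), 1)
})

test_that("inner cross-validation prefers network propagation on planted modules", {
  # planted hub module: correlations alone are unreliable at n = 30, the
  # network neighborhood carries the signal
  net <- simulate_network(300, "scale-free", seed = 4)
  chosen <- vapply(1:20, function(s) {
    sim <- simulate_cohort(net, seed = 1000 + s)
    mask <- compute_filter_mask(sim$expr)
    inner_select_d(sim$expr, sim$clinical, net,
      k = 7, n_holdouts = 5, seed = s, mask = mask
    )$d
  }, numeric(1))
  expect_gt(mean(chosen > 0), 0.5)
})

test_that("median dichotomization splits marker readouts into low/high", {
  expect_equal(dichotomize_by_median(c(0, 1, 2, 3)), c("low", "low", "high", "high"))
  expect_equal(dichotomize_by_median(c(1, 1, 1, 5)), c("low", "low", "low", "high"))
  expect_equal(
    dichotomize_by_median(c(10, 20, 80, 90)),
    c("low", "low", "high", "high")
  )
  expect_error(dichotomize_by_median(rep(2, 5)), "degenerate")
})

test_that("backward elimination keeps perfect markers and drops a coin flip", {
  # markers identical to the label: no removal strictly improves
  lab <- rep(c("poor", "good"), each = 10)
  x <- cbind(m1 = as.integer(lab == "poor"), m2 = as.integer(lab == "poor"))
  res <- backward_elimination_loocv(x, lab)
  expect_equal(res$markers, c("m1", "m2"))
  expect_equal(res$accuracy, 1)

  # the outcome-independent coin-flip marker is the one the procedure
  # eliminates; informative markers survive
  n <- 40
  removed <- t(vapply(1:30, function(s) {
    withr::with_seed(s, {
      lab2 <- rep(c("poor", "good"), each = n / 2)
      mu <- ifelse(lab2 == "poor", 0.8, -0.8)
      feats <- cbind(
        m1 = mu + rnorm(n), m2 = mu + rnorm(n),
        m3 = rbinom(n, 1, 0.5)
      )
    })
    res2 <- backward_elimination_loocv(feats, lab2)
    c(m1 = !"m1" %in% res2$markers, m2 = !"m2" %in% res2$markers,
      m3 = !"m3" %in% res2$markers)
  }, logical(3)))
  expect_gt(sum(removed[, "m3"]), 2 * sum(removed[, "m1"]))
  expect_gt(sum(removed[, "m3"]), 2 * sum(removed[, "m2"]))
  expect_gt(mean(removed[, "m3"]), 0.3)

  # never empty, never grows
  expect_gte(length(res$markers), 1)
  expect_lte(length(res$markers), 2)
})

test_that("ROC AUC follows the concordant-pairs definition", {
  lab <- c("poor", "poor", "good", "good")
  expect_equal(roc_auc(c(5, 4, 2, 1), lab), 1)
  expect_equal(roc_auc(rep(3, 4), lab), 0.5)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.1), lab), 0.75) # one inversion

  # invariant under strictly monotone transforms
  withr::with_seed(5, {
    sc <- rnorm(30)
    lb <- sample(c("poor", "good"), 30, replace = TRUE, prob = c(0.4, 0.6))
  })
  expect_equal(roc_auc(exp(sc), lb), roc_auc(sc, lb))
  expect_equal(roc_auc(2 * sc + 7, lb), roc_auc(sc, lb))
  expect_error(roc_auc(sc, rep("poor", 30)), "two classes")
})

test_that("a perfectly separable gene drives accuracy to one", {
  withr::with_seed(6, {
    outcome <- rep(c(1, 0), each = 8)
    m <- rbind(
      g_perfect = 8 + 2 * outcome + rnorm(16, sd = 0.05),
      g_null1 = rnorm(16, 8),
      g_null2 = rnorm(16, 8),
      g_null3 = rnorm(16, 8)
    )
    colnames(m) <- sprintf("s%02d", 1:16)
    surv <- ifelse(outcome == 1, runif(16, 2, 15), runif(16, 20, 50))
  })
  cohort <- make_cohort(surv, samples = colnames(m))
  cv <- monte_carlo_cv(make_expr(m), cohort,
    methods = "ttest", k = 1,
    train_sizes = 10, repeats = 15, base_seed = 8
  )
  expect_equal(summary(cv)$mean_accuracy, 1)
})

test_that("reports replay bit-exactly from their recorded splits and seeds", {
  sim <- small_sim(n_genes = 200, seed = 9)
  cv <- monte_carlo_cv(sim$expr, sim$clinical, sim$network,
    methods = c("netrank", "pearson", "random"), k = 5,
    train_sizes = c(12, 20), repeats = 4, base_seed = 77, mask = sim$mask,
    inner_holdouts = 3
  )
  cv2 <- mc_cv_replay(cv, sim$expr, sim$clinical, sim$network, mask = sim$mask)
  # replay must not silently re-draw splits
  expect_identical(cv2$splits$train, cv$splits$train)
  expect_identical(tidy(cv2)$accuracy, tidy(cv)$accuracy)
  expect_identical(tidy(cv2)$chosen_d, tidy(cv)$chosen_d)

  # the same splits are reused across methods within a run
  td <- tidy(cv)
  by_rep <- split(td$seed, paste(td$train_size, td$repeat_id))
  expect_true(all(vapply(by_rep, function(x) length(unique(x)) == 1, logical(1))))
})

test_that("cross-validation reports expose tidy, summary and autoplot", {
  sim <- small_sim(n_genes = 150, seed = 14)
  cv <- monte_carlo_cv(sim$expr, sim$clinical, sim$network,
    methods = c("pearson", "foldchange"), k = 3,
    train_sizes = 16, repeats = 5, base_seed = 2, mask = sim$mask
  )
  td <- tidy(cv)
  expect_named(
    td,
    c("method", "train_size", "k", "repeat_id", "seed", "chosen_d", "accuracy")
  )
  expect_true(all(td$accuracy >= 0 & td$accuracy <= 1))
  sm <- summary(cv)
  expect_equal(nrow(sm), 2)
  expect_equal(sm$sem, with(
    td, tapply(accuracy, method, function(x) sd(x) / sqrt(length(x)))
  )[sm$method], ignore_attr = TRUE)
  p <- ggplot2::autoplot(cv)
  expect_s3_class(p, "ggplot")
})
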