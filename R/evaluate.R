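#' Classification accuracy
#'
#' Fraction of correctly classified samples: (TP + TN) / (TP + FP + TN + FN).
#'
#' @param predicted Predicted labels.
#' @param truth True labels of equal length.
#' @return A number in \[0, 1\].
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) == 0 || length(predicted) != length(truth)) {
    abort("predicted and truth must be non-empty and of equal length")
  }
  mean(as.character(predicted) == as.character(truth))
}

#' Balanced random train/test split
#'
#' Samples the test set without replacement so that its poor/good counts are
#' ceiling(t/2) and floor(t/2) (t = n - train_size); when t is odd the
#' majority side is chosen uniformly at random. The remainder is the
#' training set. Reproducible from `seed`.
#'
#' @param cohort Cohort tibble with columns `sample` and `prognosis`.
#' @param train_size Training set size, between 2 and n - 2.
#' @param seed Integer RNG seed recorded with the split.
#' @return A `split_record`: `list(seed, train, test)` of sample ids.
#' @export
balanced_split <- function(cohort, train_size, seed) {
  n <- nrow(cohort)
  if (train_size < 2 || train_size > n - 2) {
    abort("train_size must be between 2 and n - 2")
  }
  classes <- as.character(cohort$prognosis)
  lev <- sort(unique(classes))
  if (length(lev) != 2) abort("cohort must have exactly two prognosis classes")
  t_size <- n - train_size
  withr::with_seed(seed, {
    hi <- ceiling(t_size / 2)
    lo <- floor(t_size / 2)
    counts <- c(hi, lo)
    if (hi != lo && runif(1) < 0.5) counts <- c(lo, hi)
    ids1 <- cohort$sample[classes == lev[1]]
    ids2 <- cohort$sample[classes == lev[2]]
    if (length(ids1) < counts[1] || length(ids2) < counts[2]) {
      abort("a prognosis class is too small to balance the test set")
    }
    test <- c(
      sample(ids1, counts[1]),
      sample(ids2, counts[2])
    )
    structure(
      list(seed = seed, train = setdiff(cohort$sample, test), test = test),
      class = "split_record"
    )
  })
}

# stratified holdout indices of size h within labels; each class keeps at
# least one sample on both sides
stratified_holdout <- function(labels, h) {
  lev <- sort(unique(labels))
  n <- length(labels)
  per <- pmax(1, round(h * table(factor(labels, levels = lev)) / n))
  per <- pmin(per, table(factor(labels, levels = lev)) - 1)
  while (sum(per) > h) per[which.max(per)] <- per[which.max(per)] - 1
  while (sum(per) < h) {
    room <- which(per < table(factor(labels, levels = lev)) - 1)
    if (length(room) == 0) break
    j <- room[which.max(table(factor(labels, levels = lev))[room] - per[room])]
    per[j] <- per[j] + 1
  }
  unlist(lapply(seq_along(lev), function(j) {
    idx <- which(labels == lev[j])
    idx[sample.int(length(idx), per[j])]
  }), use.names = FALSE)
}

# internal seeding over the aligned universe from a training expression
# matrix (rows already restricted to filter-passing genes)
seed_from_matrix <- function(m, survival, universe_genes, method) {
  r <- abs_cor_with(m, survival, method)
  v <- setNames(numeric(length(universe_genes)), universe_genes)
  hit <- intersect(names(r), universe_genes)
  v[hit] <- r[hit]
  v
}

# internal engine behind inner_select_d(); works on matrices and reuses
# pre-factorized solvers
inner_select_d_impl <- function(m_sel, survival, labels, universe,
                                eligible, k, d_grid, n_holdouts, seed,
                                classifier, solvers, seed_method, variant) {
  n <- length(labels)
  if (n < 6) abort("training set too small for an inner holdout (need >= 6)")
  h <- ceiling(n / 3)
  uni_genes <- universe$genes
  const_vec <- setNames(rep(1 / length(uni_genes), length(uni_genes)), uni_genes)
  acc <- matrix(NA_real_, nrow = n_holdouts, ncol = length(d_grid))
  withr::with_seed(seed, {
    for (s in seq_len(n_holdouts)) {
      hold <- stratified_holdout(labels, h)
      rem <- setdiff(seq_len(n), hold)
      seed_vec <- if (variant == "topology") {
        const_vec
      } else {
        seed_from_matrix(m_sel[, rem, drop = FALSE], survival[rem], uni_genes, seed_method)
      }
      for (di in seq_along(d_grid)) {
        scores <- solvers[[di]](seed_vec)
        sig <- top_k_from_scores(uni_genes, scores, eligible, k)
        model <- classifier$train(
          Matrix::t(m_sel[sig, rem, drop = FALSE]), labels[rem]
        )
        pred <- classifier$predict(model, Matrix::t(m_sel[sig, hold, drop = FALSE]))
        acc[s, di] <- accuracy(pred, labels[hold])
      }
    }
  })
  means <- colMeans(acc)
  list(
    d = d_grid[which.max(means)], # grid ascending: first max = smallest d
    inner = tibble(d = d_grid, mean_accuracy = means)
  )
}

solver_for <- function(solvers, d) {
  i <- which(abs(attr(solvers, "grid") - d) < 1e-12)[1]
  if (is.na(i)) abort("no solver factorized for this damping value")
  solvers[[i]]
}

top_k_from_scores <- function(genes, scores, eligible, k) {
  keep <- which(genes %in% eligible)
  if (k > length(keep)) abort("k exceeds the number of eligible genes")
  ord <- keep[order(-scores[keep], genes[keep])]
  genes[ord][seq_len(k)]
}

#' Select the damping factor by inner cross-validation
#'
#' Nested model selection for the network ranking: inside a training set,
#' repeated stratified holdouts (size ceiling(n/3)) are set aside, NetRank is
#' seeded on the remaining samples, run at every damping value of `d_grid`
#' (default 0 to 1 in steps of 0.1), and the holdout accuracy of the top-k
#' signature's classifier is recorded. The d with the best mean holdout
#' accuracy wins; ties go to the smallest d. No test-set information is
#' involved.
#'
#' @param expr Gene-level expression tibble restricted to training samples.
#' @param cohort Cohort tibble (`sample`, `survival_months`, `prognosis`)
#'   for the same samples.
#' @param network A `gene_network`.
#' @param k Signature size.
#' @param d_grid Candidate damping values, ascending.
#' @param n_holdouts Number of stratified inner holdouts.
#' @param seed RNG seed for the holdouts.
#' @param mask Optional filter mask; restricts seeding and signature
#'   eligibility to selected genes.
#' @param classifier Classifier contract, see [svm_classifier()].
#' @param method Correlation flavor for the seeds.
#' @return `list(d, inner)` where `inner` is a tibble of per-d mean inner
#'   accuracies.
#' @export
inner_select_d <- function(expr, cohort, network, k = 7,
                           d_grid = seq(0, 1, by = 0.1), n_holdouts = 10,
                           seed = 1, mask = NULL,
                           classifier = svm_classifier(),
                           method = c("pearson", "spearman")) {
  method <- match.arg(method)
  prep <- prepare_cv_data(expr, cohort, network, mask)
  solvers <- lapply(d_grid, function(d) netrank_solver(prep$universe, d))
  inner_select_d_impl(
    prep$m_sel, prep$survival, prep$labels, prep$universe, prep$eligible,
    k, d_grid, n_holdouts, seed, classifier, solvers, method, "netrank"
  )
}

# shared alignment/validation for the evaluation engine
prepare_cv_data <- function(expr, cohort, network, mask) {
  samples <- expr_samples(expr)
  if (!setequal(samples, cohort$sample) || anyDuplicated(cohort$sample)) {
    abort("expression samples and cohort samples must match one-to-one")
  }
  cohort <- cohort[match(samples, cohort$sample), , drop = FALSE]
  if (!"prognosis" %in% names(cohort)) {
    cohort$prognosis <- median_split(cohort$survival_months)
  }
  m <- expr_values(expr)
  eligible <- rownames(m)
  if (!is.null(mask)) {
    eligible <- intersect(eligible, mask$gene[mask$selected])
  }
  universe <- NULL
  if (!is.null(network)) {
    universe <- align_universe(network, rownames(m))
  }
  list(
    cohort = cohort,
    m = m,
    m_sel = m[eligible, , drop = FALSE],
    eligible = eligible,
    survival = cohort$survival_months,
    labels = as.character(cohort$prognosis),
    universe = universe
  )
}

cv_methods <- c(
  "netrank", "topology", "neighbor", "pearson", "spearman",
  "foldchange", "ttest", "sam", "random"
)

#' Monte Carlo cross-validation of gene-signature rankers
#'
#' The complete signature benchmark: for each repeat, the cohort is split
#' into a balanced training and test set, genes are ranked on the training
#' samples only by each requested method, the top-k genes become the
#' signature, a classifier is trained on the training expression of the
#' signature and its accuracy measured on the held-out test samples. The
#' exact same splits are used for every method, and every split's seed is
#' recorded so a report can be replayed bit-exactly. For the network-based
#' methods the damping factor is chosen per repeat by an inner
#' cross-validation on the training set (unless a fixed `d` is supplied).
#' Prognosis labels are fixed once on the full cohort before any splitting.
#'
#' @param expr Gene-level expression tibble (first column `gene`).
#' @param cohort Cohort tibble (`sample`, `survival_months`, optionally
#'   `prognosis`; if absent it is added by [median_split()]).
#' @param network A `gene_network`; required for methods `"netrank"`,
#'   `"topology"` and `"neighbor"`.
#' @param methods Subset of `"netrank"` (correlation seeds + propagation),
#'   `"topology"` (constant seeds + propagation), `"neighbor"`
#'   (direct-neighbor mean), `"pearson"`, `"spearman"`, `"foldchange"`,
#'   `"ttest"`, `"sam"`, `"random"`.
#' @param k Signature size (default 7).
#' @param train_sizes Integer vector of training set sizes.
#' @param repeats Number of Monte Carlo repeats per training size.
#' @param base_seed Master seed; every repeat's seed derives from it and is
#'   recorded in the report.
#' @param d Fixed damping factor, or `"auto"` for inner-CV selection.
#' @param d_grid Damping grid for `"auto"`.
#' @param inner_holdouts Inner holdout count for `"auto"`.
#' @param mask Optional filter mask restricting seeding/eligibility.
#' @param classifier Classifier contract, see [svm_classifier()].
#' @param seed_method Correlation flavor for NetRank seeds.
#' @param sam_s0 Fudge constant for the SAM score.
#' @param split_records Optional splits tibble from a previous `mc_cv`
#'   object; when supplied the recorded splits and seeds are replayed
#'   instead of drawing new ones.
#' @return An `mc_cv` object: `results` (one row per method, train size and
#'   repeat with the recorded seed, chosen d and accuracy) and `splits`.
#'   [tidy()] returns the per-repeat results, [summary()]/[glance()] the
#'   mean accuracy and standard error per method and train size,
#'   [ggplot2::autoplot()] the accuracy curves.
#' @export
monte_carlo_cv <- function(expr, cohort, network = NULL,
                           methods = "netrank", k = 7,
                           train_sizes, repeats = 1000, base_seed = 1,
                           d = "auto", d_grid = seq(0, 1, by = 0.1),
                           inner_holdouts = 10,
                           mask = NULL, classifier = svm_classifier(),
                           seed_method = c("pearson", "spearman"),
                           sam_s0 = "auto", split_records = NULL) {
  seed_method <- match.arg(seed_method)
  methods <- match.arg(methods, cv_methods, several.ok = TRUE)
  network_methods <- intersect(methods, c("netrank", "topology", "neighbor"))
  if (length(network_methods) > 0 && is.null(network)) {
    abort("a gene network is required for the network-based methods")
  }
  prep <- prepare_cv_data(expr, cohort, network, mask)
  if (k > length(prep$eligible)) abort("k exceeds the number of eligible genes")

  solvers <- NULL
  const_vec <- NULL
  if (length(network_methods) > 0) {
    uni_genes <- prep$universe$genes
    const_vec <- setNames(rep(1 / length(uni_genes), length(uni_genes)), uni_genes)
    if (any(methods %in% c("netrank", "topology"))) {
      grid <- if (identical(d, "auto")) d_grid else unique(c(d_grid, d))
      solvers <- lapply(grid, function(dd) netrank_solver(prep$universe, dd))
      attr(solvers, "grid") <- grid
    }
  }

  if (is.null(split_records)) {
    plan <- tidyr::expand_grid(train_size = train_sizes, repeat_id = seq_len(repeats))
    plan$seed <- withr::with_seed(
      base_seed, sample.int(2147483646L, nrow(plan))
    )
    plan$train <- vector("list", nrow(plan))
    plan$test <- vector("list", nrow(plan))
    fresh <- TRUE
  } else {
    plan <- split_records
    fresh <- FALSE
  }

  results <- vector("list", nrow(plan) * length(methods))
  out_i <- 0L
  for (row in seq_len(nrow(plan))) {
    size <- plan$train_size[row]
    rep_seed <- plan$seed[row]
    sub <- withr::with_seed(rep_seed, sample.int(2147483646L, 4))
    if (fresh) {
      split <- balanced_split(prep$cohort, size, sub[1])
      plan$train[[row]] <- split$train
      plan$test[[row]] <- split$test
    }
    train_ids <- plan$train[[row]]
    test_ids <- plan$test[[row]]
    tr <- match(train_ids, prep$cohort$sample)
    te <- match(test_ids, prep$cohort$sample)
    for (method in methods) {
      res <- evaluate_one_method(
        method, prep, tr, te, k, d, d_grid, inner_holdouts,
        classifier, seed_method, sam_s0, solvers, const_vec,
        inner_seed = sub[2], random_seed = sub[3]
      )
      out_i <- out_i + 1L
      results[[out_i]] <- tibble(
        method = method, train_size = size, k = k,
        repeat_id = plan$repeat_id[row], seed = rep_seed,
        chosen_d = res$chosen_d, accuracy = res$accuracy
      )
    }
  }
  structure(
    list(
      results = bind_rows(results),
      splits = plan,
      methods = methods, k = k, train_sizes = train_sizes,
      repeats = repeats, base_seed = base_seed, d = d,
      d_grid = d_grid, inner_holdouts = inner_holdouts,
      seed_method = seed_method, sam_s0 = sam_s0
    ),
    class = "mc_cv"
  )
}

evaluate_one_method <- function(method, prep, tr, te, k, d, d_grid,
                                inner_holdouts, classifier, seed_method,
                                sam_s0, solvers, const_vec,
                                inner_seed, random_seed) {
  m_sel <- prep$m_sel
  labels <- prep$labels
  survival <- prep$survival
  eligible <- prep$eligible
  chosen_d <- NA_real_
  sig <- switch(method,
    netrank = ,
    topology = {
      d_use <- if (identical(d, "auto")) {
        inner_select_d_impl(
          m_sel[, tr, drop = FALSE], survival[tr], labels[tr],
          prep$universe, eligible, k, d_grid, inner_holdouts, inner_seed,
          classifier, solvers, seed_method, method
        )$d
      } else {
        d
      }
      chosen_d <- d_use
      seed_vec <- if (method == "topology") {
        const_vec
      } else {
        seed_from_matrix(
          m_sel[, tr, drop = FALSE], survival[tr], prep$universe$genes, seed_method
        )
      }
      scores <- solver_for(solvers, d_use)(seed_vec)
      top_k_from_scores(prep$universe$genes, scores, eligible, k)
    },
    neighbor = {
      seed_vec <- seed_from_matrix(
        m_sel[, tr, drop = FALSE], survival[tr], prep$universe$genes, seed_method
      )
      sums <- as.numeric(prep$universe$adjacency %*% seed_vec)
      scores <- ifelse(prep$universe$degree > 0, sums / prep$universe$degree, 0)
      top_k_from_scores(prep$universe$genes, scores, eligible, k)
    },
    pearson = ,
    spearman = {
      r <- abs_cor_with(m_sel[, tr, drop = FALSE], survival[tr], method)
      top_k_from_scores(names(r), r, eligible, k)
    },
    foldchange = ,
    ttest = ,
    sam = {
      sub_expr <- matrix_to_expr(m_sel[, tr, drop = FALSE])
      sc <- switch(method,
        foldchange = fold_change_score(sub_expr, labels[tr]),
        ttest = t_score(sub_expr, labels[tr]),
        sam = sam_score(sub_expr, labels[tr], s0 = sam_s0)
      )
      top_k_from_scores(sc$gene, sc$score, eligible, k)
    },
    random = {
      sc <- random_score(eligible, random_seed)
      top_k_from_scores(sc$gene, sc$score, eligible, k)
    }
  )
  model <- classifier$train(Matrix::t(m_sel[sig, tr, drop = FALSE]), labels[tr])
  pred <- classifier$predict(model, Matrix::t(m_sel[sig, te, drop = FALSE]))
  list(chosen_d = chosen_d, accuracy = accuracy(pred, labels[te]))
}

matrix_to_expr <- function(m) {
  out <- as_tibble(as.data.frame(m), .name_repair = "minimal")
  dplyr::bind_cols(tibble(gene = rownames(m)), out)
}

#' @export
print.mc_cv <- function(x, ...) {
  cat(sprintf(
    "<mc_cv> %d repeats x %d train sizes, methods: %s, k = %d\n",
    x$repeats, length(x$train_sizes), paste(x$methods, collapse = ", "), x$k
  ))
  print(summary(x))
  invisible(x)
}

#' @describeIn monte_carlo_cv Per-repeat accuracies as a tibble.
#' @param x An `mc_cv` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mc_cv <- function(x, ...) {
  x$results
}

#' @describeIn monte_carlo_cv Mean accuracy and standard error of the mean
#'   per method and training size.
#' @param object An `mc_cv` object.
#' @export
summary.mc_cv <- function(object, ...) {
  object$results |>
    group_by(.data$method, .data$train_size, .data$k) |>
    summarise(
      repeats = dplyr::n(),
      mean_accuracy = mean(.data$accuracy),
      sem = sd(.data$accuracy) / sqrt(dplyr::n()),
      mean_chosen_d = mean(.data$chosen_d, na.rm = TRUE),
      .groups = "drop"
    )
}

#' @describeIn monte_carlo_cv Alias of [summary.mc_cv()].
#' @exportS3Method generics::glance
glance.mc_cv <- function(x, ...) {
  summary(x)
}

#' @describeIn monte_carlo_cv Accuracy curves (mean over repeats, one
#'   standard error of the mean as error bars) against training set size.
#' @exportS3Method ggplot2::autoplot
autoplot.mc_cv <- function(object, ...) {
  df <- summary(object)
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$train_size, y = .data$mean_accuracy,
      colour = .data$method, group = .data$method
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(
      ggplot2::aes(
        ymin = .data$mean_accuracy - .data$sem,
        ymax = .data$mean_accuracy + .data$sem
      )
    ) +
    ggplot2::labs(
      x = "training set size", y = "mean accuracy",
      title = sprintf("Monte Carlo cross-validation (k = %d)", object$k)
    ) +
    ggplot2::theme_minimal()
}

#' Replay a Monte Carlo cross-validation report
#'
#' Re-runs [monte_carlo_cv()] from the recorded splits and seeds of a
#' previous report; the reproduced accuracies are bit-identical to the
#' original.
#'
#' @param fit An `mc_cv` object.
#' @param expr,cohort,network,mask,classifier The inputs of the original run.
#' @return A new `mc_cv` object.
#' @export
mc_cv_replay <- function(fit, expr, cohort, network = NULL, mask = NULL,
                         classifier = svm_classifier()) {
  monte_carlo_cv(
    expr, cohort, network,
    methods = fit$methods, k = fit$k, train_sizes = fit$train_sizes,
    repeats = fit$repeats, base_seed = fit$base_seed, d = fit$d,
    d_grid = fit$d_grid, inner_holdouts = fit$inner_holdouts,
    seed_method = fit$seed_method, sam_s0 = fit$sam_s0,
    mask = mask, classifier = classifier, split_records = fit$splits
  )
}
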