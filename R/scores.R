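# group bookkeeping shared by the two-class scores
split_groups <- function(expr, classes, min_per_class = 1) {
  m <- expr_values(expr)
  classes <- as.character(classes)
  if (length(classes) != ncol(m)) {
    abort("classes must align with the expression samples")
  }
  lev <- sort(unique(classes))
  if (length(lev) != 2) {
    abort("need exactly two non-empty classes")
  }
  idx1 <- which(classes == lev[1])
  idx2 <- which(classes == lev[2])
  if (length(idx1) < min_per_class || length(idx2) < min_per_class) {
    abort(sprintf("each class needs at least %d samples", min_per_class))
  }
  list(m = m, idx1 = idx1, idx2 = idx2)
}

score_tibble <- function(genes, score, method) {
  tibble(gene = genes, score = unname(score), method = method)
}

#' Fold-change gene score
#'
#' Absolute difference of class means on the log2 scale, i.e. the absolute
#' log2 of the expression ratio between the two prognosis groups.
#'
#' @param expr Gene-level expression tibble (log2 scale), training samples.
#' @param classes Two-level class labels (e.g. `"poor"`/`"good"`) aligned
#'   with the sample columns.
#' @return A tibble with columns `gene`, `score`, `method`.
#' @export
fold_change_score <- function(expr, classes) {
  g <- split_groups(expr, classes)
  s <- abs(rowMeans(g$m[, g$idx1, drop = FALSE]) - rowMeans(g$m[, g$idx2, drop = FALSE]))
  score_tibble(rownames(g$m), s, "foldchange")
}

#' Student's t gene score
#'
#' Absolute pooled-variance two-sample t statistic per gene; genes with zero
#' pooled variance score 0.
#'
#' @inheritParams fold_change_score
#' @return A tibble with columns `gene`, `score`, `method`.
#' @export
t_score <- function(expr, classes) {
  g <- split_groups(expr, classes, min_per_class = 2)
  st <- pooled_stats(g)
  t <- ifelse(st$se > 0, abs(st$diff) / st$se, 0)
  score_tibble(rownames(g$m), t, "ttest")
}

# per-gene mean difference and pooled standard error
pooled_stats <- function(g) {
  x1 <- g$m[, g$idx1, drop = FALSE]
  x2 <- g$m[, g$idx2, drop = FALSE]
  n1 <- ncol(x1)
  n2 <- ncol(x2)
  v1 <- apply(x1, 1, stats::var)
  v2 <- apply(x2, 1, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  list(
    diff = rowMeans(x1) - rowMeans(x2),
    se = sqrt(sp2 * (1 / n1 + 1 / n2))
  )
}

#' SAM-style moderated gene score
#'
#' The significance-analysis-of-microarrays ranking statistic: absolute
#' difference of class means divided by the gene-wise pooled standard error
#' plus a regularizing constant s0. With `s0 = "auto"` the median of the
#' gene-wise standard errors is used, a deterministic simplification of the
#' original percentile search; an explicit nonnegative s0 may be supplied.
#'
#' @inheritParams fold_change_score
#' @param s0 `"auto"` or a nonnegative fudge constant.
#' @return A tibble with columns `gene`, `score`, `method`.
#' @export
sam_score <- function(expr, classes, s0 = "auto") {
  g <- split_groups(expr, classes, min_per_class = 2)
  st <- pooled_stats(g)
  if (identical(s0, "auto")) {
    s0 <- median(st$se)
  }
  if (!is.numeric(s0) || s0 < 0) {
    abort("s0 must be \"auto\" or a nonnegative number")
  }
  denom <- st$se + s0
  s <- ifelse(denom > 0, abs(st$diff) / denom, 0)
  score_tibble(rownames(g$m), s, "sam")
}

#' Correlation gene score
#'
#' Absolute Pearson or Spearman correlation of each gene's expression with
#' survival time; zero-variance genes score 0.
#'
#' @param expr Gene-level expression tibble, training samples.
#' @param survival_months Survival times aligned with the sample columns.
#' @param method `"pearson"` or `"spearman"`.
#' @return A tibble with columns `gene`, `score`, `method`.
#' @export
correlation_score <- function(expr, survival_months,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- expr_values(expr)
  if (length(survival_months) != ncol(m)) {
    abort("survival_months must align with the expression samples")
  }
  if (ncol(m) < 3) {
    abort("need at least 3 samples to correlate expression with survival")
  }
  r <- abs_cor_with(m, survival_months, method)
  score_tibble(rownames(m), r, method)
}

#' Random gene score (control)
#'
#' Scores genes by a uniformly random permutation, the negative-control
#' ranking. Reproducible from `seed`.
#'
#' @param genes Character vector of gene ids.
#' @param seed Integer RNG seed.
#' @return A tibble with columns `gene`, `score`, `method`; scores are the
#'   permutation ranks (higher = earlier pick).
#' @export
random_score <- function(genes, seed) {
  genes <- as.character(genes)
  n <- length(genes)
  perm <- withr::with_seed(seed, sample.int(n))
  score_tibble(genes, as.numeric(perm), "random")
}
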