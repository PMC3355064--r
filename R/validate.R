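#' Dichotomize a semi-quantitative marker at the cohort median
#'
#' Converts an immunohistochemistry readout (staining grade or percentage of
#' stained nuclei) into two levels using the cohort median as cut-off:
#' values less than or equal to the median are `"low"`, the rest `"high"`.
#'
#' @param values Numeric marker readouts (at least 2).
#' @return Character vector of `"low"` / `"high"`.
#' @export
dichotomize_by_median <- function(values) {
  if (length(values) < 2) abort("need at least 2 values")
  if (length(unique(values)) == 1) {
    abort("degenerate marker: all values identical")
  }
  ifelse(values <= median(values), "low", "high")
}

#' Leave-one-out cross-validation accuracy
#'
#' @param features Samples-by-features numeric matrix or data frame.
#' @param labels Class labels per sample.
#' @param classifier Classifier contract, see [svm_classifier()].
#' @return Accuracy of the leave-one-out predictions.
#' @export
loocv_accuracy <- function(features, labels, classifier = svm_classifier()) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (n < 4) abort("need at least 4 samples for leave-one-out")
  pred <- character(n)
  for (i in seq_len(n)) {
    model <- classifier$train(x[-i, , drop = FALSE], labels[-i])
    pred[i] <- classifier$predict(model, x[i, , drop = FALSE])
  }
  accuracy(pred, labels)
}

#' Backward elimination of markers under leave-one-out cross-validation
#'
#' Greedy marker-signature search: starting from the full marker set, the
#' leave-one-out accuracy of every single-marker removal is evaluated and
#' the removal with the greatest strict improvement is applied, until no
#' removal strictly improves the accuracy. Ties among equally good removals
#' drop the lexicographically first marker. The result is never empty and
#' never larger than the input set.
#'
#' @param features Samples-by-markers matrix or data frame (binary or
#'   numeric encodings, e.g. from [dichotomize_by_median()]); column names
#'   identify the markers.
#' @param labels Class labels per sample.
#' @param classifier Classifier contract, see [svm_classifier()].
#' @return A list with `markers` (surviving marker names), `accuracy` (their
#'   leave-one-out accuracy) and `path` (a tibble tracing each removal).
#' @export
backward_elimination_loocv <- function(features, labels,
                                       classifier = svm_classifier()) {
  x <- as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("m", seq_len(ncol(x)))
  if (ncol(x) < 2) abort("need at least 2 markers")
  current <- sort(colnames(x))
  acc <- loocv_accuracy(x[, current, drop = FALSE], labels, classifier)
  path <- list(tibble(step = 0L, removed = NA_character_, accuracy = acc))
  step <- 0L
  while (length(current) > 1) {
    cand <- vapply(current, function(drop_m) {
      loocv_accuracy(
        x[, setdiff(current, drop_m), drop = FALSE], labels, classifier
      )
    }, numeric(1))
    best <- max(cand)
    if (best <= acc) break
    drop_m <- sort(names(cand)[cand == best])[1]
    current <- setdiff(current, drop_m)
    acc <- best
    step <- step + 1L
    path <- c(path, list(tibble(step = step, removed = drop_m, accuracy = acc)))
  }
  list(markers = current, accuracy = acc, path = bind_rows(path))
}

#' Area under the ROC curve
#'
#' Rank-sum (concordant-pairs) AUC: the probability that a random positive
#' sample scores above a random negative one, ties counting one half.
#'
#' @param scores Numeric decision values or scores.
#' @param labels Two-level labels.
#' @param positive The label treated as positive; defaults to `"poor"` when
#'   present, otherwise the lexicographically larger level.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2) abort("labels must contain exactly two classes")
  if (is.null(positive)) {
    positive <- if ("poor" %in% lev) "poor" else lev[2]
  }
  pos <- labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  r <- rank(scores) # midranks handle ties as 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
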