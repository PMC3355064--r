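#' Support vector machine classifier contract
#'
#' The evaluation engine is classifier-agnostic: any list with a
#' `train(x, y)` function returning a model and a `predict(model, x)`
#' function returning labels can be plugged in. The default is a
#' radial-basis support vector machine (cost 1, kernel width 1/#features)
#' with features standardized on the training set only; the standardization
#' parameters travel with the model and are applied to test samples.
#' Training sets containing a single class yield a constant-majority
#' predictor so degenerate resamples stay well-defined.
#'
#' @param cost SVM cost parameter.
#' @param gamma Kernel width; `NULL` means 1/#features.
#' @return A classifier contract: `list(train = function(x, y), predict =
#'   function(model, x))` where `x` is a samples-by-features numeric matrix
#'   and `y` a label vector.
#' @export
svm_classifier <- function(cost = 1, gamma = NULL) {
  list(
    train = function(x, y) {
      x <- as.matrix(x)
      y <- as.character(y)
      lev <- sort(unique(y))
      if (length(lev) < 2) {
        return(structure(list(constant = lev[1]), class = "netrank_constant_clf"))
      }
      center <- colMeans(x)
      scale <- apply(x, 2, sd)
      scale[scale == 0 | !is.finite(scale)] <- 1
      xs <- sweep(sweep(x, 2, center), 2, scale, "/")
      g <- if (is.null(gamma)) 1 / ncol(x) else gamma
      fit <- e1071::svm(
        x = xs, y = factor(y, levels = lev),
        kernel = "radial", cost = cost, gamma = g, scale = FALSE
      )
      structure(
        list(fit = fit, center = center, scale = scale),
        class = "netrank_svm_clf"
      )
    },
    predict = function(model, x) {
      x <- as.matrix(x)
      if (inherits(model, "netrank_constant_clf")) {
        return(rep(model$constant, nrow(x)))
      }
      xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
      as.character(predict(model$fit, xs))
    }
  )
}
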