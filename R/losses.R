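# The composite training objective: binary cross-entropy over all rows plus
# a weighted penalty on prediction error over the truly positive slice.
# Natural logarithms throughout (a base change only rescales the losses).

#' Loss configuration
#'
#' @param lambda non-negative weight of the weighted-positive term. The
#'   total loss is `bce + lambda * wp`.
#' @param epsilon probabilities are clipped to `[epsilon, 1 - epsilon]`
#'   before any logarithm; cross-entropy is undefined at exactly 0 or 1.
#' @param globalPositiveCount optional: normalize the weighted-positive term
#'   by this global truly-positive count instead of the batch-local count
#'   (the default, which mini-batch training needs).
#' @return Named list of validated settings.
#' @export
lossConfig <- function(lambda = 1, epsilon = 1e-7,
                       globalPositiveCount = NULL) {
  assertNumber(lambda, "lambda", 0)
  if (!is.numeric(epsilon) || epsilon <= 0 || epsilon >= 0.5)
    parameterError("epsilon must lie in (0, 0.5)")
  if (!is.null(globalPositiveCount)) assertCount(globalPositiveCount,
                                                 "globalPositiveCount")
  list(lambda = lambda, epsilon = epsilon,
       globalPositiveCount = globalPositiveCount)
}

.checkLossInputs <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred))
    parameterError("labels (%d) and predictions (%d) differ in length",
                   length(yTrue), length(yPred))
  if (length(yTrue) < 1L) parameterError("need at least one sample")
  if (any(is.na(yTrue)) || !all(yTrue %in% c(0, 1)))
    parameterError("labels must be 0 or 1")
  if (any(is.na(yPred)) || any(yPred < 0) || any(yPred > 1))
    parameterError("predictions must lie in [0, 1]")
}

#' Binary cross-entropy
#'
#' Mean of `-[y * ln(p) + (1 - y) * ln(1 - p)]` with predictions clipped to
#' `[epsilon, 1 - epsilon]`. Optional per-row weights multiply each row's
#' contribution while keeping the `1/N` normalizer, so a weight `w` scales
#' that row's contribution exactly `w`-fold.
#'
#' @param yTrue 0/1 labels.
#' @param yPred probabilities in `[0, 1]`.
#' @param epsilon clipping constant.
#' @param weights optional non-negative per-row weights.
#' @return Non-negative scalar.
#' @examples
#' bceLoss(1, 0.5)       # ln 2
#' bceLoss(c(1, 0), c(0.9, 0.2))
#' @export
bceLoss <- function(yTrue, yPred, epsilon = 1e-7, weights = NULL) {
  .checkLossInputs(yTrue, yPred)
  p <- pmin(pmax(yPred, epsilon), 1 - epsilon)
  terms <- -(yTrue * log(p) + (1 - yTrue) * log(1 - p))
  if (!is.null(weights)) {
    if (length(weights) != length(yTrue))
      parameterError("weights must match the number of samples")
    terms <- weights * terms
  }
  sum(terms) / length(yTrue)
}

#' Weighted-positive loss over the truly positive slice
#'
#' Mean over the truly positive samples of
#' `(ln(p + 1) - ln(y + 1))^2`; with `y = 1` this penalizes the squared
#' log-distance of the prediction from 1 and is zero only when every truly
#' positive prediction equals 1. Pseudo-positive rows must never enter this
#' term -- any label other than 1 in the slice is a contract error.
#'
#' @param yTruePos labels of the truly positive slice (all 1).
#' @param yPredPos predicted probabilities for that slice.
#' @return Non-negative scalar; 0 (with a warning) for an empty slice.
#' @examples
#' weightedPositiveLoss(1, 0)   # (ln 2)^2
#' weightedPositiveLoss(1, 1)   # 0
#' @export
weightedPositiveLoss <- function(yTruePos, yPredPos) {
  if (length(yTruePos) != length(yPredPos))
    parameterError("labels and predictions differ in length")
  if (length(yTruePos) == 0L) {
    warning("empty truly-positive slice; weighted-positive loss is 0",
            call. = FALSE)
    return(0)
  }
  if (!all(yTruePos == 1))
    contractError("the truly-positive slice must contain only label-1 rows")
  if (any(is.na(yPredPos)) || any(yPredPos < 0) || any(yPredPos > 1))
    parameterError("predictions must lie in [0, 1]")
  mean((log(yPredPos + 1) - log(yTruePos + 1))^2)
}

#' Composite loss: cross-entropy plus the weighted-positive term
#'
#' Binary cross-entropy runs over all `N` rows of the batch (truly positive,
#' pseudo-positive and pseudo-negative alike); the weighted-positive term
#' runs only over the rows flagged truly positive, and the total is
#' `bce + lambda * wp`.
#'
#' @param yTrue 0/1 labels for the batch.
#' @param yPred predicted probabilities.
#' @param truePosMask logical mask of the truly positive rows.
#' @param config A [lossConfig()] list.
#' @param weights optional per-row BCE weights.
#' @return List with `total`, `bce`, `weightedPositive`, `lambda`, `n`,
#'   `nTruePositive`.
#' @export
compositeLoss <- function(yTrue, yPred, truePosMask, config = lossConfig(),
                          weights = NULL) {
  .checkLossInputs(yTrue, yPred)
  if (length(truePosMask) != length(yTrue))
    parameterError("truePosMask must match the number of samples")
  if (any(truePosMask & yTrue != 1))
    contractError("truly-positive rows must carry label 1")
  bce <- bceLoss(yTrue, yPred, config$epsilon, weights)
  wp <- if (any(truePosMask)) {
    slice <- mean((log(yPred[truePosMask] + 1) - log(2))^2)
    if (!is.null(config$globalPositiveCount))
      slice * sum(truePosMask) / config$globalPositiveCount
    else slice
  } else 0
  list(total = bce + config$lambda * wp, bce = bce, weightedPositive = wp,
       lambda = config$lambda, n = length(yTrue),
       nTruePositive = sum(truePosMask))
}

#' Analytic gradient of the composite loss
#'
#' Per-row derivative of the composite loss with respect to the predicted
#' probability, evaluated at predictions clipped to
#' `[epsilon, 1 - epsilon]`. For a truly positive row the weighted-positive
#' term contributes `lambda * 2 (ln(p + 1) - ln 2) / ((p + 1) * nPos)` on
#' top of the cross-entropy derivative, where `nPos` is the (batch-local)
#' truly-positive count.
#'
#' @inheritParams compositeLoss
#' @return Numeric vector of per-row derivatives.
#' @export
lossGradient <- function(yTrue, yPred, truePosMask, config = lossConfig(),
                         weights = NULL) {
  .checkLossInputs(yTrue, yPred)
  if (length(truePosMask) != length(yTrue))
    parameterError("truePosMask must match the number of samples")
  n <- length(yTrue)
  p <- pmin(pmax(yPred, config$epsilon), 1 - config$epsilon)
  g <- -(yTrue / p - (1 - yTrue) / (1 - p)) / n
  if (!is.null(weights)) g <- g * weights
  nPos <- if (!is.null(config$globalPositiveCount))
    config$globalPositiveCount else sum(truePosMask)
  if (nPos > 0L && any(truePosMask)) {
    pp <- p[truePosMask]
    g[truePosMask] <- g[truePosMask] +
      config$lambda * 2 * (log(pp + 1) - log(2)) / ((pp + 1) * nPos)
  }
  g
}
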