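# F1 and companion metrics, discriminant-threshold search, lambda selection,
# the positive-upweighting baseline, and the 60/20/20 aggregation split.

#' F1 score with confusion counts
#'
#' Standard confusion-matrix F1. Zero-division convention: precision,
#' recall and F1 are 0 when their denominator is 0.
#'
#' @param yTrue 0/1 true labels.
#' @param yPred 0/1 predicted labels.
#' @param threshold optional score threshold to record in the report.
#' @return List with `f1`, `precision`, `recall`, `threshold`, `tp`, `fp`,
#'   `fn`, `tn`.
#' @examples
#' f1Score(c(1, 1, 0, 0), c(1, 0, 1, 0))  # F1 = 0.5
#' @export
f1Score <- function(yTrue, yPred, threshold = NA_real_) {
  if (length(yTrue) != length(yPred))
    parameterError("labels and predictions differ in length")
  if (!all(yTrue %in% c(0, 1)) || !all(yPred %in% c(0, 1)))
    parameterError("f1Score expects binary inputs")
  tp <- sum(yTrue == 1 & yPred == 1)
  fp <- sum(yTrue == 0 & yPred == 1)
  fn <- sum(yTrue == 1 & yPred == 0)
  tn <- sum(yTrue == 0 & yPred == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(f1 = f1, precision = precision, recall = recall,
       threshold = threshold, tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Choose the discriminant threshold by maximizing F1
#'
#' Exhaustively evaluates the rule "predict positive when score > theta"
#' over the grid and returns the threshold with the highest F1 (ties go to
#' the smallest theta).
#'
#' @param yTrue 0/1 labels.
#' @param scores probabilities in `[0, 1]`.
#' @param grid thresholds to examine (default 0 to 1 in steps of 0.01, the
#'   resolution at which thresholds are conventionally reported).
#' @return List with `bestTheta`, `bestF1`, and the per-threshold `grid` /
#'   `f1` vectors.
#' @export
optimizeThreshold <- function(yTrue, scores, grid = seq(0, 1, by = 0.01)) {
  if (length(grid) == 0L) parameterError("threshold grid must be non-empty")
  if (any(scores < 0) || any(scores > 1))
    parameterError("scores must lie in [0, 1]")
  grid <- sort(grid)
  f1s <- vapply(grid, function(th)
    f1Score(yTrue, as.numeric(scores > th))$f1, numeric(1))
  best <- which.max(f1s)  # which.max returns the first (smallest) maximizer
  list(bestTheta = grid[best], bestF1 = f1s[best], grid = grid, f1 = f1s)
}

#' Select the weighted-positive loss weight on validation data
#'
#' For each candidate lambda: fit a backbone on the training bundle, choose
#' the discriminant threshold on the validation bundle by maximizing F1, and
#' record that F1. The lambda with the best validation F1 wins; ties go to
#' the smallest lambda.
#'
#' @param lambdaGrid candidate weights (default `c(0.1, 0.5, 1, 2, 5)`).
#' @param train,validation bundles as produced by [aggregateSplit()]: pair
#'   rows with `y` and `is_true_positive` columns.
#' @param backboneFactory function(lambda) returning a fresh backbone
#'   instance whose loss uses that lambda.
#' @param seed fit seed shared across candidates.
#' @return List with `bestLambda`, `bestF1`, `bestTheta` and a per-candidate
#'   `report` data.frame.
#' @export
selectLambda <- function(lambdaGrid = c(0.1, 0.5, 1, 2, 5), train,
                         validation, backboneFactory, seed = 1L) {
  if (length(lambdaGrid) == 0L) parameterError("lambda grid must be non-empty")
  lambdaGrid <- sort(lambdaGrid)
  rows <- lapply(lambdaGrid, function(lam) {
    model <- backboneFactory(lam)
    model$fit(train, train$y, truePosMask = train$is_true_positive,
              seed = seed)
    val <- model$predictProba(validation)
    opt <- optimizeThreshold(validation$y, val)
    list(lambda = lam, f1 = opt$bestF1, theta = opt$bestTheta)
  })
  report <- data.frame(lambda = vapply(rows, `[[`, numeric(1), "lambda"),
                       f1 = vapply(rows, `[[`, numeric(1), "f1"),
                       theta = vapply(rows, `[[`, numeric(1), "theta"))
  best <- which.max(report$f1)
  list(bestLambda = report$lambda[best], bestF1 = report$f1[best],
       bestTheta = report$theta[best], report = report)
}

#' Positive-upweighting baseline: all unlabeled treated as negatives
#'
#' The comparator strategy that skips binning and pseudo-labeling entirely:
#' one classifier is trained on the known positives (each contributing
#' `positiveWeight`-fold to the cross-entropy) against the whole unlabeled
#' pool labeled negative. Evaluated like the main pipeline: the threshold is
#' optimized on the validation bundle, and metrics are reported on the
#' evaluation rows.
#'
#' @param positives data.frame of known positive pairs (with entity strings).
#' @param unlabeled data.frame of unlabeled pairs.
#' @param positiveWeight weight `w >= 1` applied to each positive row.
#' @param backboneFactory zero-argument backbone factory.
#' @param validation optional bundle with `y` for threshold optimization
#'   (threshold 0.5 when absent).
#' @param evaluation optional bundle with `y`; when present the returned
#'   report contains test metrics at the chosen threshold.
#' @param seed fit seed.
#' @return List with the fitted `model` instance, `threshold`, and `metrics`
#'   (NULL when no evaluation bundle was given).
#' @export
baselineAllNegative <- function(positives, unlabeled, positiveWeight = 1,
                                backboneFactory, validation = NULL,
                                evaluation = NULL, seed = 1L) {
  if (positiveWeight < 1) parameterError("positiveWeight must be >= 1")
  cols <- c("compound_id", "protein_id", "smiles", "sequence")
  rows <- rbind(positives[, cols, drop = FALSE],
                unlabeled[, cols, drop = FALSE])
  y <- rep(c(1, 0), c(nrow(positives), nrow(unlabeled)))
  w <- rep(c(positiveWeight, 1), c(nrow(positives), nrow(unlabeled)))
  model <- backboneFactory()
  model$fit(rows, y, weights = w, truePosMask = y == 1, seed = seed)
  threshold <- 0.5
  if (!is.null(validation)) {
    opt <- optimizeThreshold(validation$y, model$predictProba(validation))
    threshold <- opt$bestTheta
  }
  metrics <- NULL
  if (!is.null(evaluation)) {
    p <- model$predictProba(evaluation)
    metrics <- f1Score(evaluation$y, as.numeric(p > threshold),
                       threshold = threshold)
  }
  list(model = model, threshold = threshold, metrics = metrics)
}

# Largest-remainder style partition counts: exact for 500 * (0.6, 0.2, 0.2).
.splitCounts <- function(n, ratios) {
  diff(c(0L, round(cumsum(ratios) * n)))
}

#' Aggregate positives and pseudo labels into train/validation/test bundles
#'
#' The known positives and the pseudo-labeled samples are each shuffled and
#' split by the given ratios, then unioned per partition, preserving the
#' truly-positive mask the composite loss needs. Residual (unlabeled) pairs
#' are not used.
#'
#' @param pseudoLabelSet A [PseudoLabelSet-class].
#' @param positives data.frame of known positive pairs.
#' @param ratios three fractions summing to 1 (default 60/20/20).
#' @param seed shuffle seed.
#' @return List of data.frames `train`, `validation`, `test`, each with the
#'   pair columns plus `y` (0/1) and `is_true_positive`.
#' @export
aggregateSplit <- function(pseudoLabelSet, positives,
                           ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  if (length(ratios) != 3L || any(ratios < 0) ||
      abs(sum(ratios) - 1) > 1e-9)
    parameterError("ratios must be three non-negative fractions summing to 1")
  positives <- .asPairDf(positives)
  groups <- list(
    list(df = positives, y = 1, tp = TRUE),
    list(df = if (is(pseudoLabelSet, "PseudoLabelSet"))
      psiPos(pseudoLabelSet) else pseudoLabelSet$psiPos, y = 1, tp = FALSE),
    list(df = if (is(pseudoLabelSet, "PseudoLabelSet"))
      psiNeg(pseudoLabelSet) else pseudoLabelSet$psiNeg, y = 0, tp = FALSE))
  parts <- list(train = list(), validation = list(), test = list())
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    n <- nrow(g$df)
    if (n == 0L) next
    counts <- .splitCounts(n, ratios)
    perm <- withSeed(stageSeed(seed, gi), sample.int(n))
    assign <- rep(1:3, counts)
    cols <- intersect(c("compound_id", "protein_id", "smiles", "sequence"),
                      names(g$df))
    for (p in 1:3) {
      sl <- g$df[perm[assign == p], cols, drop = FALSE]
      if (nrow(sl) == 0L) next
      sl$y <- g$y
      sl$is_true_positive <- g$tp
      parts[[p]] <- c(parts[[p]], list(sl))
    }
  }
  lapply(parts, function(ps) {
    if (!length(ps))
      return(data.frame(compound_id = character(0), protein_id = character(0),
                        smiles = character(0), sequence = character(0),
                        y = numeric(0), is_true_positive = logical(0)))
    out <- do.call(rbind, ps)
    rownames(out) <- NULL
    out
  })
}
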