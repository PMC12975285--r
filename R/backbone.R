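# Pluggable classifier contract plus the reference backbone: hashed
# k-mer / character-n-gram featurization of protein sequences and SMILES
# strings feeding a single-hidden-layer feedforward network trained by
# mini-batch gradient descent on the composite loss with decoupled weight
# decay. Any model exposing fit()/predictProba() with the same semantics can
# replace it (checkBackboneContract() validates third-party backbones).

#' Featurizer configuration
#'
#' @param proteinK k-mer length for protein sequences (default 3).
#' @param smilesN character n-gram length for SMILES strings (default 3).
#' @param hashDim feature dimension per entity; each token is hashed into
#'   one of `hashDim` buckets with a sign bit, so collisions tend to cancel
#'   rather than accumulate. Default 1024, minimum 16.
#' @param hashSeed seed of the hash function (default 17); changing it
#'   permutes the bucket pattern but preserves norms.
#' @return Named list of validated settings.
#' @export
featurizerConfig <- function(proteinK = 3L, smilesN = 3L, hashDim = 1024L,
                             hashSeed = 17L) {
  assertCount(proteinK, "proteinK")
  assertCount(smilesN, "smilesN")
  assertCount(hashDim, "hashDim", min = 16L)
  assertCount(hashSeed, "hashSeed", min = 0L)
  list(proteinK = as.integer(proteinK), smilesN = as.integer(smilesN),
       hashDim = as.integer(hashDim), hashSeed = as.integer(hashSeed))
}

#' Hashed k-mer / n-gram featurization
#'
#' `featurizeProtein()` counts the overlapping k-mers of an amino-acid
#' sequence, hashes each into `hashDim` buckets with a signed-hash
#' convention and L2-normalizes the result; `featurizeCompound()` does the
#' same with character n-grams of the SMILES string. `featurizePairs()`
#' featurizes a pair table (caching per unique entity string) and returns
#' the concatenation `[protein block | compound block]`, the input
#' representation of the reference backbone.
#'
#' @param sequence amino-acid string, length at least `proteinK`.
#' @param smiles non-empty SMILES string, length at least `smilesN`.
#' @param rows data.frame with `smiles` and `sequence` columns.
#' @param config A [featurizerConfig()] list.
#' @return A numeric vector of length `hashDim` (matrix of width
#'   `2 * hashDim` for `featurizePairs()`).
#' @examples
#' cfg <- featurizerConfig(hashDim = 64)
#' sum(featurizeProtein("MKVLAA", cfg)^2)  # 1: L2-normalized
#' @export
featurizeProtein <- function(sequence, config = featurizerConfig()) {
  if (!nzchar(sequence))
    binpuError("binpu_featurization_error", "empty protein sequence")
  hashedCountVector(overlappingTokens(sequence, config$proteinK),
                    config$hashDim, config$hashSeed)
}

#' @rdname featurizeProtein
#' @export
featurizeCompound <- function(smiles, config = featurizerConfig()) {
  if (!nzchar(smiles))
    binpuError("binpu_featurization_error", "empty SMILES string")
  hashedCountVector(overlappingTokens(smiles, config$smilesN),
                    config$hashDim, config$hashSeed)
}

#' @rdname featurizeProtein
#' @export
featurizePairs <- function(rows, config = featurizerConfig()) {
  if (!all(c("smiles", "sequence") %in% names(rows)))
    parameterError("rows must carry 'smiles' and 'sequence' columns")
  useq <- unique(rows$sequence)
  usmi <- unique(rows$smiles)
  seqF <- vapply(useq, featurizeProtein, numeric(config$hashDim),
                 config = config)
  smiF <- vapply(usmi, featurizeCompound, numeric(config$hashDim),
                 config = config)
  X <- cbind(t(seqF)[match(rows$sequence, useq), , drop = FALSE],
             t(smiF)[match(rows$smiles, usmi), , drop = FALSE])
  dimnames(X) <- NULL
  X
}

#' Training configuration for the reference backbone
#'
#' @param learningRate gradient-descent step size (default 1e-4).
#' @param weightDecay decoupled L2 weight decay (default 1e-5).
#' @param epochs passes over the training data (default 200).
#' @param batchSize mini-batch size (default 64).
#' @param hiddenUnits width of the single hidden layer (default 32).
#' @param seed optional default fit seed.
#' @return Named list of validated settings.
#' @export
trainConfig <- function(learningRate = 1e-4, weightDecay = 1e-5,
                        epochs = 200L, batchSize = 64L, hiddenUnits = 32L,
                        seed = NULL) {
  if (!is.numeric(learningRate) || learningRate <= 0)
    parameterError("learningRate must be > 0")
  if (!is.numeric(weightDecay) || weightDecay <= 0)
    parameterError("weightDecay must be > 0")
  assertCount(epochs, "epochs")
  assertCount(batchSize, "batchSize")
  assertCount(hiddenUnits, "hiddenUnits")
  list(learningRate = learningRate, weightDecay = weightDecay,
       epochs = as.integer(epochs), batchSize = as.integer(batchSize),
       hiddenUnits = as.integer(hiddenUnits), seed = seed)
}

.forward <- function(state, X) {
  H <- tanh(sweep(X %*% state$W1, 2L, state$b1, `+`))
  logit <- drop(H %*% state$W2) + state$b2
  list(H = H, p = plogis(logit))
}

#' Fit the reference backbone
#'
#' Mini-batch gradient descent on the composite loss with decoupled weight
#' decay; the network is a tanh hidden layer followed by a sigmoid output.
#' Requires at least one positive and one negative row. The per-epoch
#' training loss is recorded in the returned state. A fixed seed gives
#' bitwise-identical weights.
#'
#' @param rows data.frame with `smiles` and `sequence` columns (featurized
#'   internally), or a precomputed numeric feature matrix.
#' @param labels 0/1 labels.
#' @param loss A [lossConfig()] list.
#' @param train A [trainConfig()] list.
#' @param featurizer A [featurizerConfig()] list (ignored when `rows` is
#'   already a matrix).
#' @param weights optional per-row BCE weights (positive upweighting).
#' @param truePosMask logical mask of truly positive rows for the
#'   weighted-positive term; defaults to `labels == 1`.
#' @param seed fit seed (initialization and batch shuffling).
#' @return An object of class `binpuModel`: weight arrays, configs and the
#'   per-epoch loss curve.
#' @seealso [referencePredict()], [referenceBackbone()]
#' @export
referenceFit <- function(rows, labels, loss = lossConfig(lambda = 0),
                         train = trainConfig(),
                         featurizer = featurizerConfig(), weights = NULL,
                         truePosMask = NULL, seed = NULL) {
  seed <- seed %||% train$seed %||% 1L
  X <- if (is.matrix(rows)) rows else featurizePairs(rows, featurizer)
  y <- as.numeric(labels)
  if (length(y) != nrow(X)) parameterError("labels must match rows")
  if (all(y == 1) || all(y == 0))
    binpuError("binpu_degenerate_training_error",
               "training needs at least one positive and one negative row")
  mask <- truePosMask %||% (y == 1)
  p <- ncol(X)
  H <- train$hiddenUnits
  state <- withSeed(seed, list(
    W1 = matrix(rnorm(p * H, sd = 1 / sqrt(p)), p, H),
    b1 = numeric(H),
    W2 = matrix(rnorm(H, sd = 1 / sqrt(H)), H, 1L),
    b2 = 0))
  n <- nrow(X)
  lr <- train$learningRate
  wd <- train$weightDecay
  lossCurve <- numeric(train$epochs)
  orders <- withSeed(stageSeed(seed, 1L),
                     lapply(seq_len(train$epochs), function(e) sample.int(n)))
  for (epoch in seq_len(train$epochs)) {
    idx <- orders[[epoch]]
    starts <- seq(1L, n, by = train$batchSize)
    for (s in starts) {
      b <- idx[s:min(s + train$batchSize - 1L, n)]
      Xb <- X[b, , drop = FALSE]
      fw <- .forward(state, Xb)
      gp <- lossGradient(y[b], fw$p, mask[b], loss,
                         weights = if (!is.null(weights)) weights[b])
      gLogit <- gp * fw$p * (1 - fw$p)
      gW2 <- crossprod(fw$H, gLogit)
      gb2 <- sum(gLogit)
      gH <- (gLogit %*% t(state$W2)) * (1 - fw$H^2)
      gW1 <- crossprod(Xb, gH)
      gb1 <- colSums(gH)
      state$W1 <- state$W1 * (1 - lr * wd) - lr * gW1
      state$b1 <- state$b1 - lr * gb1
      state$W2 <- state$W2 * (1 - lr * wd) - lr * gW2
      state$b2 <- state$b2 - lr * gb2
    }
    fwAll <- .forward(state, X)
    lossCurve[epoch] <- compositeLoss(y, fwAll$p, mask, loss,
                                      weights = weights)$total
  }
  structure(list(W1 = state$W1, b1 = state$b1, W2 = state$W2, b2 = state$b2,
                 featurizer = featurizer, train = train, loss = loss,
                 seed = seed, lossCurve = lossCurve,
                 inputDim = p, version = 1L),
            class = "binpuModel")
}

#' Predict interaction probabilities with a fitted reference backbone
#'
#' @param model a fitted `binpuModel` from [referenceFit()].
#' @param rows data.frame with `smiles`/`sequence` columns or a feature
#'   matrix matching the model's input dimension.
#' @return Probabilities in (0, 1), one per row.
#' @export
referencePredict <- function(model, rows) {
  if (!inherits(model, "binpuModel"))
    stateError("model is not a fitted reference backbone")
  X <- if (is.matrix(rows)) rows else featurizePairs(rows, model$featurizer)
  if (ncol(X) != model$inputDim)
    stateError("feature dimension %d does not match the fitted model (%d)",
               ncol(X), model$inputDim)
  .forward(model, X)$p
}

#' Reference backbone factory
#'
#' Returns a zero-argument factory producing fresh, independent backbone
#' instances satisfying the backbone contract used by [scoreEnsemble()]:
#' each instance is a list with `fit(rows, labels, weights, truePosMask,
#' seed)`, `predictProba(rows)` and `isFitted()`.
#'
#' @param featurizer A [featurizerConfig()] list.
#' @param train A [trainConfig()] list.
#' @param loss A [lossConfig()] list; the default plain BCE (`lambda = 0`)
#'   is what the per-bin classifiers use.
#' @return A function returning fresh backbone instances.
#' @export
referenceBackbone <- function(featurizer = featurizerConfig(),
                              train = trainConfig(),
                              loss = lossConfig(lambda = 0)) {
  force(featurizer); force(train); force(loss)
  function() {
    env <- new.env(parent = emptyenv())
    env$model <- NULL
    list(
      fit = function(rows, labels, weights = NULL, truePosMask = NULL,
                     seed = NULL) {
        env$model <- referenceFit(rows, labels, loss = loss, train = train,
                                  featurizer = featurizer, weights = weights,
                                  truePosMask = truePosMask, seed = seed)
        invisible(NULL)
      },
      predictProba = function(rows) {
        if (is.null(env$model)) stateError("backbone has not been fitted")
        referencePredict(env$model, rows)
      },
      isFitted = function() !is.null(env$model),
      getModel = function() env$model
    )
  }
}

#' Deterministic stub backbone for pipeline tests
#'
#' A backbone whose `fit()` is a no-op and whose `predictProba()` applies a
#' user-supplied deterministic scoring function to the rows. Useful for
#' validating pipeline plumbing (bin construction, ensemble averaging,
#' pseudo-label assignment) against brute-force recomputation.
#'
#' @param scoreFun function(rows) returning probabilities in `[0, 1]`.
#' @return A backbone factory.
#' @export
stubBackbone <- function(scoreFun) {
  force(scoreFun)
  function() {
    fitted <- FALSE
    list(
      fit = function(rows, labels, weights = NULL, truePosMask = NULL,
                     seed = NULL) {
        fitted <<- TRUE
        invisible(NULL)
      },
      predictProba = function(rows) scoreFun(rows),
      isFitted = function() fitted
    )
  }
}

#' Validate a backbone against the pluggability contract
#'
#' Runs the conformance checks any backbone must satisfy before it can be
#' used in the scoring ensemble: probabilities in `[0, 1]`, deterministic
#' prediction after fitting, identical results when refitted with the same
#' seed, and independence of fresh instances.
#'
#' @param factory zero-argument backbone factory.
#' @param rows training/scoring rows to exercise the backbone with.
#' @param labels 0/1 labels for `rows` (must contain both classes).
#' @param seed fit seed used for the checks.
#' @return Invisibly, a named logical vector of passed checks; fails with a
#'   contract error otherwise.
#' @export
checkBackboneContract <- function(factory, rows, labels, seed = 1L) {
  checks <- c(range = FALSE, deterministic = FALSE, reproducible = FALSE,
              independent = FALSE)
  m1 <- factory()
  m1$fit(rows, labels, seed = seed)
  p1 <- m1$predictProba(rows)
  if (length(p1) != nrow(rows) || any(is.na(p1)) || any(p1 < 0) ||
      any(p1 > 1))
    contractError("predictProba must return one probability in [0,1] per row")
  checks["range"] <- TRUE
  if (!identical(p1, m1$predictProba(rows)))
    contractError("predictProba must be deterministic after fit")
  checks["deterministic"] <- TRUE
  m2 <- factory()
  m2$fit(rows, labels, seed = seed)
  if (max(abs(p1 - m2$predictProba(rows))) > 1e-12)
    contractError("refitting with the same seed must reproduce predictions")
  checks["reproducible"] <- TRUE
  m3 <- factory()
  m3$fit(rows, labels, seed = seed + 1L)
  m2b <- m2$predictProba(rows)
  if (max(abs(p1 - m2b)) > 1e-12)
    contractError("fitting a fresh instance must not disturb an existing one")
  checks["independent"] <- TRUE
  invisible(checks)
}

#' Save / load a fitted reference backbone
#'
#' The trained state is serialized as a single versioned JSON file of named
#' weight arrays plus a manifest (dimensions, configurations, fit seed);
#' loading validates the manifest against the arrays.
#'
#' @param model a fitted `binpuModel`.
#' @param path file path.
#' @return `saveBackbone()` returns `path` invisibly; `loadBackbone()`
#'   returns the restored `binpuModel`.
#' @export
saveBackbone <- function(model, path) {
  if (!inherits(model, "binpuModel"))
    stateError("model is not a fitted reference backbone")
  payload <- list(
    version = model$version,
    manifest = list(inputDim = model$inputDim,
                    hiddenUnits = ncol(model$W1),
                    featurizer = model$featurizer,
                    train = model$train[setdiff(names(model$train), "seed")],
                    loss = model$loss[c("lambda", "epsilon")],
                    seed = model$seed),
    weights = list(W1 = model$W1, b1 = model$b1,
                   W2 = as.numeric(model$W2), b2 = model$b2),
    lossCurve = model$lossCurve)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname saveBackbone
#' @export
loadBackbone <- function(path) {
  if (!file.exists(path)) ioError("file not found: %s", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  man <- payload$manifest
  W1 <- payload$weights$W1
  if (is.null(man$inputDim) || is.null(W1) ||
      nrow(W1) != man$inputDim || ncol(W1) != man$hiddenUnits)
    formatError("backbone file manifest does not match its weight arrays")
  fc <- do.call(featurizerConfig, man$featurizer)
  tc <- do.call(trainConfig, man$train)
  lc <- do.call(lossConfig, man$loss)
  structure(list(W1 = W1, b1 = as.numeric(payload$weights$b1),
                 W2 = matrix(payload$weights$W2, ncol = 1L),
                 b2 = payload$weights$b2,
                 featurizer = fc, train = tc, loss = lc,
                 seed = man$seed, lossCurve = payload$lossCurve,
                 inputDim = man$inputDim, version = payload$version),
            class = "binpuModel")
}
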