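# The PU-learning engine: unlabeled-pair generation, spy splitting, K-bin
# partitioning, per-bin ensemble scoring, pseudo-label assignment, and the
# spies-capture-rate diagnostic.
#
# Pair tables flowing through this module carry compound_id, protein_id,
# smiles, sequence, label and is_spy so any backbone can featurize them
# directly.

#' Pipeline configuration for pseudo-label generation
#'
#' @param K number of bins the unlabeled pool is partitioned into. Each bin,
#'   unioned with the full set of training positives, trains one classifier
#'   of the scoring ensemble. Default 20.
#' @param thetaU,thetaL upper / lower score thresholds: ensemble score
#'   strictly above `thetaU` makes a pair pseudo-positive, strictly below
#'   `thetaL` pseudo-negative; everything between stays unlabeled. Defaults
#'   0.8 / 0.2.
#' @param mode `"score"` applies `thetaU`/`thetaL` to the ensemble score
#'   directly; `"percentile"` labels the top and bottom `percentile`
#'   fraction of pairs instead.
#' @param percentile fraction in (0, 0.5] used in percentile mode
#'   (default 0.2, i.e. top-20%/bottom-20%).
#' @param spyFraction fraction of known positives hidden in the unlabeled
#'   pool as spies (default 0.2).
#' @param scoreScope `"all"`: every bin's model scores every pair and the
#'   ensemble mean runs over all K scores. `"held_out"`: a model never
#'   scores pairs from its own bin (its own training negatives), so each
#'   pair averages K-1 out-of-bin scores.
#' @param captureThreshold ensemble score above which a spy counts as
#'   captured for the SCR diagnostic (default 0.5).
#' @return A named list of validated settings.
#' @export
binPuConfig <- function(K = 20L, thetaU = 0.8, thetaL = 0.2,
                        mode = c("score", "percentile"), percentile = 0.2,
                        spyFraction = 0.2,
                        scoreScope = c("all", "held_out"),
                        captureThreshold = 0.5) {
  mode <- match.arg(mode)
  scoreScope <- match.arg(scoreScope)
  assertCount(K, "K")
  assertNumber(thetaU, "thetaU", 0, 1)
  assertNumber(thetaL, "thetaL", 0, 1)
  if (mode == "score" && thetaL >= thetaU)
    parameterError("thetaL (%.3f) must be strictly below thetaU (%.3f)",
                   thetaL, thetaU)
  if (mode == "percentile" && (percentile <= 0 || percentile > 0.5))
    parameterError("percentile must lie in (0, 0.5]")
  assertNumber(spyFraction, "spyFraction", 0, 1 - 1e-12)
  assertNumber(captureThreshold, "captureThreshold", 0, 1)
  list(K = as.integer(K), thetaU = thetaU, thetaL = thetaL, mode = mode,
       percentile = percentile, spyFraction = spyFraction,
       scoreScope = scoreScope, captureThreshold = captureThreshold)
}

.asPairDf <- function(pairs) {
  if (is(pairs, "CpiData")) pairs <- interactions(pairs)
  pairs
}

.emptyPairDf <- function() {
  data.frame(compound_id = character(0), protein_id = character(0),
             smiles = character(0), sequence = character(0),
             label = character(0), is_spy = logical(0),
             stringsAsFactors = FALSE)
}

#' Generate the unlabeled set by pairwise combination
#'
#' Forms every (compound, protein) pair from the given entity tables and
#' removes the known positives: the remainder is the unlabeled pool, which
#' mixes undiscovered true interactions with true non-interactions. Pairs are
#' emitted in deterministic lexicographic order by (compound_id,
#' protein_id).
#'
#' @param compounds data.frame (`compound_id`, `smiles`).
#' @param proteins data.frame (`protein_id`, `sequence`).
#' @param positives data.frame of known positive pairs (or a
#'   [CpiData-class], whose positive interactions are used).
#' @return data.frame of unlabeled pairs with entity strings attached.
#' @examples
#' cmp <- data.frame(compound_id = c("c1", "c2"), smiles = c("CCO", "CCN"))
#' prt <- data.frame(protein_id = "p1", sequence = "MKV")
#' pos <- data.frame(compound_id = "c1", protein_id = "p1")
#' generateUnlabeled(cmp, prt, pos)
#' @export
generateUnlabeled <- function(compounds, proteins, positives) {
  positives <- .asPairDf(positives)
  if (nrow(compounds) == 0L || nrow(proteins) == 0L)
    parameterError("cannot generate unlabeled pairs from an empty entity set")
  if (anyDuplicated(pairKey(positives$compound_id, positives$protein_id)))
    consistencyError("positive pairs must be distinct")
  if (!all(positives$compound_id %in% compounds$compound_id) ||
      !all(positives$protein_id %in% proteins$protein_id))
    consistencyError("positive pair references an unknown compound or protein")
  cid <- compounds$compound_id[lexOrder(compounds$compound_id)]
  pid <- proteins$protein_id[lexOrder(proteins$protein_id)]
  grid <- data.frame(
    compound_id = rep(cid, each = length(pid)),
    protein_id = rep(pid, times = length(cid)),
    stringsAsFactors = FALSE)
  drop <- pairKey(grid$compound_id, grid$protein_id) %in%
    pairKey(positives$compound_id, positives$protein_id)
  out <- grid[!drop, , drop = FALSE]
  out$smiles <- compounds$smiles[match(out$compound_id, compounds$compound_id)]
  out$sequence <- proteins$sequence[match(out$protein_id, proteins$protein_id)]
  out$label <- rep("unlabeled", nrow(out))
  out$is_spy <- rep(FALSE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Split known positives into training positives and spies
#'
#' Spies are known positives hidden inside the unlabeled pool: the bin
#' classifiers see them as negatives, and how many of them the ensemble
#' still scores as positive (the SCR) diagnoses pseudo-label quality.
#'
#' @param positives data.frame of known positive pairs.
#' @param spyFraction fraction in `[0, 1)` of positives to hide;
#'   `round(spyFraction * n)` spies are drawn uniformly without replacement.
#' @param seed integer seed; a fixed seed reproduces the split exactly.
#' @return list with `trainPositives` and `spies` data.frames (spies carry
#'   `label = "spy"`, `is_spy = TRUE`).
#' @export
splitSpies <- function(positives, spyFraction = 0.2, seed = 1L) {
  positives <- .asPairDf(positives)
  assertNumber(spyFraction, "spyFraction", 0, 1 - 1e-12)
  n <- nrow(positives)
  nSpies <- round(spyFraction * n)
  idx <- if (nSpies > 0L) withSeed(seed, sample.int(n, nSpies)) else integer(0)
  spies <- positives[idx, , drop = FALSE]
  train <- positives[setdiff(seq_len(n), idx), , drop = FALSE]
  if (nrow(spies)) {
    spies$label <- "spy"
    spies$is_spy <- TRUE
  }
  if (nrow(train)) train$is_spy <- FALSE
  rownames(spies) <- rownames(train) <- NULL
  list(trainPositives = train, spies = spies)
}

#' Add spy pairs to the unlabeled pool
#'
#' The returned pool keeps the spy flag for later diagnostics, but the flag
#' is invisible to the per-bin classifiers: when a bin training set is built,
#' every pool member (spies included) is labeled negative.
#'
#' @param unlabeled data.frame of unlabeled pairs.
#' @param spies data.frame of spy pairs, disjoint from `unlabeled`.
#' @return data.frame: the union, sorted lexicographically by pair id.
#' @export
injectSpies <- function(unlabeled, spies) {
  if (nrow(spies) == 0L) return(unlabeled)
  uk <- pairKey(unlabeled$compound_id, unlabeled$protein_id)
  sk <- pairKey(spies$compound_id, spies$protein_id)
  if (any(sk %in% uk))
    consistencyError("spy pair already present in the unlabeled pool")
  spies$label <- "spy"
  spies$is_spy <- TRUE
  cols <- c("compound_id", "protein_id", "smiles", "sequence", "label",
            "is_spy")
  cols <- intersect(cols, intersect(names(unlabeled), names(spies)))
  out <- rbind(unlabeled[, cols, drop = FALSE], spies[, cols, drop = FALSE])
  out <- out[lexOrder(out$compound_id, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Randomly partition the unlabeled pool into K bins
#'
#' Produces a disjoint cover with bin sizes differing by at most one, drawn
#' uniformly at random under the seed.
#'
#' @param unlabeled data.frame of pool pairs (unlabeled plus spies).
#' @param K number of bins, `1 <= K <= nrow(unlabeled)`.
#' @param seed integer seed.
#' @return A [BinAssignment-class].
#' @export
partitionBins <- function(unlabeled, K, seed = 1L) {
  assertCount(K, "K")
  n <- nrow(unlabeled)
  if (K > n)
    parameterError("K = %d exceeds the number of pool pairs (%d)", K, n)
  base <- n %/% K
  extra <- n %% K
  sizes <- rep(base, K) + c(rep(1L, extra), rep(0L, K - extra))
  membership <- withSeed(seed, sample(rep.int(seq_len(K), sizes)))
  new("BinAssignment", K = as.integer(K), membership = as.integer(membership),
      pairs = unlabeled)
}

#' Build the labeled training set for one bin
#'
#' The bin's training set is the union of the full training-positive set
#' (label 1) with that bin's slice of the unlabeled pool (label 0). Every
#' bin therefore sees all training positives; spies inside the slice are
#' serialized as plain negatives.
#'
#' @param binPairs data.frame: the pairs of one bin.
#' @param trainPositives data.frame of training positives.
#' @return data.frame with columns of the inputs plus `y` (0/1) and
#'   `is_true_positive` (the mask the weighted-positive loss needs).
#' @export
buildBinTrainingSet <- function(binPairs, trainPositives) {
  bk <- pairKey(binPairs$compound_id, binPairs$protein_id)
  pk <- pairKey(trainPositives$compound_id, trainPositives$protein_id)
  if (any(pk %in% bk))
    consistencyError("training positives overlap the bin's unlabeled pairs")
  cols <- c("compound_id", "protein_id", "smiles", "sequence")
  cols <- intersect(cols, intersect(names(binPairs), names(trainPositives)))
  pos <- trainPositives[, cols, drop = FALSE]
  neg <- binPairs[, cols, drop = FALSE]
  out <- rbind(pos, neg)
  out$y <- rep(c(1, 0), c(nrow(pos), nrow(neg)))
  out$is_true_positive <- out$y == 1
  rownames(out) <- NULL
  out
}

#' Score the unlabeled pool with the bin ensemble
#'
#' Trains one fresh backbone per bin on that bin's training set and collects
#' per-bin posterior probabilities for the pool pairs. The ensemble score of
#' a pair is the mean of its collected per-bin scores.
#'
#' @param bins A [BinAssignment-class].
#' @param trainPositives data.frame of training positives.
#' @param backboneFactory zero-argument function returning a fresh untrained
#'   backbone: a list with `fit(rows, labels, weights, truePosMask, seed)`
#'   and `predictProba(rows)` (see [checkBackboneContract()]).
#' @param seed integer seed; per-bin fit seeds are derived from it.
#' @param scoreScope `"all"` (every model scores every pair; K scores per
#'   pair) or `"held_out"` (a model skips its own bin; K-1 scores per pair,
#'   requires `K >= 2`).
#' @return A [ScoreTable-class].
#' @export
scoreEnsemble <- function(bins, trainPositives, backboneFactory, seed = 1L,
                          scoreScope = c("all", "held_out")) {
  scoreScope <- match.arg(scoreScope)
  if (!is(bins, "BinAssignment"))
    parameterError("'bins' must be a BinAssignment")
  K <- bins@K
  if (scoreScope == "held_out" && K < 2L)
    parameterError("held_out scoring needs at least 2 bins")
  pool <- bins@pairs
  n <- nrow(pool)
  scores <- matrix(NA_real_, nrow = n, ncol = K)
  for (k in seq_len(K)) {
    model <- backboneFactory()
    trainSet <- buildBinTrainingSet(pool[bins@membership == k, , drop = FALSE],
                                    trainPositives)
    model$fit(trainSet, trainSet$y, truePosMask = trainSet$is_true_positive,
              seed = stageSeed(seed, k))
    target <- if (scoreScope == "all") seq_len(n)
              else which(bins@membership != k)
    p <- model$predictProba(pool[target, , drop = FALSE])
    if (length(p) != length(target) || any(is.na(p)) || any(p < 0) ||
        any(p > 1))
      contractError("backbone for bin %d returned scores outside [0, 1]", k)
    scores[target, k] <- p
  }
  new("ScoreTable", pairs = pool, binScores = scores,
      meanScore = rowMeans(scores, na.rm = TRUE))
}

#' Assign pseudo labels from ensemble scores
#'
#' In score mode a pair becomes pseudo-positive when its ensemble score is
#' strictly above `thetaU` and pseudo-negative when strictly below `thetaL`;
#' everything else is residual and unused for further training. In
#' percentile mode the top and bottom `percentile` fraction (by score, ties
#' broken by lexicographic pair order; the bottom set is drawn from pairs
#' not already in the top set) are labeled instead. Spies never enter the
#' pseudo-labeled sets.
#'
#' @param scores A [ScoreTable-class].
#' @param config A [binPuConfig()] list.
#' @return A [PseudoLabelSet-class].
#' @export
assignPseudoLabels <- function(scores, config = binPuConfig()) {
  if (!is(scores, "ScoreTable")) parameterError("'scores' must be a ScoreTable")
  pool <- scores@pairs
  pool$score <- scores@meanScore
  isSpy <- if ("is_spy" %in% names(pool)) pool$is_spy else
    rep(FALSE, nrow(pool))
  spies <- pool[isSpy, , drop = FALSE]
  cand <- pool[!isSpy, , drop = FALSE]
  n <- nrow(cand)
  if (config$mode == "score") {
    posIdx <- which(cand$score > config$thetaU)
    negIdx <- which(cand$score < config$thetaL)
  } else {
    nSel <- floor(config$percentile * n)
    topOrder <- lexOrder(-cand$score, cand$compound_id, cand$protein_id)
    posIdx <- topOrder[seq_len(nSel)]
    rest <- setdiff(seq_len(n), posIdx)
    botOrder <- rest[lexOrder(cand$score[rest], cand$compound_id[rest],
                              cand$protein_id[rest])]
    negIdx <- botOrder[seq_len(min(nSel, length(botOrder)))]
  }
  resIdx <- setdiff(seq_len(n), c(posIdx, negIdx))
  lab <- function(df, label) {
    if (nrow(df)) df$label <- label
    rownames(df) <- NULL
    df
  }
  new("PseudoLabelSet",
      psiPos = lab(cand[posIdx, , drop = FALSE], "pseudo_positive"),
      psiNeg = lab(cand[negIdx, , drop = FALSE], "pseudo_negative"),
      residual = lab(cand[resIdx, , drop = FALSE], "unlabeled"),
      spies = lab(spies, "spy"),
      config = config)
}

#' Spies capture rate
#'
#' Fraction of spy pairs whose ensemble score is strictly above the capture
#' threshold. A rate near 1 means the ensemble recovers hidden positives
#' from the unlabeled pool.
#'
#' @param scores A [ScoreTable-class] whose pool contains the spies.
#' @param captureThreshold score above which a spy counts as captured.
#' @return A [SpyReport-class].
#' @export
computeScr <- function(scores, captureThreshold = 0.5) {
  if (!is(scores, "ScoreTable")) parameterError("'scores' must be a ScoreTable")
  assertNumber(captureThreshold, "captureThreshold", 0, 1)
  isSpy <- scores@pairs$is_spy
  if (is.null(isSpy) || sum(isSpy) == 0L)
    binpuError("binpu_undefined_metric_error",
               "SCR is undefined without spy pairs")
  spyScores <- scores@meanScore[isSpy]
  nS <- length(spyScores)
  nTS <- sum(spyScores > captureThreshold)
  new("SpyReport", nSpies = as.integer(nS), nCaptured = as.integer(nTS),
      scr = nTS / nS, captureThreshold = captureThreshold)
}

#' Run the full pseudo-labeling pipeline
#'
#' Orchestrates unlabeled-pair generation, spy splitting, spy injection,
#' bin partitioning, ensemble scoring, SCR computation and pseudo-label
#' assignment. Every stage seed is derived from the master seed, so a fixed
#' seed reproduces the output exactly.
#'
#' @param positives data.frame of known positive pairs (or [CpiData-class]).
#' @param compounds,proteins entity tables; defaulted from `positives` when
#'   it is a [CpiData-class].
#' @param config A [binPuConfig()] list.
#' @param backboneFactory see [scoreEnsemble()].
#' @param seed master integer seed.
#' @param verbose log stage cardinalities via `message()`.
#' @return A [BinPuFit-class].
#' @export
runBinPu <- function(positives, compounds = NULL, proteins = NULL,
                     config = binPuConfig(),
                     backboneFactory = referenceBackbone(),
                     seed = 1L, verbose = FALSE) {
  if (is(positives, "CpiData")) {
    compounds <- compounds %||% compounds(positives)
    proteins <- proteins %||% proteins(positives)
    positives <- interactions(positives)
  }
  if (is.null(compounds) || is.null(proteins))
    parameterError("compound and protein tables are required")
  if ("label" %in% names(positives))
    positives <- positives[positives$label == "positive", , drop = FALSE]
  if (nrow(positives) == 0L)
    parameterError("no positive pairs to learn from")
  positives$smiles <- compounds$smiles[
    match(positives$compound_id, compounds$compound_id)]
  positives$sequence <- proteins$sequence[
    match(positives$protein_id, proteins$protein_id)]
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))

  unlabeled <- generateUnlabeled(compounds, proteins, positives)
  say("[pairs] %d compounds x %d proteins - %d positives -> %d unlabeled",
      nrow(compounds), nrow(proteins), nrow(positives), nrow(unlabeled))

  split <- splitSpies(positives, config$spyFraction, stageSeed(seed, 1L))
  say("[spies] %d training positives, %d spies",
      nrow(split$trainPositives), nrow(split$spies))

  pool <- injectSpies(unlabeled, split$spies)
  bins <- partitionBins(pool, config$K, stageSeed(seed, 2L))
  say("[bins] %d pool pairs in %d bins (sizes %s)", nrow(pool), config$K,
      paste(range(binSizes(bins)), collapse = ".."))

  scores <- scoreEnsemble(bins, split$trainPositives, backboneFactory,
                          seed = stageSeed(seed, 3L),
                          scoreScope = config$scoreScope)
  hasSpies <- nrow(split$spies) > 0L
  report <- if (hasSpies) computeScr(scores, config$captureThreshold) else NULL
  if (hasSpies)
    say("[scr] %.4f (%d/%d spies captured)", report@scr, report@nCaptured,
        report@nSpies)

  labels <- assignPseudoLabels(scores, config)
  say("[pseudo] %d pseudo-positive, %d pseudo-negative, %d residual",
      nrow(labels@psiPos), nrow(labels@psiNeg), nrow(labels@residual))

  manifest <- list(
    seed = seed, K = config$K, thetaU = config$thetaU, thetaL = config$thetaL,
    mode = config$mode, percentile = config$percentile,
    spyFraction = config$spyFraction, scoreScope = config$scoreScope,
    captureThreshold = config$captureThreshold,
    scr = if (hasSpies) report@scr else NA_real_,
    cardinalities = list(
      compounds = nrow(compounds), proteins = nrow(proteins),
      positives = nrow(positives), unlabeled = nrow(unlabeled),
      trainPositives = nrow(split$trainPositives), spies = nrow(split$spies),
      pool = nrow(pool), psiPos = nrow(labels@psiPos),
      psiNeg = nrow(labels@psiNeg), residual = nrow(labels@residual)))
  new("BinPuFit", pseudoLabels = labels, spyReport = report,
      scoreTable = scores, manifest = manifest)
}

#' Serialize a pseudo-label run to a single pair table
#'
#' The emitted rows are the pseudo-positive, pseudo-negative, residual and
#' spy pairs with their ensemble scores; training positives are not part of
#' the scored pool and are not included.
#'
#' @param fit A [BinPuFit-class].
#' @return data.frame with `compound_id`, `protein_id`, `label`, `score`.
#' @export
pseudoLabelTable <- function(fit) {
  pl <- pseudoLabels(fit)
  parts <- list(psiPos(pl), psiNeg(pl), residualPairs(pl), spyPairs(pl))
  parts <- parts[vapply(parts, nrow, integer(1)) > 0L]
  cols <- c("compound_id", "protein_id", "label", "score")
  out <- do.call(rbind, lapply(parts, function(p) p[, cols, drop = FALSE]))
  out <- out[lexOrder(out$compound_id, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
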