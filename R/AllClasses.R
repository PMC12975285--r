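# S4 classes for the PU-learning pipeline. All pair tables are plain
# data.frames with at least compound_id / protein_id columns; entity tables
# carry the raw SMILES and amino-acid strings so any backbone can featurize
# them without a second lookup.

PAIR_LABELS <- c("positive", "unlabeled", "pseudo_positive",
                 "pseudo_negative", "spy")

AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

.checkPairCols <- function(df, what) {
  need <- c("compound_id", "protein_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    return(sprintf("%s lacks column(s): %s", what, paste(miss, collapse = ", ")))
  NULL
}

#' CpiData: compounds, proteins and their interaction pairs
#'
#' Container for a compound-protein interaction dataset: a compound table
#' (`compound_id`, `smiles`), a protein table (`protein_id`, `sequence`) and
#' an interaction table (`compound_id`, `protein_id`, `label`, optional
#' `score`). Entities are unique by their SMILES / sequence string and every
#' pair must reference an existing entity.
#'
#' @slot compounds data.frame with columns `compound_id`, `smiles`.
#' @slot proteins data.frame with columns `protein_id`, `sequence`.
#' @slot interactions data.frame with columns `compound_id`, `protein_id`,
#'   `label` (one of positive, unlabeled, pseudo_positive, pseudo_negative,
#'   spy) and optionally `score` in `[0, 1]`.
#'
#' @seealso [readInteractions()], [compounds()], [proteins()],
#'   [interactions()]
#' @export
setClass("CpiData", representation(
  compounds = "data.frame",
  proteins = "data.frame",
  interactions = "data.frame"
))

setValidity("CpiData", function(object) {
  cmp <- object@compounds; prt <- object@proteins; ints <- object@interactions
  msgs <- character(0)
  if (!all(c("compound_id", "smiles") %in% names(cmp)))
    msgs <- c(msgs, "compounds must have columns compound_id, smiles")
  if (!all(c("protein_id", "sequence") %in% names(prt)))
    msgs <- c(msgs, "proteins must have columns protein_id, sequence")
  m <- .checkPairCols(ints, "interactions"); if (!is.null(m)) msgs <- c(msgs, m)
  if (!length(msgs)) {
    if (anyDuplicated(cmp$compound_id)) msgs <- c(msgs, "duplicate compound_id")
    if (anyDuplicated(prt$protein_id)) msgs <- c(msgs, "duplicate protein_id")
    if (any(!nzchar(cmp$smiles))) msgs <- c(msgs, "empty SMILES string")
    if (any(!nzchar(prt$sequence))) msgs <- c(msgs, "empty protein sequence")
    if (!all(ints$compound_id %in% cmp$compound_id))
      msgs <- c(msgs, "interaction references unknown compound_id")
    if (!all(ints$protein_id %in% prt$protein_id))
      msgs <- c(msgs, "interaction references unknown protein_id")
    if ("label" %in% names(ints) && !all(ints$label %in% PAIR_LABELS))
      msgs <- c(msgs, sprintf("labels must be among: %s",
                              paste(PAIR_LABELS, collapse = ", ")))
    if (anyDuplicated(pairKey(ints$compound_id, ints$protein_id)))
      msgs <- c(msgs, "duplicate (compound_id, protein_id) pair")
    if ("score" %in% names(ints)) {
      sc <- ints$score[!is.na(ints$score)]
      if (length(sc) && (any(sc < 0) || any(sc > 1)))
        msgs <- c(msgs, "scores must lie in [0, 1]")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' BinAssignment: random K-way partition of the unlabeled pool
#'
#' @slot K integer bin count.
#' @slot membership integer vector parallel to `pairs`, values in `1..K`.
#' @slot pairs data.frame of the partitioned pairs (unlabeled plus spies).
#'
#' @seealso [partitionBins()]
#' @export
setClass("BinAssignment", representation(
  K = "integer",
  membership = "integer",
  pairs = "data.frame"
))

setValidity("BinAssignment", function(object) {
  msgs <- character(0)
  if (length(object@K) != 1L || object@K < 1L) msgs <- c(msgs, "K must be >= 1")
  if (length(object@membership) != nrow(object@pairs))
    msgs <- c(msgs, "membership length must equal nrow(pairs)")
  if (length(object@membership)) {
    if (any(object@membership < 1L) || any(object@membership > object@K))
      msgs <- c(msgs, "membership values must lie in 1..K")
    sizes <- tabulate(object@membership, nbins = object@K)
    if (max(sizes) - min(sizes) > 1L)
      msgs <- c(msgs, "bin sizes must differ by at most 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' ScoreTable: per-pair ensemble posteriors
#'
#' Holds the per-bin posterior probabilities for every scored pair and their
#' mean, the ensemble score used for pseudo-labeling. Under the `held_out`
#' scoring scope a pair is not scored by the model of its own bin, so that
#' column is `NA` and the mean runs over the remaining bins.
#'
#' @slot pairs data.frame of scored pairs, including the `is_spy` flag.
#' @slot binScores numeric matrix, one column per bin (NA = not scored).
#' @slot meanScore numeric vector of ensemble means in `[0, 1]`.
#'
#' @seealso [scoreEnsemble()], [meanScore()], [binScores()]
#' @export
setClass("ScoreTable", representation(
  pairs = "data.frame",
  binScores = "matrix",
  meanScore = "numeric"
))

setValidity("ScoreTable", function(object) {
  msgs <- character(0)
  n <- nrow(object@pairs)
  if (nrow(object@binScores) != n) msgs <- c(msgs, "binScores rows != pairs rows")
  if (length(object@meanScore) != n) msgs <- c(msgs, "meanScore length != pairs rows")
  if (n) {
    if (any(is.na(object@meanScore)) ||
        any(object@meanScore < 0) || any(object@meanScore > 1))
      msgs <- c(msgs, "meanScore must lie in [0, 1]")
    sc <- object@binScores[!is.na(object@binScores)]
    if (length(sc) && (any(sc < 0) || any(sc > 1)))
      msgs <- c(msgs, "bin scores must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' PseudoLabelSet: pseudo positives, pseudo negatives and the residual
#'
#' Partition of the scored non-spy unlabeled pairs into pseudo positives
#' (ensemble score above the upper threshold), pseudo negatives (below the
#' lower threshold) and the residual, which is left unlabeled and unused for
#' further training. Spy pairs are reported separately and never enter the
#' pseudo-labeled sets.
#'
#' @slot psiPos data.frame of pseudo-positive pairs (with `score`).
#' @slot psiNeg data.frame of pseudo-negative pairs.
#' @slot residual data.frame of pairs left unlabeled.
#' @slot spies data.frame of spy pairs with their ensemble scores.
#' @slot config list: the thresholding configuration that produced the set.
#'
#' @seealso [assignPseudoLabels()]
#' @export
setClass("PseudoLabelSet", representation(
  psiPos = "data.frame",
  psiNeg = "data.frame",
  residual = "data.frame",
  spies = "data.frame",
  config = "list"
))

setValidity("PseudoLabelSet", function(object) {
  keys <- c(pairKey(object@psiPos$compound_id, object@psiPos$protein_id),
            pairKey(object@psiNeg$compound_id, object@psiNeg$protein_id),
            pairKey(object@residual$compound_id, object@residual$protein_id))
  if (anyDuplicated(keys)) "psiPos/psiNeg/residual must be disjoint" else TRUE
})

#' SpyReport: the spies-capture-rate diagnostic
#'
#' The spies capture rate (SCR) is the fraction of spy pairs -- known
#' positives hidden in the unlabeled pool -- whose ensemble score exceeds the
#' capture threshold. Values near 1 indicate the ensemble recovers hidden
#' positives well.
#'
#' @slot nSpies integer, number of spies scored.
#' @slot nCaptured integer, spies scored above the capture threshold.
#' @slot scr numeric in `[0, 1]`, `nCaptured / nSpies`.
#' @slot captureThreshold numeric, score above which a spy counts as captured.
#'
#' @seealso [computeScr()]
#' @export
setClass("SpyReport", representation(
  nSpies = "integer",
  nCaptured = "integer",
  scr = "numeric",
  captureThreshold = "numeric"
))

setValidity("SpyReport", function(object) {
  msgs <- character(0)
  if (object@nSpies < 1L) msgs <- c(msgs, "nSpies must be >= 1")
  if (object@nCaptured < 0L || object@nCaptured > object@nSpies)
    msgs <- c(msgs, "nCaptured must lie in [0, nSpies]")
  if (object@scr < 0 || object@scr > 1) msgs <- c(msgs, "scr must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' BinPuFit: result of one full pseudo-labeling run
#'
#' @slot pseudoLabels [PseudoLabelSet-class] produced by the run.
#' @slot spyReport [SpyReport-class] diagnostic, or `NULL` when the run had
#'   no spies.
#' @slot scoreTable [ScoreTable-class] with all per-bin posteriors.
#' @slot manifest list of run parameters and stage cardinalities.
#'
#' @seealso [runBinPu()]
#' @export
setClass("BinPuFit", representation(
  pseudoLabels = "PseudoLabelSet",
  spyReport = "ANY",
  scoreTable = "ScoreTable",
  manifest = "list"
))

#' SyntheticWorld: a simulated interaction universe with known truth
#'
#' Compounds and proteins carry latent factors; the propensity of a pair to
#' interact is a logistic function of the latent inner product. The full
#' ground-truth interaction matrix is retained, and only a fraction of the
#' true positives is revealed as the observed positive set -- the PU setting.
#'
#' @slot compounds data.frame (`compound_id`, `smiles`).
#' @slot proteins data.frame (`protein_id`, `sequence`).
#' @slot truth integer matrix (compounds x proteins) of 0/1 true labels.
#' @slot observedPositives data.frame of revealed positive pairs.
#' @slot latentCompounds,latentProteins numeric latent-factor matrices.
#' @slot config list, the [worldConfig()] that generated the world.
#'
#' @seealso [generateWorld()], [worldToFiles()]
#' @export
setClass("SyntheticWorld", representation(
  compounds = "data.frame",
  proteins = "data.frame",
  truth = "matrix",
  observedPositives = "data.frame",
  latentCompounds = "matrix",
  latentProteins = "matrix",
  config = "list"
))

setValidity("SyntheticWorld", function(object) {
  msgs <- character(0)
  if (nrow(object@truth) != nrow(object@compounds) ||
      ncol(object@truth) != nrow(object@proteins))
    msgs <- c(msgs, "truth must be a compounds x proteins matrix")
  obs <- object@observedPositives
  if (nrow(obs)) {
    ij <- cbind(match(obs$compound_id, object@compounds$compound_id),
                match(obs$protein_id, object@proteins$protein_id))
    if (any(is.na(ij)) || any(object@truth[ij] != 1L))
      msgs <- c(msgs, "observed positives must be true positives")
  }
  if (length(msgs)) msgs else TRUE
})
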