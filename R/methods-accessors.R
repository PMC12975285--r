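# setMethod implementations for the accessor generics, plus show() methods.

#' @rdname CpiData-class
#' @export
setMethod("compounds", "CpiData", function(object) object@compounds)

#' @rdname CpiData-class
#' @export
setMethod("proteins", "CpiData", function(object) object@proteins)

#' @rdname CpiData-class
#' @export
setMethod("interactions", "CpiData", function(object) object@interactions)

#' @rdname SyntheticWorld-class
#' @export
setMethod("compounds", "SyntheticWorld", function(object) object@compounds)

#' @rdname SyntheticWorld-class
#' @export
setMethod("proteins", "SyntheticWorld", function(object) object@proteins)

#' @rdname SyntheticWorld-class
#' @export
setMethod("truthMatrix", "SyntheticWorld", function(object) object@truth)

#' @rdname SyntheticWorld-class
#' @export
setMethod("observedPositives", "SyntheticWorld",
          function(object) object@observedPositives)

#' @rdname BinAssignment-class
#' @export
setMethod("nBins", "BinAssignment", function(object) object@K)

#' @rdname BinAssignment-class
#' @export
setMethod("binSizes", "BinAssignment", function(object)
  tabulate(object@membership, nbins = object@K))

#' @rdname BinAssignment-class
#' @export
setMethod("binMembership", "BinAssignment", function(object) object@membership)

#' @rdname ScoreTable-class
#' @export
setMethod("meanScore", "ScoreTable", function(object) object@meanScore)

#' @rdname ScoreTable-class
#' @export
setMethod("binScores", "ScoreTable", function(object) object@binScores)

#' @rdname ScoreTable-class
#' @export
setMethod("scoredPairs", "ScoreTable", function(object) object@pairs)

#' @rdname PseudoLabelSet-class
#' @export
setMethod("psiPos", "PseudoLabelSet", function(object) object@psiPos)

#' @rdname PseudoLabelSet-class
#' @export
setMethod("psiNeg", "PseudoLabelSet", function(object) object@psiNeg)

#' @rdname PseudoLabelSet-class
#' @export
setMethod("residualPairs", "PseudoLabelSet", function(object) object@residual)

#' @rdname PseudoLabelSet-class
#' @export
setMethod("spyPairs", "PseudoLabelSet", function(object) object@spies)

#' @rdname SpyReport-class
#' @export
setMethod("scr", "SpyReport", function(object) object@scr)

#' @rdname BinPuFit-class
#' @export
setMethod("pseudoLabels", "BinPuFit", function(object) object@pseudoLabels)

#' @rdname BinPuFit-class
#' @export
setMethod("spyReport", "BinPuFit", function(object) object@spyReport)

#' @rdname BinPuFit-class
#' @export
setMethod("scoreTable", "BinPuFit", function(object) object@scoreTable)

#' @rdname BinPuFit-class
#' @export
setMethod("runManifest", "BinPuFit", function(object) object@manifest)

setMethod("show", "CpiData", function(object) {
  ints <- object@interactions
  cat(sprintf("CpiData: %d compounds, %d proteins, %d pairs\n",
              nrow(object@compounds), nrow(object@proteins), nrow(ints)))
  if (nrow(ints) && "label" %in% names(ints)) {
    tab <- table(factor(ints$label, levels = PAIR_LABELS))
    tab <- tab[tab > 0]
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
})

setMethod("show", "BinAssignment", function(object) {
  sizes <- binSizes(object)
  cat(sprintf("BinAssignment: %d pairs in %d bins (sizes %d..%d)\n",
              length(object@membership), object@K, min(sizes), max(sizes)))
})

setMethod("show", "ScoreTable", function(object) {
  cat(sprintf("ScoreTable: %d pairs x %d bins; mean ensemble score %.4f\n",
              nrow(object@pairs), ncol(object@binScores),
              if (nrow(object@pairs)) mean(object@meanScore) else NA_real_))
})

setMethod("show", "PseudoLabelSet", function(object) {
  cat(sprintf(
    "PseudoLabelSet: %d pseudo-positive, %d pseudo-negative, %d residual (%d spies held aside)\n",
    nrow(object@psiPos), nrow(object@psiNeg), nrow(object@residual),
    nrow(object@spies)))
})

setMethod("show", "SpyReport", function(object) {
  cat(sprintf("SpyReport: SCR = %.4f (%d/%d spies captured at threshold %.2f)\n",
              object@scr, object@nCaptured, object@nSpies,
              object@captureThreshold))
})

setMethod("show", "BinPuFit", function(object) {
  cat("BinPuFit\n")
  show(object@pseudoLabels)
  if (!is.null(object@spyReport)) show(object@spyReport)
  cat(sprintf("  K = %s, seed = %s\n",
              object@manifest$K %||% "?", object@manifest$seed %||% "?"))
})

setMethod("show", "SyntheticWorld", function(object) {
  cat(sprintf(
    "SyntheticWorld: %d compounds x %d proteins, %d true positives (%d observed)\n",
    nrow(object@compounds), nrow(object@proteins), sum(object@truth),
    nrow(object@observedPositives)))
})
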