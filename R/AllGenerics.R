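# Accessor generics. Slot access from user code is discouraged; these are
# the supported surface.

#' @rdname CpiData-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("compounds", function(object) standardGeneric("compounds"))

#' @rdname CpiData-class
#' @export
setGeneric("proteins", function(object) standardGeneric("proteins"))

#' @rdname CpiData-class
#' @export
setGeneric("interactions", function(object) standardGeneric("interactions"))

#' @rdname BinAssignment-class
#' @param object object of the documented class.
#' @export
setGeneric("nBins", function(object) standardGeneric("nBins"))

#' @rdname BinAssignment-class
#' @export
setGeneric("binSizes", function(object) standardGeneric("binSizes"))

#' @rdname BinAssignment-class
#' @export
setGeneric("binMembership", function(object) standardGeneric("binMembership"))

#' @rdname ScoreTable-class
#' @param object object of the documented class.
#' @export
setGeneric("meanScore", function(object) standardGeneric("meanScore"))

#' @rdname ScoreTable-class
#' @export
setGeneric("binScores", function(object) standardGeneric("binScores"))

#' @rdname ScoreTable-class
#' @export
setGeneric("scoredPairs", function(object) standardGeneric("scoredPairs"))

#' @rdname PseudoLabelSet-class
#' @param object object of the documented class.
#' @export
setGeneric("psiPos", function(object) standardGeneric("psiPos"))

#' @rdname PseudoLabelSet-class
#' @export
setGeneric("psiNeg", function(object) standardGeneric("psiNeg"))

#' @rdname PseudoLabelSet-class
#' @export
setGeneric("residualPairs", function(object) standardGeneric("residualPairs"))

#' @rdname PseudoLabelSet-class
#' @export
setGeneric("spyPairs", function(object) standardGeneric("spyPairs"))

#' @rdname SpyReport-class
#' @param object object of the documented class.
#' @export
setGeneric("scr", function(object) standardGeneric("scr"))

#' @rdname BinPuFit-class
#' @param object object of the documented class.
#' @export
setGeneric("pseudoLabels", function(object) standardGeneric("pseudoLabels"))

#' @rdname BinPuFit-class
#' @export
setGeneric("spyReport", function(object) standardGeneric("spyReport"))

#' @rdname BinPuFit-class
#' @export
setGeneric("scoreTable", function(object) standardGeneric("scoreTable"))

#' @rdname BinPuFit-class
#' @export
setGeneric("runManifest", function(object) standardGeneric("runManifest"))

#' @rdname SyntheticWorld-class
#' @export
setGeneric("truthMatrix", function(object) standardGeneric("truthMatrix"))

#' @rdname SyntheticWorld-class
#' @export
setGeneric("observedPositives",
           function(object) standardGeneric("observedPositives"))
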