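#' @rdname LabeledMatrix-class
#' @param x a \linkS4class{LabeledMatrix}.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname LabeledMatrix-class
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname LabeledMatrix-class
#' @export
setGeneric("plantedFeatures", function(x) standardGeneric("plantedFeatures"))

#' @rdname NMFFactors-class
#' @param x an \linkS4class{NMFFactors}.
#' @export
setGeneric("basisMatrix", function(x) standardGeneric("basisMatrix"))

#' @rdname NMFFactors-class
#' @export
setGeneric("coefMatrix", function(x) standardGeneric("coefMatrix"))

#' @rdname NMFFactors-class
#' @export
setGeneric("objectiveHistory", function(x) standardGeneric("objectiveHistory"))

#' @rdname FeatureWeights-class
#' @param x a \linkS4class{FeatureWeights}.
#' @export
setGeneric("featureWeights", function(x) standardGeneric("featureWeights"))

#' @rdname SelectionResult-class
#' @param x a \linkS4class{SelectionResult}.
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @rdname SelectionResult-class
#' @export
setGeneric("selectionScores", function(x) standardGeneric("selectionScores"))

#' @rdname SelectionResult-class
#' @export
setGeneric("selectionMethod", function(x) standardGeneric("selectionMethod"))

#' @rdname GeneFamilyMatrix-class
#' @param x a \linkS4class{GeneFamilyMatrix}.
#' @export
setGeneric("familyCounts", function(x) standardGeneric("familyCounts"))

#' @rdname GeneFamilyMatrix-class
#' @export
setGeneric("speciesIds", function(x) standardGeneric("speciesIds"))

#' @rdname GeneFamilyMatrix-class
#' @export
setGeneric("familyIds", function(x) standardGeneric("familyIds"))

#' @rdname GeneFamilyMatrix-class
#' @param ... passed on to methods.
#' @export
setGeneric("asLabeledMatrix", function(x, ...) standardGeneric("asLabeledMatrix"))

#' @rdname EvalReport-class
#' @param x an \linkS4class{EvalReport}.
#' @export
setGeneric("foldMetrics", function(x) standardGeneric("foldMetrics"))

#' @rdname EvalReport-class
#' @export
setGeneric("metricSummary", function(x) standardGeneric("metricSummary"))
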