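#' @rdname LabeledMatrix-class
#' @export
setMethod("featureMatrix", "LabeledMatrix", function(x)
    SummarizedExperiment::assay(x, "values"))

#' @rdname LabeledMatrix-class
#' @export
setMethod("sampleLabels", "LabeledMatrix", function(x)
    colData(x)$label)

#' @rdname LabeledMatrix-class
#' @export
setMethod("plantedFeatures", "LabeledMatrix", function(x)
    metadata(x)$planted)

setMethod("show", "LabeledMatrix", function(object) {
    cat("LabeledMatrix:", nrow(object), "features x", ncol(object),
        "samples\n")
    cat("labels:", paste(sprintf("%s(%d)", levels(sampleLabels(object)),
        tabulate(sampleLabels(object))), collapse = " "), "\n")
    if (!is.null(metadata(object)$planted))
        cat("planted informative features:",
            length(metadata(object)$planted), "\n")
})

#' @rdname NMFFactors-class
#' @export
setMethod("basisMatrix", "NMFFactors", function(x) x@W)

#' @rdname NMFFactors-class
#' @export
setMethod("coefMatrix", "NMFFactors", function(x) x@H)

#' @rdname NMFFactors-class
#' @export
setMethod("objectiveHistory", "NMFFactors", function(x) x@objectiveHistory)

setMethod("show", "NMFFactors", function(object) {
    cat("NMFFactors: rank", object@rank, "|", nrow(object@W), "features x",
        ncol(object@H), "samples\n")
    cat(sprintf("  %d iterations, final Frobenius error %.6g\n",
        object@iterationsRun, utils::tail(object@objectiveHistory, 1)))
})

#' @rdname FeatureWeights-class
#' @export
setMethod("featureWeights", "FeatureWeights", function(x) x@weights)

setMethod("show", "FeatureWeights", function(object) {
    cat("FeatureWeights:", length(object@weights), "features, k =",
        object@k, "\n")
    top <- utils::head(order(-object@weights), 5)
    cat("  top:", paste(sprintf("%s=%.4f", names(object@weights)[top],
        object@weights[top]), collapse = " "), "\n")
})

#' @rdname SelectionResult-class
#' @export
setMethod("selectedFeatures", "SelectionResult", function(x) x@selected)

#' @rdname SelectionResult-class
#' @export
setMethod("selectionScores", "SelectionResult", function(x) x@scores)

#' @rdname SelectionResult-class
#' @export
setMethod("selectionMethod", "SelectionResult", function(x) x@method)

setMethod("show", "SelectionResult", function(object) {
    cat("SelectionResult [", object@method, "]: ",
        length(object@selected), " features\n", sep = "")
    n <- min(5L, length(object@selected))
    cat("  top:", paste(sprintf("%s=%.4g", object@featureIds[seq_len(n)],
        object@scores[seq_len(n)]), collapse = " "), "\n")
})

#' @rdname GeneFamilyMatrix-class
#' @export
setMethod("familyCounts", "GeneFamilyMatrix", function(x) x@counts)

#' @rdname GeneFamilyMatrix-class
#' @export
setMethod("speciesIds", "GeneFamilyMatrix", function(x) rownames(x@counts))

#' @rdname GeneFamilyMatrix-class
#' @export
setMethod("familyIds", "GeneFamilyMatrix", function(x) colnames(x@counts))

setMethod("show", "GeneFamilyMatrix", function(object) {
    cat("GeneFamilyMatrix:", nrow(object@counts), "species x",
        ncol(object@counts), "families,",
        sum(object@counts), "assigned genes\n")
})

#' Convert a species-by-family matrix to a LabeledMatrix
#'
#' Transposes the counts (families become features, species become samples)
#' and attaches the per-species labels.
#'
#' @param x a \linkS4class{GeneFamilyMatrix}.
#' @param labels class label per species; defaults to labels stored in
#'   \code{x}, which must then be present.
#' @return a \linkS4class{LabeledMatrix} (families x species).
#' @export
setMethod("asLabeledMatrix", "GeneFamilyMatrix", function(x, labels = NULL) {
    if (is.null(labels)) {
        if (length(x@labels) == 0L)
            stop("no labels stored in the GeneFamilyMatrix; supply 'labels'")
        labels <- x@labels
    }
    LabeledMatrix(t(x@counts), labels)
})

#' @rdname EvalReport-class
#' @export
setMethod("foldMetrics", "EvalReport", function(x) x@perFold)

#' @rdname EvalReport-class
#' @export
setMethod("metricSummary", "EvalReport", function(x) x@metricSummary)

setMethod("show", "EvalReport", function(object) {
    cat("EvalReport:", object@classifier, "classifier,",
        object@nFolds, "folds x", object@nRepeats, "repeats",
        sprintf("(metric convention: %s)\n", object@metricConvention))
    s <- object@metricSummary
    for (i in seq_len(nrow(s)))
        cat(sprintf("  %s = %.4f (SE %.4f)\n", s$metric[i], s$mean[i],
            s$se[i]))
})
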