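#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' Labeled nonnegative feature matrix
#'
#' A \linkS4class{SummarizedExperiment} holding one assay \code{"values"}
#' (features in rows, samples in columns) and a per-sample class label in
#' \code{colData(x)$label}. This is the container every selector and the
#' evaluation harness consume. Entries must be finite; nonnegativity is
#' required (and checked) by the NMF-based routines, not by the class itself,
#' so that shifted microarray-style data can still flow through the
#' ReliefF/PCA/SVM-RFE baselines.
#'
#' @slot . inherits all slots from \code{SummarizedExperiment}.
#' @export
setClass("LabeledMatrix", contains = "SummarizedExperiment")

setValidity("LabeledMatrix", function(object) {
    msg <- NULL
    if (!"values" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'values' is required")
    else {
        v <- SummarizedExperiment::assay(object, "values")
        if (!is.numeric(v))
            msg <- c(msg, "assay 'values' must be numeric")
        else if (any(!is.finite(v)))
            msg <- c(msg, "assay 'values' must be finite (no NA/NaN/Inf)")
        if (nrow(object) < 1L || ncol(object) < 1L)
            msg <- c(msg, "at least one feature and one sample are required")
    }
    if (!"label" %in% colnames(colData(object)))
        msg <- c(msg, "colData column 'label' is required")
    else if (anyNA(colData(object)$label))
        msg <- c(msg, "sample labels must not contain NA")
    if (is.null(msg)) TRUE else msg
})

#' Construct a LabeledMatrix
#'
#' @param values numeric matrix, features x samples. Row and column names, if
#'   absent, are filled in as \code{f1..fm} and \code{s1..sn}.
#' @param labels class label per sample (coerced to factor), length
#'   \code{ncol(values)}.
#' @return a \linkS4class{LabeledMatrix}.
#' @examples
#' lm <- LabeledMatrix(matrix(rpois(20, 5), 4, 5), rep(c("a", "b"), c(2, 3)))
#' sampleLabels(lm)
#' @export
LabeledMatrix <- function(values, labels) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (is.null(rownames(values)))
        rownames(values) <- paste0("f", seq_len(nrow(values)))
    if (is.null(colnames(values)))
        colnames(values) <- paste0("s", seq_len(ncol(values)))
    labels <- as.factor(labels)
    if (length(labels) != ncol(values))
        stop("length(labels) [", length(labels), "] must equal the number ",
             "of samples [", ncol(values), "]")
    se <- SummarizedExperiment(
        assays = list(values = values),
        colData = DataFrame(label = labels, row.names = colnames(values)))
    new("LabeledMatrix", se)
}

#' Species-by-family copy-number matrix
#'
#' Integer counts of gene-family members, one row per species, one column per
#' family, as tallied from a gene-to-family assignment table. Row sums equal
#' the number of assigned genes per species. Optional class labels (one per
#' species) travel with the matrix so it can be converted to a
#' \linkS4class{LabeledMatrix} for selection.
#'
#' @slot counts integer matrix, species x families, all entries >= 0.
#' @slot labels character vector of per-species class labels (length 0 when
#'   unlabeled).
#' @export
setClass("GeneFamilyMatrix",
    representation(counts = "matrix", labels = "character"))

setValidity("GeneFamilyMatrix", function(object) {
    msg <- NULL
    cts <- object@counts
    if (!is.numeric(cts) || any(cts < 0) || any(cts != round(cts)))
        msg <- c(msg, "counts must be nonnegative integers")
    if (is.null(rownames(cts)) || is.null(colnames(cts)))
        msg <- c(msg, "counts must have species rownames and family colnames")
    if (length(object@labels) > 0L && length(object@labels) != nrow(cts))
        msg <- c(msg, "labels must be empty or one per species")
    if (is.null(msg)) TRUE else msg
})

#' NMF factor pair with convergence history
#'
#' Result of multiplicative-update nonnegative matrix factorization
#' V ~ WH: the basis \code{W} (features x rank, columns are metagenes), the
#' encoding \code{H} (rank x samples), and the Frobenius reconstruction error
#' recorded after every iteration.
#'
#' @slot W nonnegative basis matrix, features x rank.
#' @slot H nonnegative coefficient matrix, rank x samples.
#' @slot rank integer factorization rank.
#' @slot objectiveHistory Frobenius error \eqn{\|V - WH\|_F} per iteration
#'   (non-increasing up to numerical slack).
#' @slot iterationsRun number of update iterations performed.
#' @slot seed integer seed used for the uniform-random initialization.
#' @export
setClass("NMFFactors",
    representation(W = "matrix", H = "matrix", rank = "integer",
                   objectiveHistory = "numeric", iterationsRun = "integer",
                   seed = "integer"))

setValidity("NMFFactors", function(object) {
    msg <- NULL
    if (any(object@W < 0) || any(object@H < 0))
        msg <- c(msg, "W and H must be nonnegative")
    if (ncol(object@W) != object@rank || nrow(object@H) != object@rank)
        msg <- c(msg, "inner dimensions of W and H must equal the rank")
    if (is.null(msg)) TRUE else msg
})

#' Relief-family feature weights
#'
#' One real weight per feature from ReliefF scoring. With min-max-normalized
#' feature differences every weight lies in [-1, 1]; larger means the feature
#' separates near misses (other classes) better than it splits near hits
#' (same class).
#'
#' @slot weights named numeric vector, one weight per feature.
#' @slot k number of neighbors per class used.
#' @slot nIterations number of instances actually sampled.
#' @slot seed integer seed (only consequential when subsampling instances).
#' @export
setClass("FeatureWeights",
    representation(weights = "numeric", k = "integer", nIterations = "integer",
                   seed = "integer"))

setValidity("FeatureWeights", function(object) {
    if (any(!is.finite(object@weights)))
        "weights must be finite" else TRUE
})

#' Ordered feature-selection result
#'
#' Selected feature indices in decreasing-score order, with the scores, the
#' method and parameters that produced them, and (for factor-space methods)
#' the ReliefF weights of the latent components.
#'
#' @slot method one of \code{"nmf_relieff"}, \code{"relieff"},
#'   \code{"pca_relieff"}, \code{"svm_rfe"}.
#' @slot selected integer indices into the input feature space (or component
#'   space for \code{mode = "component"} / PCA-ReliefF).
#' @slot featureIds identifiers of the selected features, same order.
#' @slot scores numeric score per selected feature, non-increasing.
#' @slot params list of the parameters used (rank, k, nSelect, mode, seed, ...).
#' @slot componentWeights ReliefF weights of the latent components (length 0
#'   for methods that operate directly on features).
#' @export
setClass("SelectionResult",
    representation(method = "character", selected = "integer",
                   featureIds = "character", scores = "numeric",
                   params = "list", componentWeights = "numeric"))

setValidity("SelectionResult", function(object) {
    msg <- NULL
    if (!object@method %in% c("nmf_relieff", "relieff", "pca_relieff",
                              "svm_rfe"))
        msg <- c(msg, "unknown method")
    if (anyDuplicated(object@selected))
        msg <- c(msg, "selected indices must be unique")
    if (length(object@scores) != length(object@selected))
        msg <- c(msg, "one score per selected feature required")
    if (is.null(msg)) TRUE else msg
})

#' Cross-validation evaluation report
#'
#' Per-fold confusion counts and metrics (ACC/SEN/SPE/AUC) from repeated
#' stratified k-fold cross-validation, plus their mean and standard error
#' across folds x repeats.
#'
#' @slot perFold data.frame with one row per (repeat, fold): confusion counts
#'   TP/TN/FP/FN and the four metrics.
#' @slot metricSummary data.frame with one row per metric: mean and standard
#'   error over all folds and repeats.
#' @slot classifier one of \code{"svm"}, \code{"rf"}, \code{"knn"}.
#' @slot nFolds,nRepeats cross-validation layout.
#' @slot seed integer seed governing fold shuffling and classifier randomness.
#' @slot metricConvention \code{"standard"} or \code{"as_printed"} (see
#'   \code{\link{computeMetrics}}).
#' @export
setClass("EvalReport",
    representation(perFold = "data.frame", metricSummary = "data.frame",
                   classifier = "character", nFolds = "integer",
                   nRepeats = "integer", seed = "integer",
                   metricConvention = "character"))
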