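# Plain-text interchange: everything is tab-separated, one header line.
# The matrix layout is shared by GeneFamilyMatrix and LabeledMatrix:
#   species_id [<tab> label] <tab> fam1 <tab> fam2 ...
# one row per sample/species, so a labeled gene-family table round-trips
# directly into the selectors.

#' Read an assembly-stats table
#'
#' @param path TSV with header \code{species_id<tab>scaffold_n50}.
#' @return data.frame ready for \code{\link{filterAssemblies}}.
#' @export
readAssemblyStats <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("species_id", "scaffold_n50") %in% names(df)))
        stop("expected columns species_id and scaffold_n50 in ", path)
    df
}

#' Read a gene-to-family assignment table
#'
#' @param path TSV with header
#'   \code{species_id<tab>gene_id<tab>family_id}.
#' @return data.frame ready for \code{\link{buildFamilyMatrix}}.
#' @export
readFamilyAssignments <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("species_id", "gene_id", "family_id") %in% names(df)))
        stop("expected columns species_id, gene_id, family_id in ", path)
    df
}

#' Write a GeneFamilyMatrix as TSV
#'
#' First column \code{species_id}, then \code{label} when labels are stored,
#' then one integer column per family.
#'
#' @param x a \linkS4class{GeneFamilyMatrix}.
#' @param path output file.
#' @export
writeFamilyMatrix <- function(x, path) {
    stopifnot(is(x, "GeneFamilyMatrix"))
    df <- data.frame(species_id = speciesIds(x), stringsAsFactors = FALSE)
    if (length(x@labels) > 0L) df$label <- x@labels
    df <- cbind(df, as.data.frame(familyCounts(x)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a labeled matrix from TSV
#'
#' Reads the sample-per-row layout written by
#' \code{\link{writeFamilyMatrix}} / \code{\link{writeLabeledMatrix}} (first
#' column sample id, \code{label} column required, remaining columns one per
#' feature) and transposes it into the features-x-samples
#' \linkS4class{LabeledMatrix} the selectors consume.
#'
#' @param path input TSV.
#' @return a \linkS4class{LabeledMatrix}.
#' @export
readLabeledMatrix <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    if (ncol(df) < 3L || !"label" %in% names(df))
        stop("expected <id> <label> <feature...> columns in ", path)
    ids <- df[[1]]
    labels <- df$label
    feat <- df[, setdiff(names(df), c(names(df)[1], "label")),
               drop = FALSE]
    V <- t(as.matrix(feat))
    colnames(V) <- ids
    LabeledMatrix(V, labels)
}

#' Write a LabeledMatrix as TSV
#'
#' Inverse of \code{\link{readLabeledMatrix}}: samples in rows, features in
#' columns.
#'
#' @param x a \linkS4class{LabeledMatrix}.
#' @param path output file.
#' @export
writeLabeledMatrix <- function(x, path) {
    stopifnot(is(x, "LabeledMatrix"))
    df <- data.frame(sample_id = colnames(x),
                     label = as.character(sampleLabels(x)),
                     stringsAsFactors = FALSE, check.names = FALSE)
    df <- cbind(df, as.data.frame(t(featureMatrix(x)), check.names = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write feature weights as TSV
#'
#' Columns \code{feature_id}, \code{weight}, \code{rank} (1 = largest
#' weight; ties ranked by ascending feature index).
#'
#' @param x a \linkS4class{FeatureWeights}.
#' @param path output file.
#' @export
writeWeights <- function(x, path) {
    stopifnot(is(x, "FeatureWeights"))
    w <- featureWeights(x)
    ord <- order(-w, seq_along(w))
    rk <- integer(length(w)); rk[ord] <- seq_along(w)
    df <- data.frame(feature_id = names(w), weight = w, rank = rk,
                     row.names = NULL)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a selection as TSV
#'
#' Columns \code{rank}, \code{feature_id}, \code{score}.
#'
#' @param x a \linkS4class{SelectionResult}.
#' @param path output file.
#' @export
writeSelection <- function(x, path) {
    stopifnot(is(x, "SelectionResult"))
    df <- data.frame(rank = seq_along(x@selected),
                     feature_id = x@featureIds, score = x@scores)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write an evaluation report
#'
#' \code{path} gets the TSV summary
#' (\code{classifier, metric, mean, se}); with \code{jsonPath}, the full
#' per-fold table and parameters are written as JSON as well.
#'
#' @param x an \linkS4class{EvalReport}.
#' @param path summary TSV path.
#' @param jsonPath optional full-report JSON path.
#' @export
writeEvalReport <- function(x, path, jsonPath = NULL) {
    stopifnot(is(x, "EvalReport"))
    s <- metricSummary(x)
    df <- cbind(classifier = x@classifier, s)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(jsonPath)) {
        jsonlite::write_json(list(
            classifier = x@classifier, n_folds = x@nFolds,
            n_repeats = x@nRepeats, seed = x@seed,
            metric_convention = x@metricConvention,
            summary = s, per_fold = foldMetrics(x)),
            jsonPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    invisible(path)
}
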