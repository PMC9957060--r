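#' Sweep feature counts across selectors
#'
#' Runs the cross-validated pipeline for every combination of selection
#' method, selected-feature count n and classifier, and tabulates mean and
#' standard error of ACC/SEN/SPE/AUC over folds x repeats. The default grid
#' — n in \{5, 10, 20, 30, 40, 50\}, 15 repeats of five-fold CV — is the
#' standard layout for judging how many features a selector needs before
#' the classifier stops being underfit. Selection is re-fit inside every
#' training fold. A failing combination is recorded in its row's
#' \code{error} column and the sweep continues.
#'
#' @param data a \linkS4class{LabeledMatrix} with 2 classes.
#' @param methods selection methods to compare (subset of
#'   \code{"nmf_relieff"}, \code{"relieff"}, \code{"pca_relieff"},
#'   \code{"svm_rfe"}).
#' @param nValues numbers of selected features to try.
#' @param classifiers classifiers to evaluate (default \code{"svm"}).
#' @param nFolds,nRepeats cross-validation layout (defaults 5 and 15).
#' @param seed integer seed; each combination derives its folds from it.
#' @param rank,k NMF rank and ReliefF neighbor count forwarded to the
#'   selectors (\code{NULL} = their defaults).
#' @return data.frame with one row per (method, n, classifier):
#'   \code{mean_*} and \code{se_*} for the four metrics, and \code{error}
#'   (\code{NA} on success).
#' @export
runSweep <- function(data,
                     methods = c("nmf_relieff", "relieff", "pca_relieff",
                                 "svm_rfe"),
                     nValues = c(5L, 10L, 20L, 30L, 40L, 50L),
                     classifiers = "svm", nFolds = 5L, nRepeats = 15L,
                     seed = 1L, rank = NULL, k = NULL) {
    stopifnot(is(data, "LabeledMatrix"))
    if (length(methods) == 0L)
        return(data.frame(method = character(0), n = integer(0),
                          classifier = character(0)))
    methods <- match.arg(methods, several.ok = TRUE)
    if (any(nValues < 1L | nValues > nrow(data)))
        stop("nValues must lie within [1, ", nrow(data), "]")
    rows <- list()
    for (method in methods) for (n in nValues) for (clf in classifiers) {
        res <- tryCatch({
            spec <- switch(method,
                nmf_relieff = selectorSpec("nmf_relieff", nSelect = n,
                    rank = rank, k = k, mode = "gene"),
                relieff = selectorSpec("relieff", nSelect = n, k = k),
                pca_relieff = selectorSpec("pca_relieff", nSelect = n,
                    nComponents = max(n, min(dim(data)) - 1L), k = k),
                svm_rfe = selectorSpec("svm_rfe", nSelect = n))
            rep <- crossValidate(data, selector = spec, classifier = clf,
                                 nFolds = nFolds, nRepeats = nRepeats,
                                 seed = seed)
            s <- metricSummary(rep)
            stats::setNames(c(s$mean, s$se),
                c(paste0("mean_", s$metric), paste0("se_", s$metric)))
        }, error = function(e) e)
        row <- data.frame(method = method, n = n, classifier = clf,
                          mean_ACC = NA_real_, mean_SEN = NA_real_,
                          mean_SPE = NA_real_, mean_AUC = NA_real_,
                          se_ACC = NA_real_, se_SEN = NA_real_,
                          se_SPE = NA_real_, se_AUC = NA_real_,
                          error = NA_character_, stringsAsFactors = FALSE)
        if (inherits(res, "error")) {
            row$error <- conditionMessage(res)
        } else {
            row[names(res)] <- res
        }
        rows[[length(rows) + 1L]] <- row
    }
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    if (is.null(out)) out <- data.frame()
    out
}
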