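#' NMF-ReliefF feature selection
#'
#' The combined selector: the nonnegative matrix \eqn{V} (features x samples)
#' is factorized as \eqn{V \approx WH} by multiplicative updates
#' (\code{\link{nmfFactorize}}), the r metagene encodings (rows of \eqn{H},
#' one value per sample) are scored with ReliefF against the class labels,
#' and features are returned in one of two modes:
#' \describe{
#'   \item{\code{mode = "gene"}}{component weights are mapped back to the
#'     original features by
#'     \eqn{score(f) = \sum_j \max(w_j, 0)\, W_{fj} / \|W_{\cdot j}\|_1},
#'     i.e. each discriminative metagene distributes its (positive) ReliefF
#'     weight over the features composing it, proportionally to their share
#'     of the metagene. The top \code{nSelect} original features are
#'     returned — this is the mode that names gene families.}
#'   \item{\code{mode = "component"}}{the top \code{nSelect} metagene indices
#'     themselves are returned (requires \code{rank >= nSelect}).}
#' }
#'
#' @param data a \linkS4class{LabeledMatrix}; all entries must be >= 0.
#' @param rank NMF rank r; default \code{min(50, min(m, n) - 1)}.
#' @param k ReliefF neighbor count (see \code{\link{relieffWeights}}).
#' @param nSelect number of features (or components) to return.
#' @param mode \code{"gene"} (default) or \code{"component"}.
#' @param seed integer seed (NMF initialization; ReliefF full pass is
#'   deterministic).
#' @param maxIter,tol passed to \code{\link{nmfFactorize}}.
#' @return a \linkS4class{SelectionResult} with method \code{"nmf_relieff"};
#'   \code{x@componentWeights} holds the per-metagene ReliefF weights.
#' @examples
#' sim <- simulatePlantedMatrix(50, 40, nInformative = 2, effectSize = 6,
#'                              seed = 7)
#' sel <- nmfRelieffSelect(sim, rank = 5, nSelect = 2, seed = 7)
#' selectedFeatures(sel)    # recovers plantedFeatures(sim)
#' @export
nmfRelieffSelect <- function(data, rank = NULL, k = NULL, nSelect,
                             mode = c("gene", "component"), seed = 1L,
                             maxIter = 500L, tol = 1e-6) {
    mode <- match.arg(mode)
    ml <- asMatrixLabels(data)
    V <- ml$V
    checkNonnegative(V, context = "NMF-ReliefF")
    m <- nrow(V); n <- ncol(V)
    if (is.null(rank)) rank <- min(50L, min(m, n) - 1L)
    rank <- as.integer(rank)
    nSelect <- as.integer(nSelect)
    if (mode == "component" && rank < nSelect)
        stop("component mode needs rank >= nSelect (rank = ", rank,
             ", nSelect = ", nSelect, ")")
    if (mode == "gene" && (nSelect < 1L || nSelect > m))
        stop("nSelect must be in [1, ", m, "]")

    fct <- nmfFactorize(V, rank = rank, maxIter = maxIter, tol = tol,
                        seed = seed)
    H <- coefMatrix(fct)
    rownames(H) <- paste0("C", seq_len(rank))
    compW <- featureWeights(relieffWeights(LabeledMatrix(H, ml$labels),
                                           k = k, seed = seed))
    params <- list(rank = rank, k = k, nSelect = nSelect, mode = mode,
                   seed = as.integer(seed))

    if (mode == "component") {
        ord <- order(-compW, seq_along(compW))[seq_len(nSelect)]
        new("SelectionResult", method = "nmf_relieff",
            selected = as.integer(ord), featureIds = names(compW)[ord],
            scores = unname(compW[ord]), params = params,
            componentWeights = unname(compW))
    } else {
        W <- basisMatrix(fct)
        wpos <- pmax(compW, 0)
        l1 <- colSums(W)
        contrib <- ifelse(l1 > 0, wpos / l1, 0)
        score <- as.numeric(W %*% contrib)
        ord <- order(-score, seq_along(score))[seq_len(nSelect)]
        ids <- rownames(V)[ord]
        if (is.null(ids)) ids <- as.character(ord)
        new("SelectionResult", method = "nmf_relieff",
            selected = as.integer(ord), featureIds = ids,
            scores = score[ord], params = params,
            componentWeights = unname(compW))
    }
}

#' PCA-ReliefF feature selection
#'
#' Samples are projected onto the leading principal components of the
#' (column-centered) data; the component scores are then ReliefF-ranked
#' against the class labels and the top \code{nSelect} components are
#' returned. Components are ordered by explained variance, and each
#' component's sign is fixed so that its largest-magnitude loading is
#' positive.
#'
#' @param data a \linkS4class{LabeledMatrix} (negative entries allowed).
#' @param nComponents number of principal components to keep,
#'   \code{<= min(m, n)}.
#' @param k ReliefF neighbor count.
#' @param nSelect number of components to return, \code{<= nComponents}.
#' @param seed integer seed (recorded; the procedure is deterministic).
#' @return a \linkS4class{SelectionResult} with method \code{"pca_relieff"};
#'   \code{selected} indexes components, not original features.
#' @export
pcaRelieffSelect <- function(data, nComponents, k = NULL, nSelect,
                             seed = 1L) {
    ml <- asMatrixLabels(data)
    V <- ml$V
    m <- nrow(V); n <- ncol(V)
    nComponents <- as.integer(nComponents)
    nSelect <- as.integer(nSelect)
    if (nComponents < 1L || nComponents > min(m, n))
        stop("nComponents must be in [1, min(", m, ", ", n, ")]")
    if (nSelect < 1L || nSelect > nComponents)
        stop("nSelect must be in [1, nComponents = ", nComponents, "]")

    pc <- stats::prcomp(t(V), center = TRUE, scale. = FALSE)
    rot <- pc$rotation[, seq_len(nComponents), drop = FALSE]
    sco <- pc$x[, seq_len(nComponents), drop = FALSE]
    for (j in seq_len(nComponents)) {           # sign: top loading positive
        top <- which.max(abs(rot[, j]))
        if (rot[top, j] < 0) {
            rot[, j] <- -rot[, j]
            sco[, j] <- -sco[, j]
        }
    }
    comp <- t(sco)                              # components x samples
    rownames(comp) <- paste0("PC", seq_len(nComponents))
    w <- featureWeights(relieffWeights(LabeledMatrix(comp, ml$labels),
                                       k = k, seed = seed))
    ord <- order(-w, seq_along(w))[seq_len(nSelect)]
    new("SelectionResult", method = "pca_relieff",
        selected = as.integer(ord), featureIds = names(w)[ord],
        scores = unname(w[ord]),
        params = list(nComponents = nComponents, k = k, nSelect = nSelect,
                      seed = as.integer(seed)),
        componentWeights = unname(w))
}

# linear SVM primal weights from an e1071 fit: w = t(coefs) %*% SV
svmLinearWeights <- function(X, y) {
    fit <- e1071::svm(x = X, y = y, kernel = "linear", cost = 1,
                      scale = FALSE)
    as.numeric(t(fit$coefs) %*% fit$SV)
}

# mutual information (nats) between two discrete vectors
discreteMI <- function(a, b) {
    tab <- table(a, b)
    p <- tab / sum(tab)
    px <- rowSums(p); py <- colSums(p)
    nz <- p > 0
    sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

# 3 equal-frequency bins per feature (rows of V)
discretizeRows <- function(V, bins = 3L) {
    t(apply(V, 1L, function(x) {
        br <- unique(stats::quantile(x, probs = seq(0, 1, length.out =
            bins + 1L), names = FALSE, type = 7))
        if (length(br) < 2L) return(rep(1L, length(x)))
        findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
    }))
}

#' SVM-RFE feature selection
#'
#' Backward elimination guided by a linear maximum-margin classifier: a
#' linear SVM (C = 1) is trained on min-max scaled features and the
#' \code{step} features with the smallest squared weights are removed, until
#' \code{nSelect} remain. Surviving features are ranked by their squared
#' weight in the final fit.
#'
#' With \code{useMrmr = TRUE}, features are pre-ranked by a minimum-redundancy
#' maximum-relevance filter — mutual information with the label minus the mean
#' mutual information with the other features, computed on 3 equal-frequency
#' bins — and the bottom half is dropped before elimination begins.
#'
#' @param data a \linkS4class{LabeledMatrix} with exactly 2 classes.
#' @param nSelect number of features to retain.
#' @param step features removed per elimination round (default 1).
#' @param useMrmr drop the least mRMR-relevant half before RFE.
#' @param seed integer seed (recorded; the procedure is deterministic).
#' @return a \linkS4class{SelectionResult} with method \code{"svm_rfe"}.
#' @export
svmRfeSelect <- function(data, nSelect, step = 1L, useMrmr = FALSE,
                         seed = 1L) {
    ml <- asMatrixLabels(data)
    V <- ml$V
    labels <- droplevels(as.factor(ml$labels))
    if (nlevels(labels) != 2L)
        stop("SVM-RFE is a binary selector; got ", nlevels(labels),
             " classes")
    m <- nrow(V)
    nSelect <- as.integer(nSelect)
    step <- as.integer(step)
    if (nSelect < 1L || nSelect > m) stop("nSelect must be in [1, ", m, "]")
    if (step < 1L) stop("step must be >= 1")

    Xn <- minmaxRows(V)
    remaining <- seq_len(m)
    if (useMrmr && length(remaining) > nSelect) {
        disc <- discretizeRows(Xn)
        rel <- apply(disc, 1L, discreteMI, b = labels)
        nFeat <- length(remaining)
        red <- numeric(nFeat)
        if (nFeat > 1L) {
            mi <- matrix(0, nFeat, nFeat)
            for (i in seq_len(nFeat - 1L)) for (j in seq(i + 1L, nFeat)) {
                mi[i, j] <- mi[j, i] <- discreteMI(disc[i, ], disc[j, ])
            }
            red <- rowSums(mi) / (nFeat - 1L)
        }
        mrmr <- rel - red
        keep <- max(ceiling(nFeat / 2), nSelect)
        remaining <- sort(order(-mrmr, seq_len(nFeat))[seq_len(keep)])
    }

    while (length(remaining) > nSelect) {
        w <- svmLinearWeights(t(Xn[remaining, , drop = FALSE]), labels)
        nDrop <- min(step, length(remaining) - nSelect)
        drop <- order(w^2, seq_along(remaining))[seq_len(nDrop)]
        remaining <- remaining[-drop]
    }
    w <- svmLinearWeights(t(Xn[remaining, , drop = FALSE]), labels)
    ord <- order(-(w^2), seq_along(remaining))
    sel <- remaining[ord]
    ids <- rownames(V)[sel]
    if (is.null(ids)) ids <- as.character(sel)
    new("SelectionResult", method = "svm_rfe", selected = as.integer(sel),
        featureIds = ids, scores = (w^2)[ord],
        params = list(nSelect = nSelect, step = step, useMrmr = useMrmr,
                      seed = as.integer(seed)),
        componentWeights = numeric(0))
}

#' Declarative selector specification
#'
#' Describes a selector to be (re-)fit inside each cross-validation training
#' fold by \code{\link{crossValidate}} or \code{\link{runSweep}}, so that
#' feature selection never sees held-out samples.
#'
#' @param method one of \code{"nmf_relieff"}, \code{"relieff"},
#'   \code{"pca_relieff"}, \code{"svm_rfe"}.
#' @param nSelect number of features/components to select.
#' @param ... method parameters (\code{rank}, \code{k}, \code{mode},
#'   \code{nComponents}, \code{step}, \code{useMrmr}).
#' @return an object of class \code{"selectorSpec"}.
#' @export
selectorSpec <- function(method = c("nmf_relieff", "relieff", "pca_relieff",
                                    "svm_rfe"), nSelect, ...) {
    method <- match.arg(method)
    structure(list(method = method, nSelect = as.integer(nSelect),
                   args = list(...)), class = "selectorSpec")
}

# run a selectorSpec on training data; returns a SelectionResult
fitSelector <- function(spec, data, seed) {
    stopifnot(inherits(spec, "selectorSpec"))
    args <- c(list(data = data, nSelect = spec$nSelect, seed = seed),
              spec$args)
    fun <- switch(spec$method,
        nmf_relieff = nmfRelieffSelect,
        relieff = relieffSelect,
        pca_relieff = pcaRelieffSelect,
        svm_rfe = svmRfeSelect)
    do.call(fun, args)
}

#' Reduce a LabeledMatrix to selected features
#'
#' For feature-space selections (\code{relieff}, \code{svm_rfe},
#' \code{nmf_relieff} gene mode) rows of the original matrix are subset; for
#' component-space selections the samples are re-expressed in the selected
#' latent directions is not attempted — component selections are applied by
#' the evaluator through the selector's own transform.
#'
#' @param data a \linkS4class{LabeledMatrix}.
#' @param selection a \linkS4class{SelectionResult} indexing features of
#'   \code{data}.
#' @return a \linkS4class{LabeledMatrix} with the selected rows, in selection
#'   order.
#' @export
applySelection <- function(data, selection) {
    stopifnot(is(data, "LabeledMatrix"), is(selection, "SelectionResult"))
    idx <- selection@selected
    if (any(idx < 1L | idx > nrow(data)))
        stop("selection indices fall outside the feature range of 'data'")
    LabeledMatrix(featureMatrix(data)[idx, , drop = FALSE],
                  sampleLabels(data))
}
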