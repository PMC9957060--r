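#' Confusion counts, ACC/SEN/SPE and pairwise AUC
#'
#' Thresholds decision scores into class predictions (score strictly greater
#' than \code{threshold} predicts the positive class), tallies the confusion
#' table, and computes
#' \deqn{ACC = \frac{TP + TN}{TP + TN + FN + FP}}
#' and the rank-based AUC as the pairwise concordance statistic
#' \deqn{AUC = \frac{\#\{(i,j): s_i^{+} > s_j^{-}\} + \tfrac12
#'   \#\{ties\}}{n_{+} \cdot n_{-}}.}
#'
#' Two conventions for sensitivity/specificity are available:
#' \code{"standard"} gives the usual \eqn{SEN = TP/(TP+FN)} (recall) and
#' \eqn{SPE = TN/(TN+FP)}; \code{"as_printed"} gives \eqn{SEN = TP/(TP+FP)}
#' and \eqn{SPE = TP/(TP+FN)} — a nonstandard pairing (precision and recall)
#' that some published tables use. The two agree whenever FP = FN. Empty
#' denominators yield \code{NaN}.
#'
#' @param scores numeric decision score per sample (higher = more positive).
#' @param labels binary labels, coerced to factor.
#' @param threshold decision threshold (default 0; use 0.5 for vote
#'   fractions).
#' @param convention \code{"standard"} (default) or \code{"as_printed"}.
#' @param positive the label treated as positive; default the second factor
#'   level.
#' @return a list: \code{confusion} (named TP/TN/FP/FN), \code{ACC},
#'   \code{SEN}, \code{SPE}, \code{AUC}.
#' @examples
#' computeMetrics(c(0.9, 0.2, 0.5, 0.1), c("pos", "pos", "neg", "neg"),
#'                threshold = 0.3, positive = "pos")$AUC  # 0.75
#' @export
computeMetrics <- function(scores, labels,
                           threshold = 0,
                           convention = c("standard", "as_printed"),
                           positive = NULL) {
    convention <- match.arg(convention)
    labels <- droplevels(as.factor(labels))
    if (nlevels(labels) != 2L)
        stop("binary labels required; AUC is undefined with ",
             nlevels(labels), " class(es) present")
    if (any(!is.finite(scores))) stop("scores must be finite")
    if (is.null(positive)) positive <- levels(labels)[2L]
    isPos <- labels == positive
    pred <- scores > threshold

    TP <- sum(pred & isPos); FN <- sum(!pred & isPos)
    FP <- sum(pred & !isPos); TN <- sum(!pred & !isPos)
    ACC <- (TP + TN) / (TP + TN + FN + FP)
    if (convention == "standard") {
        SEN <- TP / (TP + FN)
        SPE <- TN / (TN + FP)
    } else {
        SEN <- TP / (TP + FP)
        SPE <- TP / (TP + FN)
    }
    sp <- scores[isPos]; sn <- scores[!isPos]
    cmpr <- outer(sp, sn, "-")
    AUC <- (sum(cmpr > 0) + 0.5 * sum(cmpr == 0)) / (length(sp) * length(sn))
    list(confusion = c(TP = TP, TN = TN, FP = FP, FN = FN),
         ACC = ACC, SEN = SEN, SPE = SPE, AUC = AUC)
}

# stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin into folds
stratifiedFolds <- function(labels, nFolds, seed) {
    folds <- integer(length(labels))
    withSeed(seed, for (cl in levels(labels)) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        folds[idx] <- rep_len(seq_len(nFolds), length(idx))
    })
    folds
}

# fit a selector on training data and return row-space transforms for train
# and test matrices (component-space selectors carry their projection)
fitSelectorTransform <- function(spec, trainData, seed) {
    Vtr <- featureMatrix(trainData)
    labels <- sampleLabels(trainData)
    if (spec$method == "pca_relieff") {
        args <- spec$args
        if (is.null(args$nComponents))
            args$nComponents <- min(dim(Vtr)) - 1L
        sel <- do.call(pcaRelieffSelect,
                       c(list(data = trainData, nSelect = spec$nSelect,
                              seed = seed), args))
        ctr <- rowMeans(Vtr)
        pc <- stats::prcomp(t(Vtr), center = TRUE, scale. = FALSE)
        rot <- pc$rotation[, seq_len(args$nComponents), drop = FALSE]
        for (j in seq_len(ncol(rot))) {
            top <- which.max(abs(rot[, j]))
            if (rot[top, j] < 0) rot[, j] <- -rot[, j]
        }
        rot <- rot[, sel@selected, drop = FALSE]
        transform <- function(V) t(crossprod(V - ctr, rot))
        list(selection = sel, transform = transform)
    } else if (spec$method == "nmf_relieff" &&
               identical(spec$args$mode, "component")) {
        sel <- fitSelector(spec, trainData, seed)
        rank <- sel@params$rank
        fct <- nmfFactorize(Vtr, rank = rank, seed = seed)
        W <- basisMatrix(fct)
        keep <- sel@selected
        transform <- function(V) {            # fold-in: update H with W fixed
            eps <- 1e-12
            H <- matrix(1, ncol(W), ncol(V))
            WtV <- crossprod(W, V); WtW <- crossprod(W)
            for (i in seq_len(200L)) H <- H * WtV / (WtW %*% H + eps)
            H[keep, , drop = FALSE]
        }
        list(selection = sel, transform = transform)
    } else {
        sel <- fitSelector(spec, trainData, seed)
        transform <- function(V) V[sel@selected, , drop = FALSE]
        list(selection = sel, transform = transform)
    }
}

# train one classifier and score a held-out matrix; returns decision scores
# oriented so higher = positive class, plus the matching threshold
classifierScores <- function(Xtr, ytr, Xte, classifier, positive, foldSeed) {
    sc <- minmaxFit(Xtr)
    Xtr <- minmaxApply(Xtr, sc)
    Xte <- minmaxApply(Xte, sc)
    if (classifier == "svm") {
        fit <- e1071::svm(x = t(Xtr), y = ytr, kernel = "linear", cost = 1,
                          scale = FALSE)
        dv <- attr(stats::predict(fit, t(Xte), decision.values = TRUE),
                   "decision.values")
        lv <- strsplit(colnames(dv)[1], "/")[[1]]
        s <- as.numeric(dv[, 1])
        if (lv[1] == positive) list(scores = s, threshold = 0)
        else list(scores = -s, threshold = 0)
    } else if (classifier == "rf") {
        fit <- withSeed(foldSeed,
            randomForest::randomForest(x = t(Xtr), y = ytr, ntree = 500L))
        p <- stats::predict(fit, t(Xte), type = "prob")[, positive]
        list(scores = as.numeric(p), threshold = 0.5)
    } else {                                   # knn, k = 5, Euclidean
        pred <- withSeed(foldSeed,
            class::knn(t(Xtr), t(Xte), cl = ytr, k = 5L, prob = TRUE))
        pwin <- attr(pred, "prob")
        p <- ifelse(pred == positive, pwin, 1 - pwin)
        list(scores = as.numeric(p), threshold = 0.5)
    }
}

#' Repeated stratified cross-validation of a selection + classification
#' pipeline
#'
#' Splits the samples into stratified folds, optionally re-fits a feature
#' selector on every training fold (so selection never sees test samples),
#' trains the classifier on the training fold — with min-max feature scaling
#' learned on the training fold only — and computes
#' \code{\link{computeMetrics}} on the held-out fold. Repeats re-shuffle the
#' folds with \code{seed + repeat - 1}.
#'
#' @param data a \linkS4class{LabeledMatrix} with 2 classes.
#' @param selector \code{NULL} (use all features), a fixed
#'   \linkS4class{SelectionResult} (its features are subset before CV — the
#'   laxer protocol that lets selection see all samples), or a
#'   \code{\link{selectorSpec}} (re-fit inside each training fold; the
#'   leakage-safe default protocol).
#' @param classifier \code{"svm"} (linear, C = 1), \code{"rf"} (500 trees)
#'   or \code{"knn"} (k = 5, Euclidean).
#' @param nFolds folds per repeat (default 5); every class must have at
#'   least \code{nFolds} members.
#' @param nRepeats number of re-shuffled repeats (default 1).
#' @param seed integer seed for fold shuffling, selector fits and classifier
#'   randomness.
#' @param convention metric convention, see \code{\link{computeMetrics}}.
#' @param positive positive-class label; default the second factor level.
#' @return an \linkS4class{EvalReport}.
#' @export
crossValidate <- function(data, selector = NULL,
                          classifier = c("svm", "rf", "knn"),
                          nFolds = 5L, nRepeats = 1L, seed = 1L,
                          convention = c("standard", "as_printed"),
                          positive = NULL) {
    classifier <- match.arg(classifier)
    convention <- match.arg(convention)
    stopifnot(is(data, "LabeledMatrix"))
    labels <- droplevels(as.factor(sampleLabels(data)))
    if (nlevels(labels) != 2L)
        stop("binary labels required for evaluation")
    nFolds <- as.integer(nFolds); nRepeats <- as.integer(nRepeats)
    if (nFolds < 2L) stop("nFolds must be >= 2")
    sizes <- table(labels)
    small <- names(sizes)[sizes < nFolds]
    if (length(small) > 0L)
        stop("class '", small[1], "' has ", sizes[small[1]],
             " members, fewer than nFolds = ", nFolds)
    if (is.null(positive)) positive <- levels(labels)[2L]

    if (is(selector, "SelectionResult")) {     # selection outside CV
        data <- applySelection(data, selector)
        selector <- NULL
    }
    V <- featureMatrix(data)

    rows <- list()
    for (rep in seq_len(nRepeats)) {
        repSeed <- as.integer(seed) + rep - 1L
        folds <- stratifiedFolds(labels, nFolds, repSeed)
        for (fd in seq_len(nFolds)) {
            te <- folds == fd
            trainData <- LabeledMatrix(V[, !te, drop = FALSE], labels[!te])
            foldSeed <- repSeed * 131L + fd
            if (!is.null(selector)) {
                st <- fitSelectorTransform(selector, trainData, foldSeed)
                Xtr <- st$transform(V[, !te, drop = FALSE])
                Xte <- st$transform(V[, te, drop = FALSE])
            } else {
                Xtr <- V[, !te, drop = FALSE]
                Xte <- V[, te, drop = FALSE]
            }
            cs <- classifierScores(Xtr, labels[!te], Xte, classifier,
                                   positive, foldSeed)
            mt <- computeMetrics(cs$scores, labels[te],
                                 threshold = cs$threshold,
                                 convention = convention,
                                 positive = positive)
            rows[[length(rows) + 1L]] <- data.frame(
                repeat_ = rep, fold = fd, t(mt$confusion),
                ACC = mt$ACC, SEN = mt$SEN, SPE = mt$SPE, AUC = mt$AUC)
        }
    }
    perFold <- do.call(rbind, rows)
    metrics <- c("ACC", "SEN", "SPE", "AUC")
    summ <- data.frame(
        metric = metrics,
        mean = vapply(metrics, function(m)
            mean(perFold[[m]], na.rm = TRUE), numeric(1)),
        se = vapply(metrics, function(m) {
            v <- perFold[[m]][!is.na(perFold[[m]])]
            stats::sd(v) / sqrt(length(v))
        }, numeric(1)),
        row.names = NULL)
    new("EvalReport", perFold = perFold, metricSummary = summ,
        classifier = classifier, nFolds = nFolds, nRepeats = nRepeats,
        seed = as.integer(seed), metricConvention = convention)
}

#' Pearson correlation among selected features
#'
#' Correlation of every pair of selected features across samples. A selected
#' feature with zero variance correlates 0 with everything (warned), and the
#' diagonal is 1 by definition.
#'
#' @param data a \linkS4class{LabeledMatrix} with >= 2 samples.
#' @param selected a \linkS4class{SelectionResult} (feature-space indices).
#' @return symmetric correlation matrix with unit diagonal, dimnames from
#'   the selected feature ids.
#' @export
featureCorrelation <- function(data, selected) {
    stopifnot(is(data, "LabeledMatrix"), is(selected, "SelectionResult"))
    if (ncol(data) < 2L) stop("at least 2 samples are required")
    X <- featureMatrix(data)[selected@selected, , drop = FALSE]
    rownames(X) <- selected@featureIds
    vr <- apply(X, 1L, stats::var)
    cc <- suppressWarnings(stats::cor(t(X)))
    if (any(vr == 0)) {
        warning("zero-variance feature(s): ",
                paste(rownames(X)[vr == 0], collapse = ", "),
                "; their correlations are recorded as 0")
        cc[vr == 0, ] <- 0
        cc[, vr == 0] <- 0
    }
    diag(cc) <- 1
    cc
}
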