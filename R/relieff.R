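#' ReliefF feature weights
#'
#' Instance-based feature weighting for two or more classes. For each sampled
#' instance x the k nearest same-class neighbors (near hits) and, for every
#' other class c, the k nearest members of c (near misses) are found;
#' each feature's weight is decreased by the mean hit difference and increased
#' by the prior-weighted mean miss difference,
#' \deqn{w_f \mathrel{+}= -\overline{\mathrm{diff}}_{hit}(f)
#'   + \sum_{c \ne class(x)} \frac{P(c)}{1 - P(class(x))}\,
#'     \overline{\mathrm{diff}}_{miss,c}(f),}
#' averaged over the sampled instances. Features that separate other classes
#' score high; features that split their own class score low; constant
#' features score exactly 0.
#'
#' Feature differences are min-max normalized,
#' \eqn{\mathrm{diff}(f, x_1, x_2) = |x_{1f} - x_{2f}| / (\max_f - \min_f)}
#' (0 when the feature is constant), and instances are compared by the
#' Manhattan distance on these normalized features. Neighbor ties at equal
#' distance are resolved by ascending sample index. Class priors \eqn{P(c)}
#' are the empirical class frequencies.
#'
#' @param data a \linkS4class{LabeledMatrix} with >= 2 classes.
#' @param k neighbors per class. \code{NULL} (default) uses 10, capped at the
#'   smallest class size minus one with a warning; an explicitly supplied k
#'   that reaches any class size is an error.
#' @param nIterations \code{"all"} (default) scores every instance in sample
#'   order — fully deterministic — or an integer number of instances sampled
#'   without replacement under \code{seed}.
#' @param seed integer seed (consequential only when subsampling).
#' @return a \linkS4class{FeatureWeights} with weights in [-1, 1].
#' @examples
#' lm <- LabeledMatrix(rbind(c(0, 0, 1, 1), c(5, 5, 5, 5)),
#'                     c("a", "a", "b", "b"))
#' featureWeights(relieffWeights(lm, k = 1))  # constant feature scores 0
#' @export
relieffWeights <- function(data, k = NULL, nIterations = "all", seed = 1L) {
    ml <- asMatrixLabels(data)
    V <- ml$V
    labels <- droplevels(as.factor(ml$labels))
    n <- ncol(V)
    if (nlevels(labels) < 2L)
        stop("ReliefF needs at least 2 classes; labels are constant ",
             "(no misses exist)")
    sizes <- table(labels)
    if (is.null(k)) {
        k <- 10L
        if (k > min(sizes) - 1L) {
            k <- as.integer(min(sizes)) - 1L
            warning("k capped at smallest class size - 1 = ", k)
        }
    } else {
        k <- as.integer(k)
        if (k < 1L) stop("k must be >= 1")
        small <- names(sizes)[sizes <= k]
        if (length(small) > 0L)
            stop("k = ", k, " reaches the size of class '", small[1],
                 "' (", sizes[small[1]], " members); every class needs ",
                 "at least k + 1")
    }

    Xn <- minmaxRows(V)                       # m x n, constant rows -> 0
    D <- as.matrix(stats::dist(t(Xn), method = "manhattan"))
    priors <- as.numeric(sizes) / n
    names(priors) <- names(sizes)
    classIdx <- split(seq_len(n), labels)

    if (identical(nIterations, "all")) {
        iters <- seq_len(n)
    } else {
        nIterations <- as.integer(nIterations)
        if (is.na(nIterations) || nIterations < 1L || nIterations > n)
            stop("nIterations must be 'all' or an integer in [1, ", n, "]")
        iters <- withSeed(seed, sort(sample.int(n, nIterations)))
    }

    m <- nrow(V)
    w <- numeric(m)
    for (i in iters) {
        cls <- as.character(labels[i])
        d <- D[i, ]
        for (cl in names(classIdx)) {
            cand <- classIdx[[cl]]
            if (cl == cls) cand <- cand[cand != i]
            nb <- cand[order(d[cand], cand)][seq_len(k)]
            dif <- rowMeans(abs(Xn[, i] - Xn[, nb, drop = FALSE]))
            if (cl == cls) {
                w <- w - dif
            } else {
                w <- w + (priors[[cl]] / (1 - priors[[cls]])) * dif
            }
        }
    }
    w <- w / length(iters)
    names(w) <- rownames(V)
    new("FeatureWeights", weights = w, k = k,
        nIterations = length(iters), seed = as.integer(seed))
}

#' Rank features by weight
#'
#' Returns the \code{nSelect} features with the largest weights, in
#' descending-weight order; ties are broken by ascending feature index.
#'
#' @param weights a \linkS4class{FeatureWeights}.
#' @param nSelect number of features to keep, in \code{[1, m]}.
#' @return a \linkS4class{SelectionResult} with method \code{"relieff"}.
#' @export
rankFeatures <- function(weights, nSelect) {
    stopifnot(is(weights, "FeatureWeights"))
    w <- weights@weights
    nSelect <- as.integer(nSelect)
    if (is.na(nSelect) || nSelect < 1L || nSelect > length(w))
        stop("nSelect must be in [1, ", length(w), "]")
    ord <- order(-w, seq_along(w))[seq_len(nSelect)]
    ids <- names(w)[ord]
    if (is.null(ids)) ids <- as.character(ord)
    new("SelectionResult", method = "relieff", selected = as.integer(ord),
        featureIds = ids, scores = unname(w[ord]),
        params = list(k = weights@k, nSelect = nSelect,
                      nIterations = weights@nIterations, seed = weights@seed),
        componentWeights = numeric(0))
}

#' ReliefF-only feature selection
#'
#' Convenience wrapper: \code{\link{relieffWeights}} followed by
#' \code{\link{rankFeatures}}.
#'
#' @inheritParams relieffWeights
#' @param nSelect number of features to keep.
#' @return a \linkS4class{SelectionResult} with method \code{"relieff"}.
#' @export
relieffSelect <- function(data, nSelect, k = NULL, nIterations = "all",
                          seed = 1L) {
    rankFeatures(relieffWeights(data, k = k, nIterations = nIterations,
                                seed = seed), nSelect)
}
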