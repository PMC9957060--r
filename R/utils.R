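# internal helpers shared across modules

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, code) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    code
}

# coerce the selector/evaluator input to (matrix, labels); labels required
# unless allowUnlabeled
asMatrixLabels <- function(data, allowUnlabeled = FALSE) {
    if (is(data, "LabeledMatrix")) {
        list(V = featureMatrix(data), labels = sampleLabels(data))
    } else if (is.matrix(data)) {
        if (!allowUnlabeled)
            stop("a LabeledMatrix with sample labels is required")
        list(V = data, labels = NULL)
    } else stop("'data' must be a LabeledMatrix or a matrix")
}

checkNonnegative <- function(V, context = "NMF") {
    if (any(V < 0)) {
        bad <- which(V < 0, arr.ind = TRUE)[1, ]
        stop(context, " requires a nonnegative matrix; entry [", bad[1], ",",
             bad[2], "] is negative. Shift or use a baseline selector ",
             "(relieffSelect, pcaRelieffSelect, svmRfeSelect).")
    }
    invisible(TRUE)
}

# per-feature min-max scaling; constant features map to 0
minmaxRows <- function(V) {
    rng <- apply(V, 1L, range)
    span <- rng[2L, ] - rng[1L, ]
    span[span == 0] <- 1
    (V - rng[1L, ]) / span
}

# min-max scaling parameters learned on training columns, applied to any
# matrix with the same features
minmaxFit <- function(Vtrain) {
    rng <- apply(Vtrain, 1L, range)
    span <- rng[2L, ] - rng[1L, ]
    span[span == 0] <- 1
    list(lo = rng[1L, ], span = span)
}

minmaxApply <- function(V, fit) (V - fit$lo) / fit$span

frobenius <- function(M) sqrt(sum(M * M))
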