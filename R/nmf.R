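#' Nonnegative matrix factorization by multiplicative updates
#'
#' Factorizes a nonnegative matrix \eqn{V \approx WH} (features x samples)
#' under the squared-Frobenius objective \eqn{\|V - WH\|_F^2} using the
#' classical multiplicative update rules
#' \deqn{W \leftarrow W \odot \frac{VH^\top}{WHH^\top}, \qquad
#'       H \leftarrow H \odot \frac{W^\top V}{W^\top W H},}
#' which preserve nonnegativity and never increase the objective. \code{W}'s
#' columns are metagenes; \code{H}'s columns encode each sample in metagene
#' space.
#'
#' Both factors are initialized from \code{Uniform(0.1, 1.1)} draws under
#' \code{seed} (strictly positive, so no entry is absorbed at zero), and a
#' small \code{eps = 1e-12} is added to the update denominators to guard
#' divisions. Iteration stops at \code{maxIter} or when the relative decrease
#' of the (non-squared) Frobenius error falls below \code{tol}.
#'
#' @param data a \linkS4class{LabeledMatrix} or a nonnegative numeric matrix,
#'   features x samples.
#' @param rank integer factorization rank r, \code{1 <= r <= min(m, n)}.
#' @param maxIter maximum number of update iterations (default 500).
#' @param tol relative-decrease convergence tolerance on the Frobenius error
#'   (default 1e-6); \code{tol = 0} disables the early stop and runs exactly
#'   \code{maxIter} iterations.
#' @param seed integer seed for the random initialization.
#' @return an \linkS4class{NMFFactors}.
#' @examples
#' V <- matrix(c(1, 2, 2, 4), 2, 2)  # rank one
#' f <- nmfFactorize(V, rank = 1, seed = 1)
#' tail(objectiveHistory(f), 1)      # ~ 0
#' @export
nmfFactorize <- function(data, rank, maxIter = 500L, tol = 1e-6, seed = 1L) {
    V <- asMatrixLabels(data, allowUnlabeled = TRUE)$V
    checkNonnegative(V)
    m <- nrow(V); n <- ncol(V)
    rank <- as.integer(rank)
    if (length(rank) != 1L || is.na(rank) || rank < 1L || rank > min(m, n))
        stop("rank must be an integer in [1, min(", m, ", ", n, ")]")
    if (maxIter < 1L) stop("maxIter must be >= 1")
    if (tol < 0) stop("tol must be >= 0")
    eps <- 1e-12

    init <- withSeed(seed, list(
        W = matrix(stats::runif(m * rank, 0.1, 1.1), m, rank),
        H = matrix(stats::runif(rank * n, 0.1, 1.1), rank, n)))
    W <- init$W; H <- init$H

    history <- numeric(0)
    prev <- frobenius(V - W %*% H)
    for (it in seq_len(maxIter)) {
        W <- W * (V %*% t(H)) / (W %*% (H %*% t(H)) + eps)
        H <- H * (t(W) %*% V) / ((t(W) %*% W) %*% H + eps)
        err <- frobenius(V - W %*% H)
        history <- c(history, err)
        if (tol > 0 && prev > 0 && (prev - err) / prev < tol) {
            prev <- err
            break
        }
        prev <- err
    }
    new("NMFFactors", W = W, H = H, rank = rank,
        objectiveHistory = history, iterationsRun = length(history),
        seed = as.integer(seed))
}

#' Frobenius reconstruction error
#'
#' \eqn{\|V - WH\|_F} (non-squared; square it for the squared objective).
#'
#' @param V observed matrix, m x n.
#' @param W basis matrix, m x r.
#' @param H coefficient matrix, r x n.
#' @return a single nonnegative number.
#' @export
reconstructionError <- function(V, W, H) {
    if (nrow(W) != nrow(V) || ncol(H) != ncol(V) || ncol(W) != nrow(H))
        stop("shape mismatch: V is ", nrow(V), "x", ncol(V), ", W is ",
             nrow(W), "x", ncol(W), ", H is ", nrow(H), "x", ncol(H))
    frobenius(V - W %*% H)
}
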