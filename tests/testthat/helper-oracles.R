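# Independent straight-line oracles used across the suite. Each one is a
# deliberately naive re-derivation (explicit loops, textbook formulas) kept
# free of any package internals so that agreement is evidence, not tautology.

# multiplicative-update NMF, fixed iteration count, same initialization
# protocol as the package (Uniform(0.1, 1.1) under set.seed, W then H)
nmfOracle <- function(V, rank, iters, seed) {
    set.seed(seed)
    W <- matrix(runif(nrow(V) * rank, 0.1, 1.1), nrow(V), rank)
    H <- matrix(runif(rank * ncol(V), 0.1, 1.1), rank, ncol(V))
    eps <- 1e-12
    errs <- numeric(iters)
    for (i in seq_len(iters)) {
        W <- W * (V %*% t(H)) / (W %*% (H %*% t(H)) + eps)
        H <- H * (t(W) %*% V) / ((t(W) %*% W) %*% H + eps)
        errs[i] <- sqrt(sum((V - W %*% H)^2))
    }
    list(W = W, H = H, errs = errs)
}

# ReliefF by exhaustive neighbor enumeration: per-instance, per-class
# candidate lists, explicit normalized diffs, no shared code with the package
relieffOracle <- function(V, labels, k) {
    labels <- as.factor(labels)
    m <- nrow(V); n <- ncol(V)
    rng <- apply(V, 1, function(x) max(x) - min(x))
    dif <- function(f, i, j)
        if (rng[f] == 0) 0 else abs(V[f, i] - V[f, j]) / rng[f]
    dst <- function(i, j) sum(vapply(seq_len(m), dif, 0, i = i, j = j))
    pri <- table(labels) / n
    w <- numeric(m)
    for (i in seq_len(n)) {
        for (cl in levels(labels)) {
            cand <- setdiff(which(labels == cl), i)
            dd <- vapply(cand, dst, 0, i = i)
            nb <- cand[order(dd, cand)][seq_len(k)]
            for (f in seq_len(m)) {
                md <- mean(vapply(nb, function(j) dif(f, i, j), 0))
                if (cl == as.character(labels[i])) {
                    w[f] <- w[f] - md
                } else {
                    w[f] <- w[f] +
                        pri[[cl]] / (1 - pri[[as.character(labels[i])]]) * md
                }
            }
        }
    }
    w / n
}

# pairwise-concordance AUC by double loop over (positive, negative) pairs
aucOracle <- function(scores, isPos) {
    sp <- scores[isPos]; sn <- scores[!isPos]
    tot <- 0
    for (a in sp) for (b in sn)
        tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
    tot / (length(sp) * length(sn))
}

# Pearson correlation from the raw sum formula
pearsonOracle <- function(x, y) {
    n <- length(x)
    num <- n * sum(x * y) - sum(x) * sum(y)
    den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
    num / den
}

# SVM-RFE elimination order by retraining and removing exactly one feature
# at a time; returns indices in removal order, survivors appended by final
# ranking
svmRfeOracle <- function(V, labels, nSelect) {
    rng <- apply(V, 1, range)
    span <- rng[2, ] - rng[1, ]; span[span == 0] <- 1
    Xn <- (V - rng[1, ]) / span
    remaining <- seq_len(nrow(V))
    removed <- integer(0)
    while (length(remaining) > nSelect) {
        fit <- e1071::svm(x = t(Xn[remaining, , drop = FALSE]),
                          y = labels, kernel = "linear", cost = 1,
                          scale = FALSE)
        w <- as.numeric(t(fit$coefs) %*% fit$SV)
        worst <- order(w^2, seq_along(remaining))[1]
        removed <- c(removed, remaining[worst])
        remaining <- remaining[-worst]
    }
    list(removed = removed, remaining = remaining)
}
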