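#' Simulate a labeled matrix with planted informative features
#'
#' Generates the two input regimes the selectors target: overdispersed
#' gene-family copy-number counts (negative binomial, the default), Poisson
#' counts, and continuous nonnegative microarray-style intensities
#' (Gaussian clipped at zero). A small planted subset of features is
#' class-informative: in the positive class its mean is shifted upward by
#' \code{effectSize} baseline standard deviations,
#' \eqn{\mu_1 = \mu_0 + \mathrm{effectSize} \cdot \sigma_0}; every other
#' feature is identically distributed in both classes. The planted indices
#' are recorded in \code{metadata(x)$planted} (see
#' \code{\link{plantedFeatures}}), giving selectors a known ground truth.
#'
#' Defaults emulate the small-n, high-dimension regime of gene-family and
#' microarray benchmarks: baseline mean copy number 5 with negative-binomial
#' dispersion 0.5 (variance \eqn{\mu + 0.5\mu^2}), balanced classes.
#'
#' @param nFeatures number of features (rows).
#' @param nSamples number of samples (columns).
#' @param nInformative number of planted class-informative features,
#'   \code{<= nFeatures}.
#' @param effectSize mean shift of planted features in the positive class,
#'   in units of the baseline standard deviation; 0 gives a pure-noise null.
#' @param countModel \code{"negbinom"} (default), \code{"poisson"} or
#'   \code{"gaussian_nonneg"}.
#' @param classBalance fraction of samples in the positive class, in (0, 1).
#' @param baselineMean baseline feature mean \eqn{\mu_0} (default 5).
#' @param dispersion negative-binomial dispersion (variance
#'   \eqn{\mu + \phi\mu^2}; default 0.5; ignored by the other models).
#' @param noiseSd Gaussian noise standard deviation for
#'   \code{"gaussian_nonneg"} (default 1).
#' @param seed integer seed; identical seeds give identical matrices.
#' @return a \linkS4class{LabeledMatrix} with labels \code{"neg"}/\code{"pos"}
#'   and the planted feature indices in its metadata.
#' @examples
#' sim <- simulatePlantedMatrix(50, 30, nInformative = 2, effectSize = 8,
#'                              seed = 1)
#' plantedFeatures(sim)
#' @export
simulatePlantedMatrix <- function(nFeatures, nSamples, nInformative,
                                  effectSize,
                                  countModel = c("negbinom", "poisson",
                                                 "gaussian_nonneg"),
                                  classBalance = 0.5, baselineMean = 5,
                                  dispersion = 0.5, noiseSd = 1,
                                  seed = 1L) {
    countModel <- match.arg(countModel)
    nFeatures <- as.integer(nFeatures); nSamples <- as.integer(nSamples)
    nInformative <- as.integer(nInformative)
    if (nFeatures < 1L || nSamples < 2L)
        stop("need nFeatures >= 1 and nSamples >= 2")
    if (nInformative < 0L || nInformative > nFeatures)
        stop("nInformative must be in [0, nFeatures]")
    if (effectSize < 0) stop("effectSize must be >= 0")
    if (classBalance <= 0 || classBalance >= 1)
        stop("classBalance must be in (0, 1)")

    nPos <- max(1L, min(nSamples - 1L, round(classBalance * nSamples)))
    labels <- factor(rep(c("neg", "pos"), c(nSamples - nPos, nPos)),
                     levels = c("neg", "pos"))

    mu0 <- baselineMean
    sd0 <- switch(countModel,
        poisson = sqrt(mu0),
        negbinom = sqrt(mu0 + dispersion * mu0^2),
        gaussian_nonneg = noiseSd)
    mu1 <- mu0 + effectSize * sd0

    draw <- switch(countModel,
        poisson = function(n, mu) stats::rpois(n, lambda = mu),
        negbinom = function(n, mu)
            stats::rnbinom(n, mu = mu, size = 1 / dispersion),
        gaussian_nonneg = function(n, mu)
            pmax(0, stats::rnorm(n, mean = mu, sd = noiseSd)))

    out <- withSeed(seed, {
        planted <- sort(sample.int(nFeatures, nInformative))
        V <- matrix(draw(nFeatures * nSamples, mu0), nFeatures, nSamples)
        if (nInformative > 0L && nPos > 0L) {
            pos <- labels == "pos"
            V[planted, pos] <- draw(nInformative * sum(pos), mu1)
        }
        list(V = V, planted = planted)
    })
    lm <- LabeledMatrix(out$V, labels)
    metadata(lm)$planted <- out$planted
    metadata(lm)$spec <- list(nFeatures = nFeatures, nSamples = nSamples,
                              nInformative = nInformative,
                              effectSize = effectSize,
                              countModel = countModel,
                              classBalance = classBalance,
                              baselineMean = baselineMean,
                              dispersion = dispersion, noiseSd = noiseSd,
                              seed = as.integer(seed))
    lm
}

#' Fraction of planted features recovered by a selection
#'
#' The benchmark statistic for the synthetic generator: what fraction of the
#' ground-truth informative features a selector placed among its selected
#' set.
#'
#' @param selection a \linkS4class{SelectionResult} in feature space.
#' @param truth a \linkS4class{LabeledMatrix} from
#'   \code{\link{simulatePlantedMatrix}}, or an integer vector of planted
#'   indices.
#' @return recovered fraction in [0, 1].
#' @export
plantedRecovery <- function(selection, truth) {
    planted <- if (is(truth, "LabeledMatrix")) plantedFeatures(truth)
               else as.integer(truth)
    if (is.null(planted) || length(planted) == 0L)
        stop("no planted features recorded in 'truth'")
    mean(planted %in% selectedFeatures(selection))
}
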