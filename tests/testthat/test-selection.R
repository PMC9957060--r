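test_that("NMF-ReliefF gene mode recovers strongly planted features", {
    sim <- simulatePlantedMatrix(50, 60, nInformative = 2, effectSize = 10,
                                 countModel = "negbinom", seed = 7)
    sel <- nmfRelieffSelect(sim, rank = 5, nSelect = 2, mode = "gene",
                            seed = 7)
    expect_setequal(selectedFeatures(sel), plantedFeatures(sim))
})

test_that("gene-mode scores conserve the positive component mass", {
    sim <- simulatePlantedMatrix(30, 40, nInformative = 3, effectSize = 4,
                                 seed = 3)
    sel <- nmfRelieffSelect(sim, rank = 6, nSelect = 30, mode = "gene",
                            seed = 3)
    expect_true(all(selectionScores(sel) >= 0))
    expect_equal(sum(selectionScores(sel)),
                 sum(pmax(sel@componentWeights, 0)), tolerance = 1e-10)
    # full selection returns every feature, scores non-increasing
    expect_setequal(selectedFeatures(sel), seq_len(30))
    expect_true(all(diff(selectionScores(sel)) <= 1e-12))
})

test_that("component mode returns top metagenes and respects rank bound", {
    sim <- simulatePlantedMatrix(30, 40, nInformative = 2, effectSize = 6,
                                 seed = 11)
    sel <- nmfRelieffSelect(sim, rank = 6, nSelect = 3, mode = "component",
                            seed = 11)
    expect_length(selectedFeatures(sel), 3L)
    expect_true(all(selectedFeatures(sel) <= 6L))
    expect_identical(selectionScores(sel),
                     sort(sel@componentWeights, decreasing = TRUE)[1:3])
    expect_error(nmfRelieffSelect(sim, rank = 2, nSelect = 3,
                                  mode = "component", seed = 1),
                 "rank >= nSelect")
})

test_that("selectors are pure functions of data, params and seed", {
    sim <- simulatePlantedMatrix(40, 30, nInformative = 2, effectSize = 5,
                                 seed = 13)
    a <- nmfRelieffSelect(sim, rank = 5, nSelect = 5, seed = 99)
    b <- nmfRelieffSelect(sim, rank = 5, nSelect = 5, seed = 99)
    expect_identical(selectedFeatures(a), selectedFeatures(b))
    expect_identical(selectionScores(a), selectionScores(b))

    p1 <- pcaRelieffSelect(sim, nComponents = 5, nSelect = 2, seed = 4)
    p2 <- pcaRelieffSelect(sim, nComponents = 5, nSelect = 2, seed = 4)
    expect_identical(selectionScores(p1), selectionScores(p2))

    s1 <- svmRfeSelect(sim, nSelect = 3, seed = 2)
    s2 <- svmRfeSelect(sim, nSelect = 3, seed = 2)
    expect_identical(selectedFeatures(s1), selectedFeatures(s2))
})

test_that("negative data is rejected by NMF-ReliefF with guidance", {
    V <- matrix(rnorm(40), 8, 5)
    V[1, 1] <- -5
    lm <- LabeledMatrix(V, c("a", "a", "a", "b", "b"))
    expect_error(nmfRelieffSelect(lm, rank = 2, nSelect = 2),
                 "nonnegative.*baseline")
})

test_that("PCA-ReliefF finds the variance axis and the signal direction", {
    # variance only along feature 2: PC1 is that axis up to sign
    V <- rbind(rep(1, 10), c(1:10), rep(2, 10))
    lm <- LabeledMatrix(V, rep(c("a", "b"), each = 5))
    pc <- stats::prcomp(t(V), center = TRUE)
    expect_equal(unname(abs(pc$rotation[2, 1])), 1, tolerance = 1e-12)
    sel <- pcaRelieffSelect(lm, nComponents = 1, nSelect = 1, k = 1)
    expect_identical(selectedFeatures(sel), 1L)

    # planted separation: the discriminating direction gets maximal weight
    sim <- simulatePlantedMatrix(20, 40, nInformative = 1, effectSize = 12,
                                 countModel = "gaussian_nonneg", seed = 5)
    sel2 <- pcaRelieffSelect(sim, nComponents = 5, nSelect = 1, k = 3)
    rot <- stats::prcomp(t(featureMatrix(sim)), center = TRUE)$rotation
    loading <- abs(rot[plantedFeatures(sim), selectedFeatures(sel2)])
    # the chosen component is dominated by the planted feature
    expect_gt(loading, 0.8)
    expect_error(pcaRelieffSelect(sim, nComponents = 3, nSelect = 4),
                 "nSelect")
})

test_that("SVM-RFE keeps a perfect separator and drops pure noise", {
    set.seed(19)
    V <- rbind(rep(c(0, 1), each = 10), runif(20))
    lm <- LabeledMatrix(V, rep(c("a", "b"), each = 10))
    sel <- svmRfeSelect(lm, nSelect = 1)
    expect_identical(selectedFeatures(sel), 1L)
})

test_that("SVM-RFE elimination matches the retrain-one-at-a-time oracle", {
    set.seed(29)
    V <- matrix(runif(8 * 14), 8, 14)
    V[2, ] <- V[2, ] + rep(c(0, 1.2), each = 7)     # one informative row
    labels <- factor(rep(c("a", "b"), each = 7))
    lm <- LabeledMatrix(V, labels)
    oracle <- svmRfeOracle(V, labels, nSelect = 2)
    sel <- svmRfeSelect(lm, nSelect = 2, step = 1)
    expect_setequal(selectedFeatures(sel), oracle$remaining)

    # nSelect = m keeps everything, ranked by the single fit
    all8 <- svmRfeSelect(lm, nSelect = 8)
    expect_setequal(selectedFeatures(all8), 1:8)
    expect_true(all(diff(selectionScores(all8)) <= 1e-12))

    expect_error(svmRfeSelect(LabeledMatrix(V, rep(c("a", "b", "c"),
        length.out = 14)), nSelect = 2), "binary")
})

test_that("the mRMR prefilter retains label-relevant features", {
    sim <- simulatePlantedMatrix(16, 30, nInformative = 2, effectSize = 8,
                                 seed = 37)
    sel <- svmRfeSelect(sim, nSelect = 2, useMrmr = TRUE)
    expect_setequal(selectedFeatures(sel), plantedFeatures(sim))
})

test_that("applySelection subsets rows in selection order", {
    sim <- simulatePlantedMatrix(10, 12, nInformative = 1, effectSize = 5,
                                 seed = 41)
    sel <- relieffSelect(sim, nSelect = 3, k = 2)
    sub <- applySelection(sim, sel)
    expect_identical(nrow(sub), 3L)
    expect_identical(featureMatrix(sub)[1, ],
                     featureMatrix(sim)[selectedFeatures(sel)[1], ])
})
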