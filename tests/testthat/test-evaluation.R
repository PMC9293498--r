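test_that("stratified splits are proportional, disjoint, exhaustive", {
    labels <- rep(1:2, each = 52)
    set.seed(1)
    sp <- stratifiedSplit(labels, 0.10)
    expect_length(sp$test, 10L)  # round(52 * 0.1) = 5 per class
    expect_equal(unname(table(labels[sp$test])), c(5L, 5L),
                 ignore_attr = TRUE)
    expect_length(intersect(sp$train, sp$test), 0L)
    expect_setequal(c(sp$train, sp$test), seq_along(labels))

    # boundary: half of a 2-trial class is exactly 1 test trial
    sp2 <- stratifiedSplit(rep(1:2, each = 2), 0.5)
    expect_equal(unname(table(rep(1:2, each = 2)[sp2$test])),
                 c(1L, 1L), ignore_attr = TRUE)

    # at least one test trial even when the rounded count is zero
    sp3 <- stratifiedSplit(rep(1L, 4) , 0.05)
    expect_length(sp3$test, 1L)

    expect_error(stratifiedSplit(c(1, 1, 2), 0), "testFrac")
    expect_error(stratifiedSplit(c(1, 2, 2), 0.5), "fewer than 2")

    set.seed(99); a <- stratifiedSplit(labels, 0.1)
    set.seed(99); b <- stratifiedSplit(labels, 0.1)
    expect_identical(a, b)
})

test_that("pairwise combinations enumerate C(n,2) in order", {
    p5 <- pairwiseCombinations(1:5)
    expect_equal(nrow(p5), 10L)
    expect_equal(p5[1, ], c(1L, 2L))
    expect_equal(p5[10, ], c(4L, 5L))
    expect_equal(nrow(pairwiseCombinations(1:2)), 1L)
    expect_equal(nrow(pairwiseCombinations(c(3, 1, 7))), 3L)
    expect_error(pairwiseCombinations(1), ">= 2")
})

test_that("degenerate CV configs behave and errors carry rep index", {
    tab <- makeBetaTable(smallSpec(nClasses = 2, trialsPerClass = 10,
                                   effectSize = c(1, 3), seed = 41))
    r1 <- monteCarloCV(tab, nFeatures = 20, reps = 1, seed = 5)
    expect_length(perRepAccuracy(r1), 1L)
    expect_equal(r1@sd, 0)
    expect_error(monteCarloCV(tab, nFeatures = 10000, reps = 2,
                              seed = 5),
                 "repetition 1")
    expect_error(monteCarloCV(tab, nFeatures = 20, classes = c(8, 9)),
                 "no trials")
})

test_that("per-rep accuracies are bounded and the mean is their mean", {
    tab <- makeBetaTable(smallSpec(nClasses = 3, trialsPerClass = 8,
                                   seed = 43))
    r <- monteCarloCV(tab, nFeatures = 30, reps = 12, seed = 2)
    acc <- perRepAccuracy(r)
    expect_true(all(acc >= 0 & acc <= 100))
    expect_equal(meanAccuracy(r), mean(acc))
})

test_that("identical config and seed reproduce the report exactly", {
    tab <- makeBetaTable(smallSpec(nClasses = 2, trialsPerClass = 10,
                                   effectSize = c(1, 2), seed = 47))
    r1 <- monteCarloCV(tab, nFeatures = 25, reps = 8, seed = 31)
    r2 <- monteCarloCV(tab, nFeatures = 25, reps = 8, seed = 31)
    expect_identical(r1, r2)
    f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
    writeReport(r1, f1); writeReport(r2, f2)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
    # extending reps never perturbs earlier repetitions
    r3 <- monteCarloCV(tab, nFeatures = 25, reps = 16, seed = 31)
    expect_identical(perRepAccuracy(r3)[1:8], perRepAccuracy(r1))
})

test_that("strong separation is decoded nearly perfectly", {
    tab <- makeBetaTable(smallSpec(nClasses = 2, trialsPerClass = 20,
                                   effectSize = c(2, 8),
                                   noiseSd = 0.3, seed = 53))
    r <- monteCarloCV(tab, nFeatures = 30, reps = 20, seed = 3)
    expect_gte(meanAccuracy(r), 95)
})

test_that("binary null data decode at 50 percent within error", {
    tab <- makeBetaTable(smallSpec(nClasses = 2, trialsPerClass = 26,
                                   effectSize = 0, seed = 59))
    r <- monteCarloCV(tab, nFeatures = 50, reps = 40, seed = 7)
    se <- r@sd / sqrt(length(perRepAccuracy(r)))
    expect_lt(abs(meanAccuracy(r) - 50), 3 * se + 1e-9)
})

test_that("pairwise protocol produces one report per class pair", {
    tab <- makeBetaTable(smallSpec(nClasses = 3, trialsPerClass = 10,
                                   effectSize = c(1, 3, 5),
                                   noiseSd = 0.5, seed = 61))
    r <- pairwiseCV(tab, nFeatures = 30, reps = 4, seed = 9)
    expect_equal(nrow(perPairAccuracy(r)), 3L)
    expect_equal(perPairAccuracy(r)$classA, c(1L, 1L, 2L))
    expect_equal(meanAccuracy(r),
                 mean(perRepAccuracy(r)))
    r2 <- pairwiseCV(tab, nFeatures = 30, reps = 4, seed = 9)
    expect_identical(r, r2)
})

test_that("the feature sweep returns a tidy curve per grid value", {
    tab <- makeBetaTable(smallSpec(nClasses = 2, trialsPerClass = 12,
                                   effectSize = c(1, 4),
                                   noiseSd = 0.5, seed = 67))
    curve <- featureSweep(tab, c(10, 40, 120), reps = 4, seed = 11)
    expect_equal(nrow(curve), 3L)
    expect_equal(curve$n_features, c(10L, 40L, 120L))
    expect_true(all(c("mean_accuracy", "sd", "reps", "seed") %in%
                    names(curve)))
    expect_error(featureSweep(tab, c(10, 1e6), reps = 2, seed = 1),
                 "exceeds")
})

test_that("label-shuffled data sweep out flat at chance", {
    tab <- makeBetaTable(smallSpec(nClasses = 2, trialsPerClass = 26,
                                   effectSize = c(1, 4), seed = 71))
    shuffled <- new("TrialFeatureTable", values = featureValues(tab),
                    labels = lrbsf:::withSeed(5L,
                                 sample(trialLabels(tab))),
                    trialIds = trialIds(tab), voxelSet = tab@voxelSet)
    curve <- featureSweep(shuffled, c(20, 80, 200), reps = 25,
                          seed = 13)
    for (i in seq_len(nrow(curve))) {
        se <- curve$sd[i] / sqrt(curve$reps[i])
        expect_lt(abs(curve$mean_accuracy[i] - 50), 4 * se)
    }
})
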