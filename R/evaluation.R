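#' Stratified random train/test split
#'
#' Splits per class proportionally: each class contributes
#' \code{floor(n * testFrac + 0.5)} test trials (round half up), never
#' fewer than one. Train and test are disjoint and exhaustive. Uses the
#' current RNG state; seed it (or go through [monteCarloCV()]) for
#' reproducible splits.
#'
#' @param labels Integer class label per trial.
#' @param testFrac Test fraction in (0, 1); the emulated protocol uses
#'   0.10 (90/10 splits).
#' @return List with integer row index vectors \code{train} and
#'   \code{test}.
#' @export
stratifiedSplit <- function(labels, testFrac = 0.10) {
    if (testFrac <= 0 || testFrac >= 1)
        stop("testFrac must be in (0, 1)", call. = FALSE)
    test <- integer(0)
    for (cl in sort(unique(labels))) {
        rows <- which(labels == cl)
        if (length(rows) < 2)
            stop("class ", cl, " has fewer than 2 trials", call. = FALSE)
        nTest <- max(1L, min(length(rows) - 1L,
                             as.integer(floor(length(rows) * testFrac
                                              + 0.5))))
        test <- c(test, sample(rows, nTest))
    }
    test <- sort(test)
    list(train = setdiff(seq_along(labels), test), test = test)
}

#' All unordered class pairs
#'
#' C(n, 2) pairs in lexicographic order; 5 classes give the 10
#' one-to-one decoding combinations of the pairwise protocol.
#'
#' @param labels Vector of distinct class labels (>= 2).
#' @return 2-column matrix, one pair per row.
#' @examples
#' pairwiseCombinations(1:5)  # 10 rows
#' @export
pairwiseCombinations <- function(labels) {
    labels <- sort(unique(labels))
    if (length(labels) < 2) stop("need >= 2 labels", call. = FALSE)
    t(utils::combn(labels, 2))
}

# Per-repetition seeds: one stream seeded once, drawn sequentially, so
# extending reps never perturbs earlier repetitions.
repSeeds <- function(seed, n) {
    withSeed(seed, sample.int(.Machine$integer.max, n))
}

# One CV repetition on a (possibly class-subset) trial table.
# Returns accuracy in percent.
runRep <- function(table, nFeatures, mode, eightFeature, theta,
                   testFrac, selection, fixedRanking, pairRank) {
    split <- stratifiedSplit(table@labels, testFrac)
    ranking <- if (selection == "refit")
        rankTableVoxels(table, rows = split$train, pair = pairRank)
    else fixedRanking
    vs <- selectTopN(ranking, nFeatures, enforceLimits = FALSE)
    sub <- buildTrialTable(table, vs)
    trainTab <- new("TrialFeatureTable",
                    values = sub@values[split$train, , drop = FALSE],
                    labels = sub@labels[split$train],
                    trialIds = sub@trialIds[split$train], voxelSet = vs)
    testTab <- new("TrialFeatureTable",
                   values = sub@values[split$test, , drop = FALSE],
                   labels = sub@labels[split$test],
                   trialIds = sub@trialIds[split$test], voxelSet = vs)
    trainC <- transformTable(trainTab, mode = mode,
                             eightFeature = eightFeature)
    testC <- transformTable(testTab, mode = mode,
                            eightFeature = eightFeature)
    model <- fitDecoder(trainC, theta = theta)
    if (length(model@classes) == 2L) {
        # binary: explicit likelihood-ratio rule with threshold theta,
        # lower class label on the null-hypothesis (numerator) side
        sc <- decodeTable(model, testC)
        logLr <- sc$logLik[, 1] - sc$logLik[, 2]
        predicted <- ifelse(logLr >= log(theta),
                            model@classes[1], model@classes[2])
        100 * mean(predicted == testTab@labels)
    } else {
        decodeTable(model, testC)$accuracy
    }
}

#' Monte-Carlo cross-validation of the full decoding chain
#'
#' For each repetition: draw a stratified 90/10 (by default) split,
#' rank and select the top-N voxels on the training rows only, cumulant-
#' transform both folds, train the KDE likelihood-ratio decoder on the
#' training fold and score the test fold. Reports per-repetition
#' accuracies and their mean/sd. Fully reproducible: the same table,
#' configuration and seed give an identical report, and extending
#' \code{reps} leaves earlier repetitions unchanged.
#'
#' @param table A [TrialFeatureTable-class] over candidate voxels.
#' @param nFeatures Number of voxels to select per repetition.
#' @param classes Optional class subset (e.g. one pair) to decode.
#' @param mode Cumulant convention ("paper" or "standard").
#' @param eightFeature Use the 8-feature cumulant set.
#' @param theta Binary decision threshold (ignored for > 2 classes).
#' @param reps Number of Monte-Carlo repetitions (default 100).
#' @param testFrac Test fraction (default 0.10).
#' @param seed Integer seed for the repetition stream.
#' @param selection \code{"refit"} recomputes the voxel ranking inside
#'   every training fold (default, leakage-free); \code{"fixed"} ranks
#'   once on the full table, reproducing whole-data selection.
#' @param pairRank Rank with the per-pair two-sample statistic instead
#'   of the pooled one-sample statistic (binary tasks only).
#' @return A [McCvReport-class].
#' @examples
#' tab <- makeBetaTable(syntheticSpec(nClasses = 2, trialsPerClass = 20,
#'     gridShape = c(8, 8, 6), effectSize = c(1, 3), noiseSd = 0.3,
#'     seed = 11))
#' monteCarloCV(tab, nFeatures = 60, reps = 5, seed = 1)
#' @export
monteCarloCV <- function(table, nFeatures, classes = NULL,
                         mode = c("paper", "standard"),
                         eightFeature = FALSE, theta = 1, reps = 100,
                         testFrac = 0.10, seed = 1,
                         selection = c("refit", "fixed"),
                         pairRank = FALSE) {
    mode <- match.arg(mode)
    selection <- match.arg(selection)
    stopifnot(is(table, "TrialFeatureTable"), reps >= 1)
    if (!is.null(classes)) {
        keep <- table@labels %in% classes
        if (!any(keep))
            stop("no trials with the requested classes", call. = FALSE)
        table <- new("TrialFeatureTable",
                     values = table@values[keep, , drop = FALSE],
                     labels = table@labels[keep],
                     trialIds = table@trialIds[keep],
                     voxelSet = table@voxelSet)
    }
    classLabels <- sort(unique(table@labels))
    pairRankArg <- if (pairRank) {
        if (length(classLabels) != 2L)
            stop("pairRank requires exactly 2 classes", call. = FALSE)
        classLabels
    } else NULL
    fixedRanking <- if (selection == "fixed")
        rankTableVoxels(table, pair = pairRankArg) else NULL
    seeds <- repSeeds(seed, reps)
    acc <- numeric(reps)
    for (r in seq_len(reps)) {
        acc[r] <- tryCatch(
            withSeed(seeds[r],
                runRep(table, nFeatures, mode, eightFeature, theta,
                       testFrac, selection, fixedRanking, pairRankArg)),
            error = function(e) stop("repetition ", r, ": ",
                                     conditionMessage(e), call. = FALSE))
    }
    cfg <- list(nFeatures = as.integer(nFeatures),
                classes = as.integer(classLabels), mode = mode,
                eightFeature = eightFeature, theta = theta,
                reps = as.integer(reps), testFrac = testFrac,
                seed = as.integer(seed), selection = selection,
                pairRank = pairRank)
    new("McCvReport", perRepAccuracy = acc, meanAccuracy = mean(acc),
        sd = if (reps > 1) stats::sd(acc) else 0, config = cfg,
        perPair = data.frame())
}

#' Pairwise (one-to-one) decoding over all class pairs
#'
#' Runs [monteCarloCV()] for every unordered class pair — the 10
#' one-to-one combinations with 5 classes — and aggregates: the report's
#' per-repetition accuracies are the pair-wise means per repetition, and
#' a per-pair breakdown is attached. Per-pair seeds derive
#' deterministically from \code{seed}.
#'
#' @inheritParams monteCarloCV
#' @return A [McCvReport-class] with a populated per-pair breakdown
#'   (columns classA, classB, meanAccuracy, sd).
#' @export
pairwiseCV <- function(table, nFeatures, mode = c("paper", "standard"),
                       eightFeature = FALSE, theta = 1, reps = 100,
                       testFrac = 0.10, seed = 1,
                       selection = c("refit", "fixed"),
                       pairRank = FALSE) {
    mode <- match.arg(mode)
    selection <- match.arg(selection)
    pairs <- pairwiseCombinations(table@labels)
    pairSeeds <- repSeeds(seed + 1L, nrow(pairs))
    repMat <- matrix(NA_real_, reps, nrow(pairs))
    breakdown <- data.frame(classA = pairs[, 1], classB = pairs[, 2],
                            meanAccuracy = NA_real_, sd = NA_real_)
    for (p in seq_len(nrow(pairs))) {
        rep_p <- monteCarloCV(table, nFeatures,
                              classes = pairs[p, ], mode = mode,
                              eightFeature = eightFeature, theta = theta,
                              reps = reps, testFrac = testFrac,
                              seed = pairSeeds[p], selection = selection,
                              pairRank = pairRank)
        repMat[, p] <- rep_p@perRepAccuracy
        breakdown$meanAccuracy[p] <- rep_p@meanAccuracy
        breakdown$sd[p] <- rep_p@sd
    }
    acc <- rowMeans(repMat)
    cfg <- list(nFeatures = as.integer(nFeatures), mode = mode,
                eightFeature = eightFeature, theta = theta,
                reps = as.integer(reps), testFrac = testFrac,
                seed = as.integer(seed), selection = selection,
                pairRank = pairRank, protocol = "pairwise")
    new("McCvReport", perRepAccuracy = acc, meanAccuracy = mean(acc),
        sd = if (reps > 1) stats::sd(acc) else 0, config = cfg,
        perPair = breakdown)
}

#' Accuracy as a function of the number of selected voxels
#'
#' Runs [monteCarloCV()] (or [pairwiseCV()] with
#' \code{protocol = "pairwise"}) for every grid value and returns a tidy
#' curve, the protocol behind accuracy-vs-feature-count plots.
#'
#' @param table A [TrialFeatureTable-class].
#' @param nGrid Integer vector of feature counts (classically within
#'   50-5000).
#' @param protocol \code{"multiclass"} or \code{"pairwise"}.
#' @inheritParams monteCarloCV
#' @return data.frame with columns n_features, mean_accuracy, sd, reps,
#'   seed.
#' @export
featureSweep <- function(table, nGrid, protocol = c("multiclass",
                                                    "pairwise"),
                         mode = c("paper", "standard"),
                         eightFeature = FALSE, theta = 1, reps = 100,
                         testFrac = 0.10, seed = 1,
                         selection = c("refit", "fixed")) {
    protocol <- match.arg(protocol)
    mode <- match.arg(mode)
    selection <- match.arg(selection)
    nGrid <- as.integer(nGrid)
    if (max(nGrid) > ncol(table@values))
        stop("largest grid value ", max(nGrid), " exceeds the ",
             ncol(table@values), " available voxels", call. = FALSE)
    rows <- lapply(nGrid, function(n) {
        rep_n <- if (protocol == "pairwise")
            pairwiseCV(table, n, mode = mode,
                       eightFeature = eightFeature, theta = theta,
                       reps = reps, testFrac = testFrac, seed = seed,
                       selection = selection)
        else
            monteCarloCV(table, n, mode = mode,
                         eightFeature = eightFeature, theta = theta,
                         reps = reps, testFrac = testFrac, seed = seed,
                         selection = selection)
        data.frame(n_features = n, mean_accuracy = rep_n@meanAccuracy,
                   sd = rep_n@sd, reps = as.integer(reps),
                   seed = as.integer(seed))
    })
    do.call(rbind, rows)
}
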