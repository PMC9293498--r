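#' @import methods
NULL

setClassUnion("arrayOrNULL", c("array", "NULL"))

#' BoldRun: a 4-D BOLD time series
#'
#' Container for a preprocessed 4-D blood-oxygen-level-dependent (BOLD)
#' acquisition: an x-by-y-by-z-by-time voxel grid, the repetition time,
#' and an optional brain mask. Voxels are addressed by 0-based linear
#' indices with the x axis fastest, matching the on-disk NIfTI-1 layout.
#'
#' @slot data 4-D numeric array (x, y, z, time) of signal values.
#' @slot tr Repetition time in seconds (time between successive volumes).
#' @slot mask Optional 3-D logical array restricting analysis to brain
#'   voxels; \code{NULL} means all voxels.
#'
#' @seealso [makeBoldRun()], [readBoldRun()], [fitGlm()]
#' @export
setClass("BoldRun",
    representation(data = "array", tr = "numeric", mask = "arrayOrNULL"),
    validity = function(object) {
        msg <- character()
        if (length(dim(object@data)) != 4L)
            msg <- c(msg, "data must be a 4-D array (x, y, z, time)")
        if (length(object@tr) != 1L || !is.finite(object@tr) || object@tr <= 0)
            msg <- c(msg, "tr must be a single positive number (seconds)")
        if (!is.null(object@mask)) {
            if (!identical(dim(object@mask), dim(object@data)[1:3]))
                msg <- c(msg, "mask dimensions must equal the spatial grid")
            if (!is.logical(object@mask))
                msg <- c(msg, "mask must be logical")
        }
        if (length(msg)) msg else TRUE
    })

#' DesignMatrix: labeled GLM design
#'
#' A J-by-L design matrix for the voxel-wise general linear model, with a
#' kind label per column: \code{condition} or \code{trial} regressors are
#' HRF-convolved stimulus time courses, \code{nuisance} columns pass
#' through unconvolved, and exactly one \code{baseline} column (constant 1)
#' models the session mean.
#'
#' @slot X Numeric matrix, time points (rows) by regressors (columns).
#' @slot labels data.frame with columns \code{name} and \code{kind}
#'   (one row per design column).
#' @slot tr Repetition time in seconds.
#'
#' @seealso [buildDesignMatrix()], [fitGlm()]
#' @export
setClass("DesignMatrix",
    representation(X = "matrix", labels = "data.frame", tr = "numeric"),
    validity = function(object) {
        msg <- character()
        if (nrow(object@labels) != ncol(object@X))
            msg <- c(msg, "one label row per design column required")
        if (!all(c("name", "kind") %in% names(object@labels)))
            msg <- c(msg, "labels need 'name' and 'kind' columns")
        else {
            if (!all(object@labels$kind %in%
                     c("condition", "trial", "nuisance", "baseline")))
                msg <- c(msg, "kind must be condition/trial/nuisance/baseline")
            if (sum(object@labels$kind == "baseline") > 1L)
                msg <- c(msg, "at most one baseline column allowed")
        }
        if (nrow(object@X) <= ncol(object@X))
            msg <- c(msg, "need more time points than regressors (J > L)")
        if (length(msg)) msg else TRUE
    })

#' GlmFit: per-voxel OLS estimates
#'
#' Ordinary-least-squares fit of a [DesignMatrix-class] to every (masked)
#' voxel: coefficient matrix, residual variances and degrees of freedom.
#'
#' @slot beta L-by-V matrix of coefficients (regressors by voxels).
#' @slot sigma2 Length-V vector of residual variances (RSS / dof).
#' @slot dof Residual degrees of freedom, J - rank(X).
#' @slot design The [DesignMatrix-class] that was fitted.
#' @slot voxelIndices 0-based linear indices of the fitted voxels.
#' @slot gridDim Spatial grid dimensions of the source run.
#'
#' @seealso [fitGlm()], [tContrast()], [trialBetas()]
#' @export
setClass("GlmFit",
    representation(beta = "matrix", sigma2 = "numeric", dof = "numeric",
                   design = "DesignMatrix", voxelIndices = "integer",
                   gridDim = "integer"),
    validity = function(object) {
        msg <- character()
        if (object@dof <= 0) msg <- c(msg, "dof must be positive")
        if (any(object@sigma2 < 0)) msg <- c(msg, "sigma2 must be >= 0")
        if (ncol(object@beta) != length(object@sigma2))
            msg <- c(msg, "beta columns must match sigma2 length")
        if (length(object@voxelIndices) != length(object@sigma2))
            msg <- c(msg, "voxelIndices must match fitted voxel count")
        if (length(msg)) msg else TRUE
    })

#' TStatMap: voxel-wise t statistics for a contrast
#'
#' @slot t t value per fitted voxel.
#' @slot contrast The contrast vector c applied to the coefficients.
#' @slot dof Degrees of freedom of the t distribution.
#' @slot voxelIndices 0-based linear indices matching \code{t}.
#' @slot gridDim Spatial grid dimensions.
#' @slot flagged Logical per voxel: TRUE where the residual variance was
#'   zero and t was assigned a signed infinity.
#'
#' @seealso [tContrast()], [rankVoxels()]
#' @export
setClass("TStatMap",
    representation(t = "numeric", contrast = "numeric", dof = "numeric",
                   voxelIndices = "integer", gridDim = "integer",
                   flagged = "logical"))

#' VoxelSet: an ordered voxel selection
#'
#' Ordered 0-based linear voxel indices retained by feature selection,
#' together with a description of the contrast that ranked them.
#'
#' @slot indices Ordered unique 0-based linear voxel indices.
#' @slot sourceContrast Free-text description of the ranking statistic.
#'
#' @seealso [selectTopN()], [buildTrialTable()]
#' @export
setClass("VoxelSet",
    representation(indices = "integer", sourceContrast = "character"),
    validity = function(object) {
        if (anyDuplicated(object@indices)) "voxel indices must be unique"
        else TRUE
    })

#' TrialFeatureTable: trials-by-voxels beta features
#'
#' The pre-cumulant feature space: one row per trial, one column per
#' selected voxel, holding trial-wise GLM beta estimates, plus the class
#' label and trial id of each row.
#'
#' @slot values trials-by-voxels numeric matrix of beta values.
#' @slot labels Integer class label per trial (1..n_classes).
#' @slot trialIds Unique integer id per trial.
#' @slot voxelSet [VoxelSet-class] describing the columns.
#'
#' @seealso [buildTrialTable()], [makeBetaTable()], [transformTable()]
#' @export
setClass("TrialFeatureTable",
    representation(values = "matrix", labels = "integer",
                   trialIds = "integer", voxelSet = "VoxelSet"),
    validity = function(object) {
        msg <- character()
        if (anyNA(object@values)) msg <- c(msg, "values must have no NA")
        if (nrow(object@values) != length(object@labels))
            msg <- c(msg, "one label per trial row required")
        if (nrow(object@values) != length(object@trialIds))
            msg <- c(msg, "one trial id per row required")
        if (anyDuplicated(object@trialIds))
            msg <- c(msg, "trial ids must be unique")
        if (length(object@labels) && !length(unique(object@labels)))
            msg <- c(msg, "label set must be non-empty")
        if (length(object@voxelSet@indices) &&
            length(object@voxelSet@indices) != ncol(object@values))
            msg <- c(msg, "voxel set size must match column count")
        if (length(msg)) msg else TRUE
    })

#' CumulantFeatureTable: per-trial moment/cumulant features
#'
#' Each trial's selected-voxel beta vector compressed to at most eight
#' moment/cumulant features (psi20, psi21, psi40, psi41, psi42, optionally
#' the raw moments m20, m21, m42).
#'
#' @slot values trials-by-features numeric matrix with named columns.
#' @slot labels Integer class label per trial.
#' @slot trialIds Unique integer id per trial.
#' @slot mode Cumulant convention used: \code{"paper"} or \code{"standard"}
#'   (see [cumulantFeatures()]).
#'
#' @seealso [transformTable()], [fitDecoder()]
#' @export
setClass("CumulantFeatureTable",
    representation(values = "matrix", labels = "integer",
                   trialIds = "integer", mode = "character"),
    validity = function(object) {
        msg <- character()
        if (nrow(object@values) != length(object@labels))
            msg <- c(msg, "one label per row required")
        if (ncol(object@values) > 8L)
            msg <- c(msg, "at most eight features allowed")
        if (is.null(colnames(object@values)))
            msg <- c(msg, "feature columns must be named")
        if (length(msg)) msg else TRUE
    })

#' KdeDensity: Gaussian-kernel density estimate
#'
#' Nonparametric density for one (class, feature) pair: the training
#' values plus a Silverman-rule bandwidth. Densities are floored at a tiny
#' positive bound when evaluated so likelihood ratios stay finite.
#'
#' @slot samples Training values.
#' @slot bandwidth Positive kernel bandwidth.
#'
#' @seealso [fitKde()], [kdeDensityAt()]
#' @export
setClass("KdeDensity",
    representation(samples = "numeric", bandwidth = "numeric"),
    validity = function(object) {
        if (object@bandwidth <= 0) "bandwidth must be positive" else TRUE
    })

#' LrbsfModel: trained likelihood-ratio score-fusion decoder
#'
#' Per-class, per-feature kernel densities over standardized cumulant
#' features, the standardization statistics (training-set mean/sd), and
#' the decision threshold theta of the binary likelihood-ratio rule.
#'
#' @slot classes Integer class labels the model knows.
#' @slot densities List (one element per class) of lists (one
#'   [KdeDensity-class] per feature).
#' @slot theta Decision threshold of the likelihood-ratio test (> 0).
#' @slot featureNames Feature column names, in scoring order.
#' @slot center,scale Training-set mean and sd applied to test vectors.
#'
#' @seealso [fitDecoder()], [likelihoodRatio()], [predictMulticlass()]
#' @export
setClass("LrbsfModel",
    representation(classes = "integer", densities = "list",
                   theta = "numeric", featureNames = "character",
                   center = "numeric", scale = "numeric"),
    validity = function(object) {
        msg <- character()
        if (object@theta <= 0) msg <- c(msg, "theta must be > 0")
        if (length(object@densities) != length(object@classes))
            msg <- c(msg, "one density list per class required")
        ok <- vapply(object@densities, function(d)
            length(d) == length(object@featureNames), logical(1))
        if (!all(ok))
            msg <- c(msg, "every class needs a density for every feature")
        if (length(msg)) msg else TRUE
    })

#' McCvReport: Monte-Carlo cross-validation summary
#'
#' @slot perRepAccuracy Accuracy (percent) of each repetition.
#' @slot meanAccuracy Arithmetic mean of the per-repetition accuracies.
#' @slot sd Standard deviation of the per-repetition accuracies.
#' @slot config Echo of the configuration that produced the report.
#' @slot perPair Per-pair breakdown (data.frame) for pairwise protocols,
#'   or a zero-row data.frame otherwise.
#'
#' @seealso [monteCarloCV()], [pairwiseCV()], [writeReport()]
#' @export
setClass("McCvReport",
    representation(perRepAccuracy = "numeric", meanAccuracy = "numeric",
                   sd = "numeric", config = "list", perPair = "data.frame"),
    validity = function(object) {
        msg <- character()
        if (any(object@perRepAccuracy < 0 | object@perRepAccuracy > 100))
            msg <- c(msg, "accuracies must lie in [0, 100]")
        if (length(object@perRepAccuracy) &&
            abs(object@meanAccuracy - mean(object@perRepAccuracy)) > 1e-8)
            msg <- c(msg, "meanAccuracy must equal mean(perRepAccuracy)")
        if (length(msg)) msg else TRUE
    })

setMethod("show", "BoldRun", function(object) {
    d <- dim(object@data)
    cat("BoldRun:", paste(d[1:3], collapse = " x "), "grid,",
        d[4], "volumes, TR =", object@tr, "s\n")
    if (!is.null(object@mask))
        cat("  mask:", sum(object@mask), "of", prod(d[1:3]), "voxels\n")
})

setMethod("show", "DesignMatrix", function(object) {
    cat("DesignMatrix:", nrow(object@X), "time points x",
        ncol(object@X), "regressors (TR =", object@tr, "s)\n")
    print(table(object@labels$kind))
})

setMethod("show", "GlmFit", function(object) {
    cat("GlmFit:", nrow(object@beta), "coefficients x",
        ncol(object@beta), "voxels, dof =", object@dof, "\n")
})

setMethod("show", "TStatMap", function(object) {
    cat("TStatMap:", length(object@t), "voxels, dof =", object@dof,
        "; |t| range", sprintf("%.3g..%.3g", min(abs(object@t)),
                               max(abs(object@t))), "\n")
})

setMethod("show", "VoxelSet", function(object) {
    cat("VoxelSet:", length(object@indices), "voxels (",
        object@sourceContrast, ")\n")
})

setMethod("show", "TrialFeatureTable", function(object) {
    cat("TrialFeatureTable:", nrow(object@values), "trials x",
        ncol(object@values), "voxels;",
        length(unique(object@labels)), "classes\n")
})

setMethod("show", "CumulantFeatureTable", function(object) {
    cat("CumulantFeatureTable:", nrow(object@values), "trials x",
        ncol(object@values), "features [",
        paste(colnames(object@values), collapse = ", "),
        "] mode =", object@mode, "\n")
})

setMethod("show", "LrbsfModel", function(object) {
    cat("LrbsfModel:", length(object@classes), "classes x",
        length(object@featureNames), "features =",
        length(object@classes) * length(object@featureNames),
        "densities; theta =", object@theta, "\n")
})

setMethod("show", "McCvReport", function(object) {
    cat(sprintf("McCvReport: mean accuracy %.2f%% (sd %.2f) over %d reps\n",
                object@meanAccuracy, object@sd,
                length(object@perRepAccuracy)))
    if (nrow(object@perPair))
        cat("  pairwise tasks:", nrow(object@perPair), "\n")
})

#' @describeIn BoldRun-class the 4-D signal array.
#' @param bold A [BoldRun-class].
#' @export
boldData <- function(bold) bold@data

#' @describeIn BoldRun-class the repetition time in seconds.
#' @export
boldTr <- function(bold) bold@tr

#' @describeIn BoldRun-class the brain mask (or NULL).
#' @export
boldMask <- function(bold) bold@mask

#' @describeIn DesignMatrix-class the raw design matrix.
#' @param design A [DesignMatrix-class].
#' @export
designMatrix <- function(design) design@X

#' @describeIn DesignMatrix-class the per-column name/kind labels.
#' @export
designLabels <- function(design) design@labels

#' @describeIn VoxelSet-class the ordered 0-based voxel indices.
#' @param vs A [VoxelSet-class].
#' @export
voxelIndices <- function(vs) vs@indices

#' @describeIn TrialFeatureTable-class the trials-by-features matrix.
#' @param x A [TrialFeatureTable-class] or [CumulantFeatureTable-class].
#' @export
featureValues <- function(x) x@values

#' @describeIn TrialFeatureTable-class integer class label per trial.
#' @export
trialLabels <- function(x) x@labels

#' @describeIn TrialFeatureTable-class integer id per trial.
#' @export
trialIds <- function(x) x@trialIds

#' @describeIn McCvReport-class per-repetition accuracies (percent).
#' @param report A [McCvReport-class].
#' @export
perRepAccuracy <- function(report) report@perRepAccuracy

#' @describeIn McCvReport-class mean accuracy (percent).
#' @export
meanAccuracy <- function(report) report@meanAccuracy

#' @describeIn McCvReport-class per-pair accuracy breakdown.
#' @export
perPairAccuracy <- function(report) report@perPair
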