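# Hard lower bound on evaluated densities: keeps likelihood ratios
# finite for test points far outside the training support.
.DENSITY_FLOOR <- 1e-300

#' Fit a Gaussian-kernel density estimate
#'
#' Nonparametric class-conditional density for one feature: a Gaussian
#' kernel at every training value with Silverman's rule-of-thumb
#' bandwidth \eqn{h = 0.9 \min(sd, IQR/1.34) n^{-1/5}}. If one of the
#' two spread measures is zero the other is used; if all samples are
#' identical the bandwidth falls back to \code{1e-3 * (|value| + 1)}
#' (reported via a message).
#'
#' @param samples Numeric training values (>= 2 recommended).
#' @return A [KdeDensity-class].
#' @examples
#' k <- fitKde(rnorm(100))
#' kdeDensityAt(k, c(-1, 0, 1))
#' @export
fitKde <- function(samples) {
    samples <- as.numeric(samples)
    if (!length(samples)) stop("no samples", call. = FALSE)
    n <- length(samples)
    sdv <- if (n > 1) stats::sd(samples) else 0
    iqr <- stats::IQR(samples) / 1.34
    spread <- min(sdv, iqr)
    if (spread == 0) spread <- max(sdv, iqr)
    if (spread == 0) {
        bw <- 1e-3 * (abs(samples[1]) + 1)
        message("degenerate KDE sample (all values identical); ",
                "fallback bandwidth ", signif(bw, 3))
    } else {
        bw <- 0.9 * spread * n^(-1/5)
    }
    new("KdeDensity", samples = samples, bandwidth = bw)
}

#' Evaluate a kernel density estimate
#'
#' Mean of Gaussian kernels over the training samples, floored at a tiny
#' positive bound so log-likelihoods stay finite.
#'
#' @param kde A [KdeDensity-class].
#' @param y Evaluation points.
#' @return Density values, elementwise \code{>= 1e-300}.
#' @export
kdeDensityAt <- function(kde, y) {
    stopifnot(is(kde, "KdeDensity"))
    h <- kde@bandwidth
    z <- outer(y, kde@samples, "-") / h
    pmax(rowMeans(stats::dnorm(z)) / h, .DENSITY_FLOOR)
}

standardizeFeatures <- function(model, y) {
    (as.numeric(y) - model@center) / model@scale
}

# Sum of per-feature log densities of a standardized feature vector
# under one class: the fused match score.
classLogScore <- function(model, z, class) {
    ci <- match(class, model@classes)
    if (is.na(ci)) stop("unknown class label: ", class, call. = FALSE)
    dens <- model@densities[[ci]]
    sum(vapply(seq_along(dens), function(k)
        log(kdeDensityAt(dens[[k]], z[k])), numeric(1)))
}

#' Train the likelihood-ratio score-fusion decoder
#'
#' For every (class, feature) pair a [KdeDensity-class] is fitted to the
#' training trials of that class. Features are standardized with the
#' training-set mean and sd (stored in the model and applied to test
#' vectors); the joint class-conditional density is the product of the
#' per-feature marginals, evaluated in the log domain.
#'
#' @param train A [CumulantFeatureTable-class] with >= 2 classes and
#'   >= 2 trials per class.
#' @param theta Decision threshold of the binary rule (> 0, default 1 =
#'   maximum-likelihood decision).
#' @return An [LrbsfModel-class].
#' @examples
#' tab <- transformTable(makeBetaTable(syntheticSpec(
#'     nClasses = 2, trialsPerClass = 20, gridShape = c(6, 6, 4),
#'     effectSize = c(0, 3), noiseSd = 0.5, seed = 5)))
#' fitDecoder(tab)
#' @export
fitDecoder <- function(train, theta = 1) {
    stopifnot(is(train, "CumulantFeatureTable"))
    if (theta <= 0) stop("theta must be > 0", call. = FALSE)
    classes <- sort(unique(train@labels))
    if (length(classes) < 2)
        stop("need at least 2 classes", call. = FALSE)
    counts <- table(train@labels)
    if (any(counts < 2))
        stop("class ", names(counts)[which(counts < 2)[1]],
             " has fewer than 2 training trials", call. = FALSE)
    V <- train@values
    center <- colMeans(V)
    scale <- apply(V, 2, stats::sd)
    scale[scale == 0] <- 1
    Z <- sweep(sweep(V, 2, center), 2, scale, "/")
    densities <- lapply(classes, function(cl) {
        rows <- train@labels == cl
        lapply(seq_len(ncol(Z)), function(k) fitKde(Z[rows, k]))
    })
    new("LrbsfModel", classes = as.integer(classes),
        densities = densities, theta = as.numeric(theta),
        featureNames = colnames(V), center = center, scale = scale)
}

#' Log likelihood ratio between two classes
#'
#' The fused score \eqn{\log LR = \sum_k [\log p_a(y_k) - \log
#' p_b(y_k)]}: the log of the likelihood-ratio statistic
#' \eqn{p(Y|H_0)/p(Y|H_1)} with class_a playing the null-hypothesis
#' role. Finite for any finite input thanks to the density floor.
#'
#' @param model An [LrbsfModel-class].
#' @param y Feature vector (unstandardized, length = number of model
#'   features).
#' @param classA,classB Class labels; classA is the H0 (numerator) side.
#' @return Log likelihood ratio (single number).
#' @export
likelihoodRatio <- function(model, y, classA, classB) {
    stopifnot(is(model, "LrbsfModel"))
    if (length(y) != length(model@featureNames))
        stop("feature vector has length ", length(y), " but the model ",
             "expects ", length(model@featureNames), call. = FALSE)
    z <- standardizeFeatures(model, y)
    classLogScore(model, z, classA) - classLogScore(model, z, classB)
}

#' Binary likelihood-ratio decision
#'
#' Accepts the null-hypothesis class (classA) iff \eqn{LR \ge \theta},
#' i.e. \eqn{\log LR \ge \log\theta}; the boundary goes to the null
#' side. With the default \eqn{\theta = 1} this is the
#' maximum-likelihood decision.
#'
#' @param logLr Log likelihood ratio (classA over classB).
#' @param theta Decision threshold (> 0).
#' @param classA,classB Labels to return.
#' @return \code{classA} or \code{classB}.
#' @export
decideBinary <- function(logLr, theta = 1, classA = 1L, classB = 2L) {
    if (theta <= 0) stop("theta must be > 0", call. = FALSE)
    if (logLr >= log(theta)) classA else classB
}

#' Multiclass decision by maximum fused score
#'
#' Returns the class whose fused log-likelihood of the test vector is
#' highest; exact ties break to the lowest class label. With two classes
#' this coincides with [decideBinary()] at theta = 1.
#'
#' @param model An [LrbsfModel-class].
#' @param y Feature vector (unstandardized).
#' @return The predicted class label.
#' @export
predictMulticlass <- function(model, y) {
    stopifnot(is(model, "LrbsfModel"))
    z <- standardizeFeatures(model, y)
    scores <- vapply(model@classes, function(cl)
        classLogScore(model, z, cl), numeric(1))
    model@classes[which.max(scores)]
}

#' Score a cumulant table with a trained decoder
#'
#' Computes per-class fused log-likelihoods for every row and the argmax
#' prediction; when the table carries labels the overall accuracy
#' (percent) is attached.
#'
#' @param model An [LrbsfModel-class].
#' @param table A [CumulantFeatureTable-class] with matching features.
#' @return List with \code{predicted} (label per row), \code{logLik}
#'   (rows x classes matrix) and \code{accuracy} (percent, or NA without
#'   labels).
#' @export
decodeTable <- function(model, table) {
    stopifnot(is(model, "LrbsfModel"), is(table, "CumulantFeatureTable"))
    if (!identical(colnames(table@values), model@featureNames))
        stop("feature columns [",
             paste(colnames(table@values), collapse = ", "),
             "] do not match the model's [",
             paste(model@featureNames, collapse = ", "), "]",
             call. = FALSE)
    V <- table@values
    Z <- sweep(sweep(V, 2, model@center), 2, model@scale, "/")
    K <- ncol(Z)
    logLik <- vapply(seq_along(model@classes), function(ci) {
        dens <- model@densities[[ci]]
        ll <- numeric(nrow(Z))
        for (k in seq_len(K))
            ll <- ll + log(kdeDensityAt(dens[[k]], Z[, k]))
        ll
    }, numeric(nrow(Z)))
    logLik <- matrix(logLik, nrow = nrow(Z),
                     dimnames = list(NULL, model@classes))
    predicted <- model@classes[max.col(logLik, ties.method = "first")]
    acc <- if (length(table@labels))
        100 * mean(predicted == table@labels) else NA_real_
    list(predicted = predicted, logLik = logLik, accuracy = acc)
}
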