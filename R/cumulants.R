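#' Empirical signal moment M_pq
#'
#' The order-(p, q) empirical moment of a signal x(n):
#' \deqn{M_{pq} = E[x(n)^{p-q} \, x^*(n)^q]}
#' with the expectation taken as the sample mean. Beta features are real,
#' so conjugation is the identity and M_pq reduces to mean(x^p); the
#' product form is still evaluated literally. Complex input is not
#' supported.
#'
#' @param x Non-empty real vector.
#' @param p,q Integer moment orders with p >= q >= 0.
#' @return The empirical moment (a single number).
#' @examples
#' empiricalMoment(c(1, -1, 1, -1), 2, 0)  # 1
#' empiricalMoment(c(2, -2, 2, -2), 4, 0)  # 16
#' @export
empiricalMoment <- function(x, p, q) {
    if (!length(x)) stop("x must be non-empty", call. = FALSE)
    if (is.complex(x))
        stop("complex signals are not supported; features are real",
             call. = FALSE)
    if (p < q || q < 0) stop("need p >= q >= 0", call. = FALSE)
    mean(x^(p - q) * x^q)
}

#' Second- and fourth-order cumulant features of a trial vector
#'
#' Compresses a trial's selected-voxel beta vector x into the cumulant
#' set \{Psi20, Psi21, Psi40, Psi41, Psi42\} built from the empirical
#' moments M20 = E[x^2], M21 = E[|x|^2], M40 = M41 = M42 = E[x^4] (all
#' fourth moments coincide for real signals; likewise Psi20 = Psi21
#' numerically).
#'
#' Two conventions are provided. \code{"paper"} (the default) evaluates
#' the published formulas verbatim:
#' \deqn{\Psi_{40} = M_{40} - 3 M_{20}^2,\quad
#'       \Psi_{41} = M_{40} - 3 M_{20} M_{21},\quad
#'       \Psi_{42} = M_{42} - M_{20}^2 - 2 M_{21}}
#' (note the unsquared M21 in Psi42). \code{"standard"} uses the
#' textbook fourth-order cumulant forms
#' \eqn{\Psi_{41} = M_{41} - 3 M_{21} M_{20}} and
#' \eqn{\Psi_{42} = M_{42} - |M_{20}|^2 - 2 M_{21}^2}, under which all
#' three fourth-order features equal the excess kurtosis numerator
#' \eqn{E[x^4] - 3 E[x^2]^2} for real x and vanish for Gaussian input.
#'
#' @param x Non-empty real vector (one trial's selected-voxel betas).
#' @param mode \code{"paper"} or \code{"standard"}.
#' @param eightFeature Append the raw moments M20, M21, M42 to reach the
#'   maximal eight-feature set.
#' @return Named numeric vector of 5 (default) or 8 features.
#' @examples
#' cumulantFeatures(c(2, -2, 2, -2))
#' #  psi40 = 16 - 3*16 = -32; psi42 = 16 - 16 - 2*4 = -8
#' @export
cumulantFeatures <- function(x, mode = c("paper", "standard"),
                             eightFeature = FALSE) {
    mode <- match.arg(mode)
    if (!length(x)) stop("x must be non-empty", call. = FALSE)
    m20 <- empiricalMoment(x, 2, 0)
    m21 <- mean(abs(x)^2)
    m40 <- empiricalMoment(x, 4, 0)
    m41 <- empiricalMoment(x, 4, 1)
    m42 <- empiricalMoment(x, 4, 2)
    psi20 <- m20
    psi21 <- m21
    psi40 <- m40 - 3 * m20^2
    if (mode == "paper") {
        psi41 <- m40 - 3 * m20 * m21
        psi42 <- m42 - m20^2 - 2 * m21
    } else {
        psi41 <- m41 - 3 * m21 * m20
        psi42 <- m42 - abs(m20)^2 - 2 * m21^2
    }
    out <- c(psi20 = psi20, psi21 = psi21, psi40 = psi40,
             psi41 = psi41, psi42 = psi42)
    if (eightFeature)
        out <- c(out, m20 = m20, m21 = m21, m42 = m42)
    out
}

#' Cumulant-transform a trial feature table
#'
#' Applies [cumulantFeatures()] row-wise: each trial's n-voxel beta
#' vector becomes a 5-feature (or 8-feature) cumulant row, reducing the
#' feature space from hundreds or thousands of voxels to at most eight
#' numbers per trial. Labels and trial ids are preserved. All-zero trial
#' rows are allowed (they map to a zero feature row) and reported via a
#' message as degenerate.
#'
#' @param table A [TrialFeatureTable-class].
#' @param mode Cumulant convention, see [cumulantFeatures()].
#' @param eightFeature Emit the 8-feature variant.
#' @param zscoreTrials Z-score each trial vector across voxels before
#'   computing moments (off by default).
#' @return A [CumulantFeatureTable-class].
#' @examples
#' tab <- makeBetaTable(syntheticSpec(nClasses = 2, trialsPerClass = 5,
#'                                    gridShape = c(6, 6, 4), seed = 3))
#' transformTable(tab)
#' @export
transformTable <- function(table, mode = c("paper", "standard"),
                           eightFeature = FALSE, zscoreTrials = FALSE) {
    mode <- match.arg(mode)
    stopifnot(is(table, "TrialFeatureTable"))
    V <- table@values
    if (!nrow(V)) stop("table is empty", call. = FALSE)
    if (zscoreTrials) {
        mu <- rowMeans(V)
        sdv <- sqrt(pmax(rowMeans(V^2) - mu^2, 0) *
                    ncol(V) / max(ncol(V) - 1, 1))
        sdv[sdv == 0] <- 1
        V <- (V - mu) / sdv
    }
    degenerate <- rowSums(V != 0) == 0
    if (any(degenerate))
        message(sum(degenerate),
                " all-zero trial vector(s) produced zero feature rows")
    # vectorized row-wise moments (real signals)
    m2 <- rowMeans(V^2)
    m4 <- rowMeans(V^4)
    psi40 <- m4 - 3 * m2^2
    if (mode == "paper") {
        psi41 <- m4 - 3 * m2 * m2
        psi42 <- m4 - m2^2 - 2 * m2
    } else {
        psi41 <- m4 - 3 * m2 * m2
        psi42 <- m4 - 3 * m2^2
    }
    out <- cbind(psi20 = m2, psi21 = m2, psi40 = psi40,
                 psi41 = psi41, psi42 = psi42)
    if (eightFeature)
        out <- cbind(out, m20 = m2, m21 = m2, m42 = m4)
    new("CumulantFeatureTable", values = out, labels = table@labels,
        trialIds = table@trialIds, mode = mode)
}
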