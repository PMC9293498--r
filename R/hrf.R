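#' Canonical double-gamma hemodynamic response function
#'
#' The canonical HRF used throughout: a gamma density peaking at 6 s minus
#' a 16 s undershoot gamma scaled by 1/6, the standard two-gamma shape of
#' event-related fMRI analysis. The returned kernel is scaled so that the
#' response to a 1-second unit boxcar peaks at 1, which makes simulated
#' effect sizes read directly as peak signal amplitude.
#'
#' @param t Time grid in seconds (t >= 0).
#' @return HRF values on \code{t}.
#' @examples
#' t <- seq(0, 32, by = 0.1)
#' h <- canonicalHrf(t)
#' t[which.max(h)]  # close to 6 s
#' @export
canonicalHrf <- function(t) {
    h <- stats::dgamma(t, shape = 6, rate = 1) -
         stats::dgamma(t, shape = 16, rate = 1) / 6
    h / .hrfUnitPeak()
}

# Peak of a 1-s unit boxcar convolved with the raw double-gamma shape;
# cached because it is a fixed constant of the kernel.
.hrfUnitPeakCache <- new.env(parent = emptyenv())
.hrfUnitPeak <- function(dt = 0.01) {
    key <- as.character(dt)
    if (!is.null(.hrfUnitPeakCache[[key]])) return(.hrfUnitPeakCache[[key]])
    t <- seq(0, 40, by = dt)
    raw <- stats::dgamma(t, shape = 6, rate = 1) -
           stats::dgamma(t, shape = 16, rate = 1) / 6
    box <- rep(1, round(1 / dt))
    peak <- max(stats::convolve(raw, rev(box), type = "open")) * dt
    .hrfUnitPeakCache[[key]] <- peak
    peak
}

# One HRF-convolved regressor sampled at scan times. Used identically by
# the simulator (forward model) and the design builder (inverse model) so
# noiseless recovery is exact by construction.
#
# onsets/durations in seconds; returns length-nScans numeric.
hrfRegressor <- function(onsets, durations, nScans, tr, dt = 0.1) {
    stopifnot(length(onsets) == length(durations), nScans >= 1, tr > 0)
    totalT <- nScans * tr
    if (any(onsets < 0) || any(onsets + durations > totalT))
        stop("events extend beyond the run: run length ", totalT,
             " s is too short", call. = FALSE)
    m <- ceiling(totalT / dt) + 1L
    s <- numeric(m)
    for (i in seq_along(onsets)) {
        a <- floor(onsets[i] / dt) + 1L
        b <- max(a, ceiling((onsets[i] + durations[i]) / dt))
        s[a:min(b, m)] <- 1
    }
    h <- canonicalHrf(seq(0, 32, by = dt)) * dt
    conv <- stats::convolve(s, rev(h), type = "open")[seq_len(m)]
    conv[round((seq_len(nScans) - 1L) * tr / dt) + 1L]
}

# Regressor matrix (nScans x nEvents or nScans x nGroups).
# groups: integer vector mapping events to columns (e.g. condition id or
# trial index); one column per unique group level, in sorted order.
hrfRegressorMatrix <- function(onsets, durations, groups, nScans, tr,
                               dt = 0.1) {
    lev <- sort(unique(groups))
    X <- vapply(lev, function(g) {
        sel <- groups == g
        hrfRegressor(onsets[sel], durations[sel], nScans, tr, dt)
    }, numeric(nScans))
    colnames(X) <- as.character(lev)
    X
}
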