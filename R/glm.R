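#' Build a GLM design matrix from an event table
#'
#' In \code{"condition"} mode the design has one HRF-convolved regressor
#' per stimulus condition — with 5 conditions, 6 nuisance columns and the
#' baseline this is the classic 12-regressor layout. In
#' \code{"beta_series"} mode every trial gets its own HRF-convolved
#' regressor (least-squares-all estimation), which is how the per-trial
#' beta features for decoding are obtained. Nuisance columns (e.g. motion
#' realignment parameters) are appended unconvolved; the baseline is a
#' constant-1 column.
#'
#' @param events data.frame with columns onset, duration, condition,
#'   trial_id (seconds; conditions 1..K; unique trial ids).
#' @param nScans Number of volumes in the run.
#' @param tr Repetition time in seconds.
#' @param mode \code{"condition"} or \code{"beta_series"}.
#' @param nuisance Optional nScans-by-m matrix of nuisance regressors.
#' @return A [DesignMatrix-class].
#' @examples
#' ev <- data.frame(onset = c(8, 20, 32), duration = 1,
#'                  condition = c(1, 2, 1), trial_id = 1:3)
#' d <- buildDesignMatrix(ev, nScans = 40, tr = 2, mode = "condition")
#' d  # 2 conditions + baseline = 3 regressors
#' @export
buildDesignMatrix <- function(events, nScans, tr,
                              mode = c("condition", "beta_series"),
                              nuisance = NULL) {
    mode <- match.arg(mode)
    stopifnot(all(c("onset", "duration", "condition") %in% names(events)))
    if (is.null(events$trial_id)) events$trial_id <- seq_len(nrow(events))
    if (max(events$onset + events$duration) > nScans * tr)
        stop("events extend beyond the run (", nScans * tr, " s)",
             call. = FALSE)
    groups <- if (mode == "condition") events$condition
              else events$trial_id
    Xs <- hrfRegressorMatrix(events$onset, events$duration, groups,
                             nScans, tr)
    prefix <- if (mode == "condition") "cond" else "trial"
    labels <- data.frame(
        name = paste0(prefix, colnames(Xs)),
        kind = if (mode == "condition") "condition" else "trial",
        stringsAsFactors = FALSE)
    X <- Xs
    if (!is.null(nuisance)) {
        nuisance <- as.matrix(nuisance)
        if (nrow(nuisance) != nScans)
            stop("nuisance must have nScans rows", call. = FALSE)
        if (ncol(nuisance) > 0) {
            nn <- colnames(nuisance)
            if (is.null(nn)) nn <- paste0("nuis", seq_len(ncol(nuisance)))
            X <- cbind(X, nuisance)
            labels <- rbind(labels, data.frame(name = nn,
                                               kind = "nuisance"))
        }
    }
    X <- cbind(X, 1)
    labels <- rbind(labels, data.frame(name = "baseline",
                                       kind = "baseline"))
    colnames(X) <- labels$name
    design <- new("DesignMatrix", X = X, labels = labels,
                  tr = as.numeric(tr))
    checkDesignRank(design)  # fail early with column names
    design
}

# Rank check: tolerance 1e-10 relative to the largest singular value;
# names the offending columns via QR column pivoting.
checkDesignRank <- function(design) {
    X <- design@X
    d <- svd(X, nu = 0, nv = 0)$d
    rank <- sum(d > 1e-10 * d[1])
    if (rank < ncol(X)) {
        qrX <- qr(X, tol = 1e-10 * d[1] / sqrt(nrow(X)))
        bad <- qrX$pivot[seq(qrX$rank + 1L, ncol(X))]
        stop("design matrix is rank deficient (rank ", rank, " < ",
             ncol(X), "); collinear columns: ",
             paste(design@labels$name[bad], collapse = ", "),
             call. = FALSE)
    }
    invisible(rank)
}

#' Fit the voxel-wise general linear model by ordinary least squares
#'
#' Per (masked) voxel, solves beta = argmin ||Y - X beta||^2 via QR
#' decomposition and records the residual variance RSS / dof with
#' dof = J - rank(X). Deterministic; errors on a time-dimension mismatch
#' or a rank-deficient design.
#'
#' @param bold A [BoldRun-class] whose time dimension equals nrow(X).
#' @param design A [DesignMatrix-class].
#' @return A [GlmFit-class].
#' @examples
#' spec <- syntheticSpec(nClasses = 2, trialsPerClass = 3,
#'                       gridShape = c(6, 6, 4), noiseSd = 0, seed = 9)
#' run <- makeBoldRun(spec)
#' d <- buildDesignMatrix(run$events, dim(boldData(run$bold))[4],
#'                        boldTr(run$bold), mode = "beta_series")
#' fit <- fitGlm(run$bold, d)
#' max(abs(trialBetas(fit) - run$truth))  # ~ 0
#' @export
fitGlm <- function(bold, design) {
    stopifnot(is(bold, "BoldRun"), is(design, "DesignMatrix"))
    d4 <- dim(bold@data)
    X <- design@X
    if (d4[4] != nrow(X))
        stop("run has ", d4[4], " volumes but design has ", nrow(X),
             " rows", call. = FALSE)
    checkDesignRank(design)
    nvox <- prod(d4[1:3])
    Y <- t(matrix(bold@data, nvox, d4[4]))  # time x voxels
    vox <- if (is.null(bold@mask)) seq_len(nvox) else which(bold@mask)
    if (!length(vox)) stop("mask is empty", call. = FALSE)
    Y <- Y[, vox, drop = FALSE]
    qrX <- qr(X)
    beta <- qr.coef(qrX, Y)
    res <- Y - X %*% beta
    dof <- nrow(X) - qrX$rank
    sigma2 <- colSums(res^2) / dof
    # residual variance at round-off level (noiseless interpolation) is
    # reported as an exact zero so downstream t maps can flag it
    sigma2[sigma2 < 1e-20 * colMeans(Y^2)] <- 0
    rownames(beta) <- design@labels$name
    new("GlmFit", beta = beta, sigma2 = as.numeric(sigma2), dof = dof,
        design = design, voxelIndices = as.integer(vox - 1L),
        gridDim = as.integer(d4[1:3]))
}

#' Extract the trial-by-voxel beta matrix from a beta-series fit
#'
#' @param fit A [GlmFit-class] from a \code{"beta_series"} design.
#' @return trials-by-voxels matrix, rows in trial-id order.
#' @export
trialBetas <- function(fit) {
    stopifnot(is(fit, "GlmFit"))
    sel <- fit@design@labels$kind == "trial"
    if (!any(sel))
        stop("fit has no trial regressors; use mode = 'beta_series'",
             call. = FALSE)
    fit@beta[sel, , drop = FALSE]
}

#' Assemble a TrialFeatureTable from a beta-series fit
#'
#' Pairs the trial-wise betas with the class labels of the event table.
#'
#' @param fit A beta-series [GlmFit-class].
#' @param events The event table the design was built from.
#' @return A [TrialFeatureTable-class] over the fitted voxels.
#' @export
trialBetaTable <- function(fit, events) {
    B <- t(trialBetas(fit))          # voxels x trials
    sel <- fit@design@labels$kind == "trial"
    ids <- as.integer(sub("^trial", "", fit@design@labels$name[sel]))
    ord <- order(ids)
    B <- t(B[, ord, drop = FALSE])   # trials x voxels, id order
    ids <- ids[ord]
    lab <- events$condition[match(ids, events$trial_id)]
    vs <- new("VoxelSet", indices = fit@voxelIndices,
              sourceContrast = "beta-series fit voxels")
    new("TrialFeatureTable", values = B, labels = as.integer(lab),
        trialIds = ids, voxelSet = vs)
}

#' Voxel-wise t statistic for a contrast of GLM coefficients
#'
#' t = c'beta / sqrt(sigma2 * c'(X'X)^-1 c) per voxel, with
#' dof = J - rank(X). Voxels with zero residual variance get a signed
#' infinite t and are flagged.
#'
#' @param fit A [GlmFit-class].
#' @param contrast Numeric contrast vector of length L (nonzero).
#' @return A [TStatMap-class].
#' @examples
#' # condition-vs-baseline: +1 on the condition column, 0 elsewhere
#' @export
tContrast <- function(fit, contrast) {
    stopifnot(is(fit, "GlmFit"))
    contrast <- as.numeric(contrast)
    if (length(contrast) != nrow(fit@beta))
        stop("contrast length ", length(contrast),
             " != number of regressors ", nrow(fit@beta), call. = FALSE)
    if (all(contrast == 0)) stop("contrast must be nonzero", call. = FALSE)
    X <- fit@design@X
    XtXinv <- chol2inv(chol(crossprod(X)))
    cvar <- drop(t(contrast) %*% XtXinv %*% contrast)
    eff <- drop(crossprod(contrast, fit@beta))
    se <- sqrt(fit@sigma2 * cvar)
    t <- ifelse(se > 0, eff / se, sign(eff) * Inf)
    # on zero-variance voxels an effect at round-off scale is a zero
    effTol <- sqrt(.Machine$double.eps) * max(abs(eff), 1)
    t[se == 0 & abs(eff) <= effTol] <- 0
    new("TStatMap", t = as.numeric(t), contrast = contrast,
        dof = fit@dof, voxelIndices = fit@voxelIndices,
        gridDim = fit@gridDim, flagged = se == 0)
}

#' Condition-average contrast vector
#'
#' Convenience: equal weight on every condition (or trial) regressor,
#' zero on nuisance and baseline — the pooled activation-vs-baseline
#' contrast used for voxel ranking.
#'
#' @param design A [DesignMatrix-class].
#' @return Numeric contrast vector.
#' @export
pooledContrast <- function(design) {
    kind <- design@labels$kind
    sel <- kind %in% c("condition", "trial")
    if (!any(sel)) stop("design has no task regressors", call. = FALSE)
    ifelse(sel, 1 / sum(sel), 0)
}
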