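#' Rank voxels by absolute t statistic
#'
#' Sorts voxels by |t| in decreasing order; exact ties fall back to
#' ascending linear index, giving a deterministic total order. An
#' optional uncorrected-p pre-filter (two-sided, Student t with the
#' map's dof) can drop sub-threshold voxels before ranking; it is off by
#' default so selection stays purely rank-based.
#'
#' @param tmap A [TStatMap-class].
#' @param mask Optional logical vector/array over the grid restricting
#'   candidates.
#' @param alpha Optional uncorrected p-value threshold (e.g. 0.001);
#'   \code{NULL} disables the pre-filter.
#' @return Integer vector of 0-based voxel indices, best first.
#' @examples
#' # |t| = (0.1, 5, 3) -> order: voxel with 5, then 3, then 0.1
#' @export
rankVoxels <- function(tmap, mask = NULL, alpha = NULL) {
    stopifnot(is(tmap, "TStatMap"))
    t <- tmap@t
    idx <- tmap@voxelIndices
    if (!is.null(mask)) {
        keep <- as.logical(mask)[idx + 1L]
        if (!any(keep)) stop("mask is empty", call. = FALSE)
        t <- t[keep]; idx <- idx[keep]
    }
    if (!is.null(alpha)) {
        thr <- stats::qt(1 - alpha / 2, df = tmap@dof)
        keep <- abs(t) > thr
        t <- t[keep]; idx <- idx[keep]
    }
    ord <- order(-abs(t), idx)
    idx[ord]
}

#' Take the top-N voxels of a ranking
#'
#' Selection is rank-based, not threshold-based: the first \code{n}
#' entries of the ranking are returned regardless of their t values.
#' The emulated protocol explores 50-5000 features; by default those
#' bounds are enforced (overridable for small desk examples).
#'
#' @param ranked Integer vector of ranked 0-based voxel indices.
#' @param n Number of voxels to keep.
#' @param enforceLimits Require 50 <= n <= 5000 (default TRUE).
#' @return A [VoxelSet-class] of size \code{n}, in ranking order.
#' @export
selectTopN <- function(ranked, n, enforceLimits = TRUE) {
    n <- as.integer(n)
    if (n > length(ranked))
        stop("requested ", n, " voxels but only ", length(ranked),
             " are ranked", call. = FALSE)
    if (enforceLimits && (n < 50L || n > 5000L))
        stop("n = ", n, " outside the 50-5000 feature range; pass ",
             "enforceLimits = FALSE to override", call. = FALSE)
    new("VoxelSet", indices = as.integer(ranked[seq_len(n)]),
        sourceContrast = paste0("top-", n, " by |t|"))
}

#' Subset a trial table to a voxel set
#'
#' Columns are taken in voxel-set order, so permuting the set permutes
#' the columns identically.
#'
#' @param table A [TrialFeatureTable-class] (columns = voxels).
#' @param voxelSet A [VoxelSet-class] whose indices refer to the same
#'   grid as \code{table}'s voxel set.
#' @return A [TrialFeatureTable-class] with \code{length(voxelSet)}
#'   columns.
#' @export
buildTrialTable <- function(table, voxelSet) {
    stopifnot(is(table, "TrialFeatureTable"), is(voxelSet, "VoxelSet"))
    pos <- match(voxelSet@indices, table@voxelSet@indices)
    if (anyNA(pos))
        stop("voxel indices not present in the table: ",
             paste(utils::head(voxelSet@indices[is.na(pos)], 5),
                   collapse = ", "), call. = FALSE)
    new("TrialFeatureTable",
        values = table@values[, pos, drop = FALSE],
        labels = table@labels, trialIds = table@trialIds,
        voxelSet = voxelSet)
}

# One-sample t per column (mean against zero): the fold-internal ranking
# statistic for trial-beta tables, equivalent to pooled
# condition-vs-baseline since trial betas are already baseline-relative.
columnTStats <- function(values) {
    n <- nrow(values)
    m <- colMeans(values)
    v <- (colSums(values^2) - n * m^2) / (n - 1)
    v[v < 0] <- 0
    se <- sqrt(v / n)
    ifelse(se > 0, m / se, sign(m) * Inf)
}

#' Rank a trial table's voxels from training rows only
#'
#' Computes a per-voxel one-sample t statistic (mean trial beta against
#' zero, pooled over conditions) on the given rows and ranks by |t| with
#' the deterministic tie rule of [rankVoxels()]. With
#' \code{pair = c(a, b)} a two-sample t between the two classes is used
#' instead (per-pair contrast selection).
#'
#' @param table A [TrialFeatureTable-class].
#' @param rows Row indices to use (training fold); default all.
#' @param pair Optional length-2 class pair for a two-sample statistic.
#' @return Integer vector of ranked 0-based voxel indices.
#' @export
rankTableVoxels <- function(table, rows = seq_len(nrow(table@values)),
                            pair = NULL) {
    V <- table@values[rows, , drop = FALSE]
    if (is.null(pair)) {
        t <- columnTStats(V)
    } else {
        lab <- table@labels[rows]
        a <- V[lab == pair[1], , drop = FALSE]
        b <- V[lab == pair[2], , drop = FALSE]
        if (nrow(a) < 2 || nrow(b) < 2)
            stop("need >= 2 training trials per class for pairwise ",
                 "ranking", call. = FALSE)
        ma <- colMeans(a); mb <- colMeans(b)
        va <- (colSums(a^2) - nrow(a) * ma^2) / (nrow(a) - 1)
        vb <- (colSums(b^2) - nrow(b) * mb^2) / (nrow(b) - 1)
        se <- sqrt(pmax(va, 0) / nrow(a) + pmax(vb, 0) / nrow(b))
        t <- ifelse(se > 0, (ma - mb) / se, sign(ma - mb) * Inf)
    }
    idx <- table@voxelSet@indices
    idx[order(-abs(t), idx)]
}
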