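#' SyntheticSpec: parameters of the synthetic BOLD generator
#'
#' Describes an event-related acquisition with class-specific activation
#' confined to compact voxel clusters, emulating a visual-category
#' experiment: balanced stimulus classes, randomized inter-stimulus
#' intervals, canonical-HRF responses and i.i.d. Gaussian scanner noise.
#'
#' Classes differ both in where they activate (one compact cluster per
#' class, placed in a posterior "occipital-like" slab) and in how strongly
#' (per-class effect sizes). Distinct amplitudes matter downstream:
#' per-trial cumulant features are invariant to permuting voxels, so
#' classes that differed only in cluster location at equal amplitude would
#' be indistinguishable after cumulant compression.
#'
#' @slot nClasses Number of stimulus classes.
#' @slot trialsPerClass Trials per class (balanced design).
#' @slot gridShape 3 integers, the spatial voxel grid.
#' @slot tr Repetition time in seconds.
#' @slot isiRange Uniform inter-stimulus-interval range in seconds
#'   (onset-to-onset gap beyond the stimulus itself).
#' @slot stimDuration Stimulus duration in seconds.
#' @slot activeClusters List of 0-based linear voxel index vectors, one
#'   per class; empty list means auto-placed compact cubes.
#' @slot effectSize Mean beta in active voxels, recycled per class.
#' @slot noiseSd Gaussian noise standard deviation (signal units).
#' @slot baseline Constant baseline signal level.
#' @slot nScans Run length override in volumes; 0 = sized automatically
#'   from the event schedule.
#' @slot seed RNG seed; identical specs generate identical data.
#'
#' @seealso [syntheticSpec()], [makeBoldRun()], [makeBetaTable()]
#' @export
setClass("SyntheticSpec",
    representation(nClasses = "integer", trialsPerClass = "integer",
                   gridShape = "integer", tr = "numeric",
                   isiRange = "numeric", stimDuration = "numeric",
                   activeClusters = "list", effectSize = "numeric",
                   noiseSd = "numeric", baseline = "numeric",
                   nScans = "integer", seed = "integer"),
    validity = function(object) {
        msg <- character()
        if (object@nClasses < 1L) msg <- c(msg, "need at least one class")
        if (object@trialsPerClass < 1L)
            msg <- c(msg, "need at least one trial per class")
        if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
            msg <- c(msg, "gridShape must be 3 positive integers")
        if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
        if (!all(is.finite(object@effectSize)))
            msg <- c(msg, "effectSize must be finite")
        if (length(object@isiRange) != 2L ||
            object@isiRange[1] > object@isiRange[2] ||
            object@isiRange[1] < 0)
            msg <- c(msg, "isiRange must be an increasing pair >= 0")
        nvox <- prod(object@gridShape)
        if (length(object@activeClusters)) {
            if (length(object@activeClusters) != object@nClasses)
                msg <- c(msg, "one active cluster per class required")
            all_idx <- unlist(object@activeClusters)
            if (length(all_idx) &&
                (min(all_idx) < 0 || max(all_idx) >= nvox))
                msg <- c(msg, "active cluster indices outside the grid")
        }
        if (length(msg)) msg else TRUE
    })

setMethod("show", "SyntheticSpec", function(object) {
    cat("SyntheticSpec:", object@nClasses, "classes x",
        object@trialsPerClass, "trials;",
        paste(object@gridShape, collapse = " x "), "grid; TR =",
        object@tr, "s; noise sd =", object@noiseSd, "; seed =",
        object@seed, "\n")
})

#' Construct a synthetic-acquisition specification
#'
#' Defaults mirror the emulated study: 5 balanced classes, 52 trials per
#' class (260 trials total), TR = 2 s, and a desk-scale 16 x 16 x 12 grid
#' (the full 63 x 53 x 46 acquisition grid is available by passing
#' \code{gridShape = c(63, 53, 46)}). Inter-stimulus intervals are drawn
#' uniformly from 4-8 s and stimuli last 1 s. Each class activates a
#' compact 27-voxel cube in a posterior slab, with per-class amplitudes
#' evenly spaced over \code{effectSize} (recycled to \code{nClasses}).
#'
#' @param nClasses,trialsPerClass,gridShape,tr,isiRange,stimDuration,
#'   activeClusters,effectSize,noiseSd,baseline,nScans,seed See
#'   [SyntheticSpec-class].
#' @return A validated [SyntheticSpec-class].
#' @examples
#' spec <- syntheticSpec(nClasses = 2, trialsPerClass = 6, seed = 1)
#' spec
#' @export
syntheticSpec <- function(nClasses = 5, trialsPerClass = 52,
                          gridShape = c(16, 16, 12), tr = 2.0,
                          isiRange = c(4, 8), stimDuration = 1.0,
                          activeClusters = NULL,
                          effectSize = seq(0.5, 2.5,
                                           length.out = nClasses),
                          noiseSd = 1.0, baseline = 100, nScans = 0,
                          seed = 1L) {
    spec <- new("SyntheticSpec",
        nClasses = as.integer(nClasses),
        trialsPerClass = as.integer(trialsPerClass),
        gridShape = as.integer(gridShape), tr = as.numeric(tr),
        isiRange = as.numeric(isiRange),
        stimDuration = as.numeric(stimDuration),
        activeClusters = if (is.null(activeClusters)) list()
                         else lapply(activeClusters, as.integer),
        effectSize = rep_len(as.numeric(effectSize),
                             as.integer(nClasses)),
        noiseSd = as.numeric(noiseSd), baseline = as.numeric(baseline),
        nScans = as.integer(nScans), seed = as.integer(seed))
    validObject(spec)
    spec
}

# Auto-placed clusters: non-overlapping cubes in a posterior slab
# (low-y third of the grid), spaced along x then z.
defaultClusters <- function(gridShape, nClasses, size = 3L) {
    nx <- gridShape[1]; ny <- gridShape[2]; nz <- gridShape[3]
    size <- min(size, nx, ny, nz)
    y0 <- 1L  # posterior edge
    repeat {  # shrink cubes until nClasses disjoint ones fit
        xs <- seq(1L, nx - size + 1L, by = size)
        zs <- seq(1L, nz - size + 1L, by = size)
        origins <- expand.grid(x = xs, z = zs)
        if (nrow(origins) >= nClasses || size == 1L) break
        size <- size - 1L
    }
    if (nrow(origins) < nClasses)
        stop("grid too small to place ", nClasses,
             " disjoint clusters", call. = FALSE)
    lapply(seq_len(nClasses), function(c) {
        o <- origins[c, ]
        g <- expand.grid(x = o$x:(o$x + size - 1L),
                         y = y0:(y0 + size - 1L),
                         z = o$z:(o$z + size - 1L))
        as.integer((g$x - 1L) + nx * ((g$y - 1L) + ny * (g$z - 1L)))
    })
}

# Resolve clusters, recycling spec or auto-placing.
resolveClusters <- function(spec) {
    if (length(spec@activeClusters)) spec@activeClusters
    else defaultClusters(spec@gridShape, spec@nClasses)
}

# Evaluate expr under a seed, restoring the caller's RNG state after.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

# Randomized balanced event schedule. Returns the EventTable data.frame.
simulateEvents <- function(spec) {
    n <- spec@nClasses * spec@trialsPerClass
    cond <- sample(rep(seq_len(spec@nClasses), spec@trialsPerClass))
    gaps <- stats::runif(n, spec@isiRange[1], spec@isiRange[2])
    onsets <- 8 + cumsum(c(0, (spec@stimDuration + gaps)[-n]))
    data.frame(onset = onsets, duration = rep(spec@stimDuration, n),
               condition = cond, trial_id = seq_len(n))
}

# Ground-truth trial-by-voxel beta matrix for an event schedule.
groundTruthBetas <- function(spec, events) {
    clusters <- resolveClusters(spec)
    nvox <- prod(spec@gridShape)
    B <- matrix(0, nrow(events), nvox)
    for (c in seq_len(spec@nClasses)) {
        rows <- which(events$condition == c)
        B[rows, clusters[[c]] + 1L] <- spec@effectSize[c]
    }
    B
}

#' Simulate an event-related BOLD run with known ground truth
#'
#' Builds a 4-D volume voxel by voxel as the sum of trial responses
#' (trial beta times the HRF-convolved stimulus boxcar), a constant
#' baseline, and i.i.d. Gaussian noise. A voxel's trial beta equals the
#' class effect size when the voxel belongs to that class's active
#' cluster and zero otherwise. The identical regressor construction is
#' used by [buildDesignMatrix()], so fitting the GLM to a noiseless run
#' recovers the ground-truth betas to numerical precision.
#'
#' @param spec A [SyntheticSpec-class].
#' @return List with elements \code{bold} ([BoldRun-class]),
#'   \code{events} (data.frame: onset, duration, condition, trial_id) and
#'   \code{truth} (trials-by-voxels matrix of true betas).
#' @examples
#' spec <- syntheticSpec(nClasses = 2, trialsPerClass = 3,
#'                       gridShape = c(6, 6, 4), seed = 42)
#' run <- makeBoldRun(spec)
#' run$bold
#' head(run$events)
#' @export
makeBoldRun <- function(spec) {
    stopifnot(is(spec, "SyntheticSpec"))
    withSeed(spec@seed, {
        events <- simulateEvents(spec)
        lastT <- max(events$onset + events$duration)
        nScans <- if (spec@nScans > 0L) spec@nScans
                  else as.integer(ceiling((lastT + 32) / spec@tr))
        R <- hrfRegressorMatrix(events$onset, events$duration,
                                events$trial_id, nScans, spec@tr)
        truth <- groundTruthBetas(spec, events)
        nvox <- prod(spec@gridShape)
        Y <- R %*% truth + spec@baseline
        if (spec@noiseSd > 0)
            Y <- Y + matrix(stats::rnorm(nScans * nvox,
                                         sd = spec@noiseSd),
                            nScans, nvox)
        arr <- array(t(Y), dim = c(spec@gridShape, nScans))
        bold <- new("BoldRun", data = arr, tr = spec@tr, mask = NULL)
        list(bold = bold, events = events, truth = truth)
    })
}

#' Simulate a trial-by-voxel beta table directly
#'
#' Fast path that bypasses the BOLD forward model and GLM: draws each
#' trial's voxel betas as ground truth plus Gaussian noise. Useful for
#' exercising selection, cumulant compression and decoding at scale.
#'
#' @param spec A [SyntheticSpec-class]; \code{noiseSd} here is the
#'   standard deviation of the beta estimation noise.
#' @return A [TrialFeatureTable-class] over all grid voxels, with
#'   balanced class labels.
#' @examples
#' tab <- makeBetaTable(syntheticSpec(nClasses = 2, trialsPerClass = 5,
#'                                    gridShape = c(6, 6, 4), seed = 3))
#' tab
#' @export
makeBetaTable <- function(spec) {
    stopifnot(is(spec, "SyntheticSpec"))
    withSeed(spec@seed, {
        n <- spec@nClasses * spec@trialsPerClass
        labels <- rep(seq_len(spec@nClasses), spec@trialsPerClass)
        events <- data.frame(condition = labels, trial_id = seq_len(n))
        values <- groundTruthBetas(spec, events)
        if (spec@noiseSd > 0)
            values <- values + matrix(stats::rnorm(length(values),
                                                   sd = spec@noiseSd),
                                      nrow(values), ncol(values))
        nvox <- prod(spec@gridShape)
        vs <- new("VoxelSet", indices = 0:(nvox - 1L),
                  sourceContrast = "all grid voxels (synthetic)")
        new("TrialFeatureTable", values = values,
            labels = as.integer(labels),
            trialIds = seq_len(n), voxelSet = vs)
    })
}
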