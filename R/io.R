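#' Read a 4-D BOLD run from NIfTI-1
#'
#' The repetition time is taken from the header (pixdim slot 4, in
#' seconds); if the header carries no TR an explicit \code{tr} must be
#' supplied. Voxel addressing is 0-based with x fastest, matching the
#' on-disk layout. A failed or non-4-D read raises an error without
#' returning a partial object.
#'
#' @param path NIfTI-1 file (.nii or .nii.gz).
#' @param tr Optional TR override in seconds.
#' @param mask Optional path to a 3-D mask NIfTI (nonzero = in-brain).
#' @return A [BoldRun-class].
#' @export
readBoldRun <- function(path, tr = NULL, mask = NULL) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 4L)
        stop(path, " is ", length(d), "-D; a 4-D BOLD file is required",
             call. = FALSE)
    hdrTr <- RNifti::pixdim(img)[4]
    if (is.null(tr)) {
        if (!is.finite(hdrTr) || hdrTr <= 0)
            stop("no TR in the NIfTI header; pass tr= explicitly",
                 call. = FALSE)
        tr <- hdrTr
    }
    m <- NULL
    if (!is.null(mask)) {
        mi <- RNifti::readNifti(mask)
        if (!identical(dim(mi)[1:3], d[1:3]))
            stop("mask grid does not match the BOLD grid", call. = FALSE)
        m <- array(as.vector(mi) != 0, dim = d[1:3])
    }
    new("BoldRun", data = array(as.vector(img), dim = d),
        tr = as.numeric(tr), mask = m)
}

#' Write a BOLD run as NIfTI-1
#'
#' Stores the TR in pixdim slot 4 and the voxel size (default 3 mm
#' isotropic) in slots 1-3; doubles are written so a round-trip is
#' bit-identical.
#'
#' @param bold A [BoldRun-class].
#' @param path Output path (.nii or .nii.gz).
#' @param voxelSizeMm Isotropic voxel edge in millimetres.
#' @return \code{path}, invisibly.
#' @export
writeBoldRun <- function(bold, path, voxelSizeMm = 3.0) {
    stopifnot(is(bold, "BoldRun"))
    img <- RNifti::asNifti(bold@data)
    RNifti::pixdim(img) <- c(rep(voxelSizeMm, 3), bold@tr)
    RNifti::writeNifti(img, path, datatype = "double")
    invisible(path)
}

#' Write a 3-D map (e.g. per-class truth or a t map) as NIfTI-1
#'
#' @param values Numeric vector over the full grid (x-fastest order) or
#'   a 3-D array.
#' @param gridDim 3 integers (ignored when \code{values} is an array).
#' @param path Output path.
#' @param voxelSizeMm Isotropic voxel edge in millimetres.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(values, gridDim, path, voxelSizeMm = 3.0) {
    arr <- if (is.array(values) && length(dim(values)) == 3L) values
           else array(values, dim = gridDim)
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- rep(voxelSizeMm, 3)
    RNifti::writeNifti(img, path, datatype = "double")
    invisible(path)
}

#' Read an event table from TSV
#'
#' Expects a header line \code{onset  duration  condition  trial_id}
#' (trial_id optional: generated when absent). Conditions are mapped to
#' integers 1..K in first-appearance order (mapping reported via a
#' message when labels are not already integers). Rows are sorted by
#' onset, stable by trial id; overlapping trials warn, onsets beyond the
#' run error at design-build time.
#'
#' @param path TSV file.
#' @return data.frame with columns onset, duration, condition (integer),
#'   trial_id.
#' @export
readEvents <- function(path) {
    ev <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!nrow(ev)) stop("event table ", path, " is empty", call. = FALSE)
    need <- c("onset", "duration", "condition")
    if (!all(need %in% names(ev)))
        stop("event table needs columns: ",
             paste(need, collapse = ", "), call. = FALSE)
    if (is.null(ev$trial_id)) ev$trial_id <- seq_len(nrow(ev))
    if (anyDuplicated(ev$trial_id))
        stop("trial_id values must be unique", call. = FALSE)
    if (!is.numeric(ev$condition)) {
        lev <- unique(ev$condition)
        message("condition labels mapped to integers: ",
                paste(sprintf("%s=%d", lev, seq_along(lev)),
                      collapse = ", "))
        ev$condition <- match(ev$condition, lev)
    }
    ev <- ev[order(ev$onset, ev$trial_id), ]
    rownames(ev) <- NULL
    ends <- ev$onset + ev$duration
    if (any(ev$onset[-1] < ends[-nrow(ev)]))
        warning("overlapping trials in ", path)
    ev[, c("onset", "duration", "condition", "trial_id")]
}

#' Write an event table as TSV
#'
#' @param events data.frame with onset, duration, condition, trial_id.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeEvents <- function(events, path) {
    utils::write.table(
        events[, c("onset", "duration", "condition", "trial_id")],
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Trial feature table CSV round-trip
#'
#' Rows are trials; columns are the 0-based voxel indices (prefixed
#' \code{v}), followed by \code{label} and \code{trial_id}.
#'
#' @param table A [TrialFeatureTable-class].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeTrialTable <- function(table, path) {
    stopifnot(is(table, "TrialFeatureTable"))
    df <- as.data.frame(table@values)
    names(df) <- paste0("v", table@voxelSet@indices)
    df$label <- table@labels
    df$trial_id <- table@trialIds
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeTrialTable
#' @return \code{readTrialTable}: the reconstructed
#'   [TrialFeatureTable-class].
#' @export
readTrialTable <- function(path) {
    df <- utils::read.csv(path)
    stopifnot(all(c("label", "trial_id") %in% names(df)))
    vcols <- grep("^v[0-9]+$", names(df), value = TRUE)
    idx <- as.integer(sub("^v", "", vcols))
    vs <- new("VoxelSet", indices = idx,
              sourceContrast = paste0("read from ", basename(path)))
    new("TrialFeatureTable",
        values = as.matrix(df[, vcols, drop = FALSE]),
        labels = as.integer(df$label),
        trialIds = as.integer(df$trial_id), voxelSet = vs)
}

#' Cumulant feature table CSV round-trip
#'
#' Named feature columns (psi20..psi42, optional m20/m21/m42) followed
#' by \code{label} and \code{trial_id}; the cumulant mode travels in a
#' \code{# mode:} comment line.
#'
#' @param table A [CumulantFeatureTable-class].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeCumulantTable <- function(table, path) {
    stopifnot(is(table, "CumulantFeatureTable"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# mode: ", table@mode), con)
    df <- as.data.frame(table@values)
    df$label <- table@labels
    df$trial_id <- table@trialIds
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeCumulantTable
#' @return \code{readCumulantTable}: the reconstructed
#'   [CumulantFeatureTable-class].
#' @export
readCumulantTable <- function(path) {
    first <- readLines(path, n = 1)
    mode <- if (grepl("^# mode:", first))
        trimws(sub("^# mode:", "", first)) else "paper"
    df <- utils::read.csv(path, comment.char = "#")
    fcols <- setdiff(names(df), c("label", "trial_id"))
    new("CumulantFeatureTable",
        values = as.matrix(df[, fcols, drop = FALSE]),
        labels = as.integer(df$label),
        trialIds = as.integer(df$trial_id), mode = mode)
}

#' Serialize a cross-validation report
#'
#' JSON (full report: config echo, per-repetition accuracies, summary,
#' per-pair breakdown) or CSV (one row per repetition). Identical
#' reports serialize to identical bytes, so determinism can be checked
#' on the files themselves.
#'
#' @param report A [McCvReport-class].
#' @param path Output path; format chosen by extension (.json or .csv).
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(report, path) {
    stopifnot(is(report, "McCvReport"))
    if (grepl("\\.json$", path)) {
        obj <- list(config = report@config,
                    mean_accuracy = report@meanAccuracy,
                    sd = report@sd,
                    per_rep_accuracy = report@perRepAccuracy)
        if (nrow(report@perPair)) obj$per_pair <- report@perPair
        jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                             dataframe = "rows")
    } else {
        utils::write.csv(
            data.frame(rep = seq_along(report@perRepAccuracy),
                       accuracy = report@perRepAccuracy),
            path, row.names = FALSE, quote = FALSE)
    }
    invisible(path)
}

#' Read a pipeline configuration (YAML or JSON)
#'
#' Missing keys fall back to documented defaults; numeric fields are
#' range-checked. The configuration round-trips losslessly through
#' [writePipelineConfig()].
#'
#' @param path YAML (.yaml/.yml) or JSON (.json) file.
#' @return Named list with the full configuration.
#' @export
readPipelineConfig <- function(path) {
    cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                 simplifyVector = TRUE)
           else yaml::read_yaml(path)
    defaults <- list(nClasses = 5L, trialsPerClass = 52L,
                     gridShape = c(16L, 16L, 12L), tr = 2.0,
                     effectSize = NULL, noiseSd = 1.0,
                     nFeatures = 450L, mode = "paper",
                     eightFeature = FALSE, theta = 1.0, reps = 100L,
                     testFrac = 0.10, seed = 1L, selection = "refit",
                     protocol = "pairwise", bold = NULL, events = NULL,
                     mask = NULL, betas = NULL)
    for (k in names(defaults))
        if (is.null(cfg[[k]])) cfg[k] <- defaults[k]
    stopifnot(cfg$testFrac > 0, cfg$testFrac < 1, cfg$reps >= 1,
              cfg$theta > 0, cfg$nFeatures >= 1,
              cfg$mode %in% c("paper", "standard"),
              cfg$selection %in% c("refit", "fixed"),
              cfg$protocol %in% c("pairwise", "multiclass"))
    cfg
}

#' @rdname readPipelineConfig
#' @param cfg Configuration list.
#' @param path Output path (.yaml or .json).
#' @export
writePipelineConfig <- function(cfg, path) {
    if (grepl("\\.json$", path))
        jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
    else yaml::write_yaml(cfg, path)
    invisible(path)
}
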