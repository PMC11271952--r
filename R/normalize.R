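#' Normalized task volumes
#'
#' Container for the output of the normalization chain: a volume x voxel
#' matrix plus per-volume metadata.
#'
#' @slot data volume x voxel matrix
#' @slot meta data.frame of per-volume metadata (trial/item/phase/run)
#' @slot roi ROI label
#' @slot task task label
#' @slot center,scale the task-level per-voxel z parameters used in step 4
#'   (empty when step 4 was not applied)
#'
#' @exportClass NormalizedVolumes
setClass("NormalizedVolumes", representation(
    data = "matrix", meta = "data.frame", roi = "character",
    task = "character", center = "numeric", scale = "numeric"))

setValidity("NormalizedVolumes", function(object) {
    if (nrow(object@data) != nrow(object@meta))
        return("meta must have one row per volume")
    TRUE
})

setMethod("show", "NormalizedVolumes", function(object) {
    cat(sprintf("NormalizedVolumes: %s/%s — %d volumes x %d voxels\n",
                object@task, object@roi, nrow(object@data),
                ncol(object@data)))
})

# z-score columns of a matrix; constant columns map to zero (with a
# warning when warn = TRUE)
.zcols <- function(x, warn = FALSE, what = "column") {
    mu <- colMeans(x)
    sd <- apply(x, 2, stats::sd)
    bad <- !is.finite(sd) | sd == 0
    if (any(bad) && warn)
        warning(sum(bad), " constant ", what, "(s) mapped to zero")
    sd[bad] <- Inf
    scale(x, center = mu, scale = sd)[, , drop = FALSE]
}

# steps 1-2 for one run: per-voxel z across time, then per-volume z across
# voxels; returns volume x voxel matrix
.runZ <- function(run) {
    x <- t(boldData(run))            # volumes x voxels
    x <- .zcols(x, warn = TRUE, what = "voxel")   # step 1
    t(.zcols(t(x)))                  # step 2: z within each volume
}

#' Select task volumes per trial and phase
#'
#' Implements the TR-selection conventions: for the localizer and the
#' encoding phase, the third TR after picture onset (the volume starting
#' two TRs, i.e. 4 s, after the onset volume); for maintenance, the two
#' TRs beginning 4 s after the second cue onset (averaged downstream);
#' per-TR mode returns the volumes for TR0..TR3 of the trial (TR0 covers
#' the 1-s fixation and 1-s first cue), each with the same two-TR
#' hemodynamic shift.
#'
#' @param events attention-task events (\code{\link{attentionEvents}}) or
#'   localizer events (\code{\link{localizerEvents}})
#' @param tr repetition time (s)
#' @param phase \code{"encoding"}, \code{"maintenance"}, \code{"per-tr"}
#'   or \code{"localizer"}
#' @return data.frame with one row per trial (x TR in per-TR mode):
#'   \code{row} (row index into \code{events}), \code{phase}, \code{v1}
#'   and \code{v2} (1-based volume indices; \code{v2} is NA except for
#'   maintenance). Catch trials are skipped for attention phases.
#' @export
selectPhaseVolumes <- function(events, tr = 2,
                               phase = c("encoding", "maintenance",
                                         "per-tr", "localizer")) {
    phase <- match.arg(phase)
    events <- as.data.frame(events)
    if (phase == "localizer") {
        onset <- events$onset
        .checkGrid(onset, tr, events$item)
        return(data.frame(row = seq_len(nrow(events)), phase = "localizer",
                          v1 = onset / tr + 3, v2 = NA_integer_))
    }
    keep <- which(!events$is_catch)
    onset <- events$onset[keep]
    .checkGrid(onset, tr, paste0("run ", events$run[keep],
                                 " trial ", events$trial[keep]))
    base <- onset / tr + 1          # 1-based onset volume
    if (phase == "encoding") {
        data.frame(row = keep, phase = "encoding", v1 = base + 3,
                   v2 = NA_integer_)
    } else if (phase == "maintenance") {
        data.frame(row = keep, phase = "maintenance", v1 = base + 4,
                   v2 = base + 5)
    } else {
        do.call(rbind, lapply(0:3, function(k)
            data.frame(row = keep, phase = paste0("TR", k),
                       v1 = base + k + 2, v2 = NA_integer_)))
    }
}

.checkGrid <- function(onset, tr, what) {
    off <- abs(onset / tr - round(onset / tr)) > 1e-9
    if (any(off))
        stop("onset not on the TR grid for: ",
             paste(utils::head(what[off], 3), collapse = ", "))
}

#' The z-scoring normalization chain
#'
#' Ordered chain applied to a task's runs: (1) each voxel is z-scored
#' across time within each run; (2) each volume is z-scored across voxels;
#' (3) the phase-specific volumes are selected (the two maintenance TRs
#' are averaged into one row); (4) each voxel is z-scored across all
#' selected volumes of the task. Constant voxels or volumes map to zeros
#' with a warning.
#'
#' @param runs list of \code{\linkS4class{BoldRun}} for one ROI and task
#' @param selection data.frame as returned by
#'   \code{\link{selectPhaseVolumes}} plus a \code{run} column naming each
#'   row's run, and any metadata columns to carry through; if NULL, all
#'   volumes of all runs are retained (step 3 skipped)
#' @param step4 apply the task-level per-voxel z (step 4); disable when
#'   the caller applies fold-specific parameters
#' @return a \code{\linkS4class{NormalizedVolumes}}; rows follow
#'   \code{selection}.
#' @export
normalizeChain <- function(runs, selection = NULL, step4 = TRUE) {
    if (!is.list(runs)) runs <- list(runs)
    stopifnot(length(runs) >= 1)
    for (r in runs)
        if (ncol(r) < 2 || nrow(r) < 2)
            stop("need at least 2 volumes and 2 voxels per run")
    runIds <- vapply(runs, function(r) as.character(runLabel(r)), "")
    zByRun <- lapply(runs, .runZ)
    names(zByRun) <- runIds
    if (is.null(selection)) {
        data <- do.call(rbind, zByRun)
        meta <- data.frame(run = rep(runIds, vapply(zByRun, nrow, 1L)))
    } else {
        selection <- as.data.frame(selection)
        stopifnot("run" %in% colnames(selection))
        rows <- lapply(seq_len(nrow(selection)), function(i) {
            z <- zByRun[[as.character(selection$run[i])]]
            v1 <- selection$v1[i]; v2 <- selection$v2[i]
            if (v1 > nrow(z) || (!is.na(v2) && v2 > nrow(z)))
                stop("selected volume beyond run end (row ", i, ")")
            if (is.na(v2)) z[v1, ] else (z[v1, ] + z[v2, ]) / 2
        })
        data <- do.call(rbind, rows)
        meta <- selection
    }
    if (nrow(data) < 2) stop("fewer than 2 selected volumes")
    center <- numeric(); scl <- numeric()
    if (step4) {
        center <- colMeans(data)
        scl <- apply(data, 2, stats::sd)
        bad <- !is.finite(scl) | scl == 0
        scl[bad] <- Inf
        data <- scale(data, center = center, scale = scl)[, , drop = FALSE]
        scl[bad] <- 0
    }
    new("NormalizedVolumes", data = unname(data), meta = meta,
        roi = roiLabel(runs[[1]]), task = taskLabel(runs[[1]]),
        center = center, scale = scl)
}
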