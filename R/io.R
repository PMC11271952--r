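# External interfaces: BIDS-style events TSV, NIfTI volumes/masks via
# RNifti, YAML configuration, CSV result tables.

#' Read and write BIDS-style events tables
#'
#' Events are written as tab-separated text with an \code{onset} and
#' \code{duration} column first, missing values as \code{"n/a"}.
#'
#' @param events any of the package's event data.frames
#' @param path file path (.tsv)
#' @return \code{readEventsTsv} returns the data.frame.
#' @export
writeEventsTsv <- function(events, path) {
    events <- as.data.frame(events)
    first <- intersect(c("onset", "duration"), colnames(events))
    events <- events[, c(first, setdiff(colnames(events), first))]
    utils::write.table(events, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "n/a")
    invisible(path)
}

#' @rdname writeEventsTsv
#' @export
readEventsTsv <- function(path) {
    utils::read.table(path, header = TRUE, sep = "\t", na.strings = "n/a",
                      stringsAsFactors = FALSE)
}

# lay V voxels out on a near-cubic 3-D grid
.voxelGrid <- function(V) {
    nx <- ceiling(V^(1 / 3))
    ny <- ceiling(sqrt(V / nx))
    nz <- ceiling(V / (nx * ny))
    c(nx, ny, nz)
}

#' Write and read a BOLD run as NIfTI + confounds
#'
#' The ROI's voxels are laid out on a compact 3-D grid; the run is stored
#' as a 4-D NIfTI (time as 4th axis) with the TR in the pixdim, the ROI
#' mask as a 3-D NIfTI of 0/1 labels, and motion/FD as a confounds TSV.
#'
#' @param run a \code{\linkS4class{BoldRun}}
#' @param prefix path prefix; writes \code{<prefix>_bold.nii.gz},
#'   \code{<prefix>_mask.nii.gz} and \code{<prefix>_confounds.tsv}
#' @return (invisibly) the bold path; \code{readBoldRun} reconstructs the
#'   \code{BoldRun} from the three files.
#' @export
writeBoldRun <- function(run, prefix) {
    x <- boldData(run)
    V <- nrow(x); nT <- ncol(x)
    dims <- .voxelGrid(V)
    arr <- array(0, c(dims, nT))
    mask <- array(0L, dims)
    mask[seq_len(V)] <- 1L
    for (t in seq_len(nT)) {
        vol <- array(0, dims)
        vol[seq_len(V)] <- x[, t]
        arr[, , , t] <- vol
    }
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(1, 1, 1, repetitionTime(run))
    RNifti::writeNifti(img, paste0(prefix, "_bold.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(mask), paste0(prefix, "_mask.nii.gz"))
    conf <- data.frame(motionParams(run))
    colnames(conf) <- paste0("motion", 1:6)
    conf$fd <- framewiseDisplacement(run)
    utils::write.table(conf, paste0(prefix, "_confounds.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(paste0(prefix, "_bold.nii.gz"))
}

#' @param prefix path prefix used by \code{writeBoldRun}
#' @param roi,runId,task metadata to attach on read
#' @rdname writeBoldRun
#' @export
readBoldRun <- function(prefix, roi, runId, task) {
    arr <- RNifti::readNifti(paste0(prefix, "_bold.nii.gz"))
    mask <- RNifti::readNifti(paste0(prefix, "_mask.nii.gz"))
    tr <- RNifti::pixdim(arr)[4]
    sel <- which(as.array(mask) != 0)
    nT <- dim(arr)[4]
    x <- matrix(NA_real_, length(sel), nT)
    for (t in seq_len(nT)) {
        vol <- as.array(arr[, , , t, drop = FALSE])
        x[, t] <- vol[sel]
    }
    conf <- utils::read.table(paste0(prefix, "_confounds.tsv"),
                              header = TRUE, sep = "\t")
    boldRun(x, tr = tr, roi = roi, run = runId, task = task,
            motion = as.matrix(conf[, paste0("motion", 1:6)]),
            fd = conf$fd)
}

#' Write and read single-trial pattern sets
#'
#' Patterns are stored as a 4-D NIfTI (trial as 4th axis, voxels on the
#' compact grid) plus a CSV manifest mapping volume index to trial
#' metadata.
#'
#' @param patterns a \code{\linkS4class{TrialPatternSet}}
#' @param prefix path prefix; writes \code{<prefix>_tmaps.nii.gz} and
#'   \code{<prefix>_manifest.csv}
#' @return (invisibly) the NIfTI path; \code{readTrialPatterns}
#'   reconstructs the object.
#' @export
writeTrialPatterns <- function(patterns, prefix) {
    x <- patternData(patterns)
    V <- nrow(x); n <- ncol(x)
    dims <- .voxelGrid(V)
    arr <- array(0, c(dims, n))
    for (t in seq_len(n)) {
        vol <- array(0, dims)
        vol[seq_len(V)] <- ifelse(is.na(x[, t]), 0, x[, t])
        arr[, , , t] <- vol
    }
    RNifti::writeNifti(RNifti::asNifti(arr), paste0(prefix, "_tmaps.nii.gz"))
    man <- patternInfo(patterns)
    man$volume <- seq_len(n)
    man$nVoxels <- V
    man$roi <- roiLabel(patterns)
    utils::write.csv(man, paste0(prefix, "_manifest.csv"),
                     row.names = FALSE)
    invisible(paste0(prefix, "_tmaps.nii.gz"))
}

#' @rdname writeTrialPatterns
#' @export
readTrialPatterns <- function(prefix) {
    arr <- RNifti::readNifti(paste0(prefix, "_tmaps.nii.gz"))
    man <- utils::read.csv(paste0(prefix, "_manifest.csv"))
    V <- man$nVoxels[1]
    n <- dim(arr)[4]
    x <- matrix(NA_real_, V, n)
    for (t in seq_len(n)) {
        vol <- as.array(arr[, , , t, drop = FALSE])
        x[, t] <- vol[seq_len(V)]
    }
    x[, !man$ok] <- NA_real_
    info <- man[, setdiff(colnames(man), c("volume", "nVoxels", "roi"))]
    trialPatternSet(x, info, roi = man$roi[1])
}

#' Write and read the simulation configuration and ground truth as YAML
#'
#' @param config a \code{\linkS4class{SimulationConfig}}
#' @param truth a \code{\linkS4class{GroundTruth}}
#' @param path YAML file path
#' @return \code{readSimulationYaml} returns
#'   \code{list(config, truth)}.
#' @export
writeSimulationYaml <- function(config, truth, path) {
    asList <- function(obj) {
        sl <- methods::slotNames(class(obj))
        out <- lapply(sl, function(s) {
            v <- methods::slot(obj, s)
            if (is(v, "HrfParams")) lapply(methods::slotNames(v), function(q)
                methods::slot(v, q))
            else if (is.null(names(v))) v
            else as.list(v)
        })
        names(out) <- sl
        if ("hrf" %in% sl)
            names(out$hrf) <- methods::slotNames("HrfParams")
        out
    }
    yaml::write_yaml(list(config = asList(config), truth = asList(truth)),
                     path)
    invisible(path)
}

#' @rdname writeSimulationYaml
#' @export
readSimulationYaml <- function(path) {
    y <- yaml::read_yaml(path)
    cfg <- y$config
    cfg$hrf <- do.call(hrfParams, cfg$hrf)
    cfg$trialTiming <- unlist(cfg$trialTiming)
    config <- do.call(simulationConfig, cfg)
    tr <- y$truth
    for (nm in c("gainAttended", "gainIgnored", "ignoredRoiScale",
                 "repulsionRho", "behaviorHitMeans", "confHighProb"))
        tr[[nm]] <- unlist(tr[[nm]])
    truth <- do.call(groundTruth, tr)
    list(config = config, truth = truth)
}
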