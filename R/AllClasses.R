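#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

.CUE_GROUPS <- c("BL", "PA", "PI", "RA", "RI")
.CONDITIONS <- c("prospective", "retrospective", "baseline")

#' Double-gamma HRF parameters
#'
#' Canonical double-gamma hemodynamic response function parameters
#' (SPM/FSL convention): the response is the difference of two gamma
#' densities, the second (undershoot) scaled down by
#' \code{peakUndershootRatio}.
#'
#' @slot peakDelay time to peak of the positive lobe (s)
#' @slot undershootDelay time to peak of the undershoot (s)
#' @slot peakDispersion dispersion of the positive lobe (s)
#' @slot undershootDispersion dispersion of the undershoot (s)
#' @slot peakUndershootRatio ratio of peak to undershoot amplitude
#' @slot duration length of sampled kernel support (s); must cover >= 30 s
#'
#' @exportClass HrfParams
setClass("HrfParams", representation(
    peakDelay = "numeric",
    undershootDelay = "numeric",
    peakDispersion = "numeric",
    undershootDispersion = "numeric",
    peakUndershootRatio = "numeric",
    duration = "numeric"
))

setValidity("HrfParams", function(object) {
    vals <- c(object@peakDelay, object@undershootDelay, object@peakDispersion,
              object@undershootDispersion, object@peakUndershootRatio,
              object@duration)
    if (any(!is.finite(vals)) || any(vals <= 0))
        return("all HRF parameters must be positive and finite")
    if (object@duration < 30)
        return("kernel duration must cover at least 30 s")
    TRUE
})

#' @param peakDelay,undershootDelay,peakDispersion,undershootDispersion,peakUndershootRatio,duration
#'   see slot documentation.
#' @return \code{hrfParams()} returns an \code{HrfParams} object.
#' @rdname HrfParams-class
#' @export
hrfParams <- function(peakDelay = 6, undershootDelay = 16,
                      peakDispersion = 1, undershootDispersion = 1,
                      peakUndershootRatio = 6, duration = 32) {
    new("HrfParams", peakDelay = peakDelay, undershootDelay = undershootDelay,
        peakDispersion = peakDispersion,
        undershootDispersion = undershootDispersion,
        peakUndershootRatio = peakUndershootRatio, duration = duration)
}

#' Simulation configuration
#'
#' Holds the study geometry of the synthetic cohort: the selective-attention
#' task (1-s fixation, 1-s cue, 2-s encoding, 4-s maintenance epochs; catch
#' probes on one-sixth of trials; five cue-attention item groups BL/PA/PI/
#' RA/RI), the block localizer (mini-blocks of 10 pictures x 2 s separated
#' by 8-s Gabor blocks), the recognition test (2-s fixation + 4-s picture),
#' and the ROI geometry. Defaults reproduce the published study layout at
#' its original size; tests and examples typically shrink
#' \code{nItemsPerCondition}, \code{nVoxels} and \code{nSubjects}.
#'
#' @slot nSubjects number of subjects in the cohort
#' @slot nVoxels voxels per ROI
#' @slot roiNames ROI labels (default dLPC, vLPC, VTC)
#' @slot nCategories number of picture categories (3: face, scene, object)
#' @slot nItemsPerCondition items per cue-attention group (divisible by
#'   \code{nCategories} and by \code{nRunsAttention/2})
#' @slot nRunsAttention,nRunsLocalizer,nRunsRecognition run counts
#' @slot tr repetition time (s)
#' @slot trialTiming named durations (s) for fixation/cue/encode/maintain
#' @slot itiSeconds inter-trial interval (s), a multiple of \code{tr}
#' @slot catchFraction fraction of attention trials that are catch probes
#' @slot noiseSd Gaussian noise SD (signal units) added to every volume
#' @slot motionCoupling SD of per-voxel loadings on the motion traces
#' @slot fdSpikeRate per-volume probability of a motion spike (drives FD
#'   excursions above the 0.3 mm censoring threshold)
#' @slot noResponseRate probability a recognition trial has no response
#' @slot hrf an \code{\linkS4class{HrfParams}} object
#' @slot lssEpoch which 2-s window the single-trial recognition GLM models:
#'   \code{"trial"} (from trial start, i.e. fixation-to-picture-onset) or
#'   \code{"stimulus"} (first 2 s of the picture)
#' @slot repulsionAtEncoding also inject pattern repulsion into
#'   attention-task (encoding) signals, not only retrieval patterns
#' @slot seed integer seed; all randomness derives from it
#'
#' @exportClass SimulationConfig
setClass("SimulationConfig", representation(
    nSubjects = "integer",
    nVoxels = "integer",
    roiNames = "character",
    nCategories = "integer",
    nItemsPerCondition = "integer",
    nRunsAttention = "integer",
    nRunsLocalizer = "integer",
    nRunsRecognition = "integer",
    tr = "numeric",
    trialTiming = "numeric",
    itiSeconds = "numeric",
    catchFraction = "numeric",
    noiseSd = "numeric",
    motionCoupling = "numeric",
    fdSpikeRate = "numeric",
    noResponseRate = "numeric",
    hrf = "HrfParams",
    lssEpoch = "character",
    repulsionAtEncoding = "logical",
    seed = "integer"
))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    counts <- c(object@nSubjects, object@nVoxels, object@nCategories,
                object@nItemsPerCondition, object@nRunsAttention,
                object@nRunsLocalizer, object@nRunsRecognition)
    if (any(counts < 1L)) msg <- c(msg, "all counts must be >= 1")
    if (object@nCategories < 2L) msg <- c(msg, "need at least 2 categories")
    if (object@tr <= 0) msg <- c(msg, "tr must be positive")
    if (object@catchFraction < 0 || object@catchFraction >= 1)
        msg <- c(msg, "catchFraction must lie in [0, 1)")
    if (!identical(names(object@trialTiming),
                   c("fixation", "cue", "encode", "maintain")))
        msg <- c(msg, "trialTiming must be named fixation/cue/encode/maintain")
    if (object@nItemsPerCondition %% object@nCategories != 0L)
        msg <- c(msg, "nItemsPerCondition must be divisible by nCategories")
    if (object@nRunsAttention %% 2L != 0L)
        msg <- c(msg, "nRunsAttention must be even (two presentation rounds)")
    if (object@nItemsPerCondition %% (object@nRunsAttention / 2L) != 0L)
        msg <- c(msg, "nItemsPerCondition must be divisible by nRunsAttention/2")
    if (object@tr > 0 && object@itiSeconds %% object@tr != 0)
        msg <- c(msg, "itiSeconds must be a multiple of tr (onset grid)")
    if (!object@lssEpoch %in% c("trial", "stimulus"))
        msg <- c(msg, "lssEpoch must be 'trial' or 'stimulus'")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' @param nSubjects,nVoxels,roiNames,nCategories,nItemsPerCondition,nRunsAttention,nRunsLocalizer,nRunsRecognition,tr,trialTiming,itiSeconds,catchFraction,noiseSd,motionCoupling,fdSpikeRate,noResponseRate,hrf,lssEpoch,repulsionAtEncoding,seed
#'   see slot documentation.
#' @return \code{simulationConfig()} returns a \code{SimulationConfig}.
#' @rdname SimulationConfig-class
#' @export
simulationConfig <- function(nSubjects = 27, nVoxels = 60,
                             roiNames = c("dLPC", "vLPC", "VTC"),
                             nCategories = 3, nItemsPerCondition = 30,
                             nRunsAttention = 6, nRunsLocalizer = 3,
                             nRunsRecognition = 4, tr = 2,
                             trialTiming = c(fixation = 1, cue = 1,
                                             encode = 2, maintain = 4),
                             itiSeconds = 2, catchFraction = 1 / 6,
                             noiseSd = 18, motionCoupling = 0.5,
                             fdSpikeRate = 0.02, noResponseRate = 0.02,
                             hrf = hrfParams(), lssEpoch = "trial",
                             repulsionAtEncoding = FALSE, seed = 1) {
    new("SimulationConfig",
        nSubjects = as.integer(nSubjects), nVoxels = as.integer(nVoxels),
        roiNames = roiNames, nCategories = as.integer(nCategories),
        nItemsPerCondition = as.integer(nItemsPerCondition),
        nRunsAttention = as.integer(nRunsAttention),
        nRunsLocalizer = as.integer(nRunsLocalizer),
        nRunsRecognition = as.integer(nRunsRecognition),
        tr = tr, trialTiming = trialTiming, itiSeconds = itiSeconds,
        catchFraction = catchFraction, noiseSd = noiseSd,
        motionCoupling = motionCoupling, fdSpikeRate = fdSpikeRate,
        noResponseRate = noResponseRate, hrf = hrf, lssEpoch = lssEpoch,
        repulsionAtEncoding = repulsionAtEncoding, seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@nSubjects, "subjects,",
        object@nVoxels, "voxels x", length(object@roiNames), "ROIs (",
        paste(object@roiNames, collapse = ", "), ")\n")
    cat("  attention:", object@nRunsAttention, "runs,",
        object@nItemsPerCondition, "items/cue-attention group, catch",
        sprintf("%.3f", object@catchFraction), "\n")
    cat("  localizer:", object@nRunsLocalizer,
        "runs; recognition:", object@nRunsRecognition, "runs; TR",
        object@tr, "s; noise SD", object@noiseSd, "; seed",
        object@seed, "\n")
})

#' Ground-truth simulation parameters
#'
#' The effect structure injected into a synthetic cohort: multiplicative
#' attentional gains on category signal by cue condition and phase,
#' per-ROI scaling of the prospective-ignored (filtered) signal,
#' pair-specific representational repulsion at retrieval, and the
#' behavioral hit/false-alarm/confidence parameters.
#'
#' @slot gainAttended named (prospective, retrospective) gain applied to the
#'   attended item once the effective cue is available
#' @slot gainIgnored named (prospective, retrospective) gain for the ignored
#'   item after the effective cue
#' @slot gainBaseline gain for the single baseline item
#' @slot gainRetroEncoding shared gain for both items during retrospective
#'   encoding (cue not yet shown)
#' @slot ignoredRoiScale named per-ROI multiplier on the
#'   prospective-ignored gain (default zeroes parietal ROIs, keeps VTC)
#' @slot repulsionRho named (prospective, retrospective) proportion in [0,1]
#'   by which an old item's retrieval signal component parallel to its
#'   co-presented partner is shrunk
#' @slot behaviorHitMeans named hit probabilities for BL/PA/PI/RA/RI
#' @slot falseAlarmRate probability a novel item is judged old
#' @slot confHighProb named probability that a hit is high-confidence
#' @slot itemSd SD of item-specific voxel components (category prototypes
#'   have SD 1)
#' @slot commonAmp amplitude of the stimulus-evoked component shared by
#'   all stimuli within an ROI; it gives any two trial patterns a
#'   positive baseline correlation, as observed in real data, which the
#'   pair-specific repulsion then reduces
#' @slot signalAmplitude overall scaling of the neural signal
#'
#' @exportClass GroundTruth
setClass("GroundTruth", representation(
    gainAttended = "numeric",
    gainIgnored = "numeric",
    gainBaseline = "numeric",
    gainRetroEncoding = "numeric",
    ignoredRoiScale = "numeric",
    repulsionRho = "numeric",
    behaviorHitMeans = "numeric",
    falseAlarmRate = "numeric",
    confHighProb = "numeric",
    itemSd = "numeric",
    commonAmp = "numeric",
    signalAmplitude = "numeric"
))

setValidity("GroundTruth", function(object) {
    msg <- character()
    gains <- c(object@gainAttended, object@gainIgnored, object@gainBaseline,
               object@gainRetroEncoding, object@ignoredRoiScale)
    if (any(gains < 0)) msg <- c(msg, "gains must be >= 0")
    if (any(object@repulsionRho < 0 | object@repulsionRho > 1))
        msg <- c(msg, "repulsionRho must lie in [0, 1]")
    if (object@commonAmp < 0) msg <- c(msg, "commonAmp must be >= 0")
    pr <- c(object@behaviorHitMeans, object@falseAlarmRate,
            object@confHighProb)
    if (any(pr < 0 | pr > 1))
        msg <- c(msg, "hit means, false-alarm rate and confidence probabilities must lie in [0, 1]")
    if (!all(.CUE_GROUPS %in% names(object@behaviorHitMeans)))
        msg <- c(msg, "behaviorHitMeans must name all of BL, PA, PI, RA, RI")
    for (s in c("gainAttended", "gainIgnored", "repulsionRho"))
        if (!all(c("prospective", "retrospective") %in% names(slot(object, s))))
            msg <- c(msg, paste(s, "must name prospective and retrospective"))
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' @param gainAttended,gainIgnored,gainBaseline,gainRetroEncoding,ignoredRoiScale,repulsionRho,behaviorHitMeans,falseAlarmRate,confHighProb,itemSd,signalAmplitude
#'   see slot documentation.
#' @return \code{groundTruth()} returns a \code{GroundTruth}.
#' @rdname GroundTruth-class
#' @export
groundTruth <- function(gainAttended = c(prospective = 1.0, retrospective = 0.8),
                        gainIgnored = c(prospective = 0.3, retrospective = 0.5),
                        gainBaseline = 1.0, gainRetroEncoding = 0.7,
                        ignoredRoiScale = c(dLPC = 0, vLPC = 0, VTC = 1),
                        repulsionRho = c(prospective = 0.3, retrospective = 0),
                        behaviorHitMeans = c(BL = 0.80, PA = 0.80, PI = 0.35,
                                             RA = 0.70, RI = 0.55),
                        falseAlarmRate = 0.20,
                        confHighProb = c(BL = 0.70, PA = 0.70, PI = 0.40,
                                         RA = 0.55, RI = 0.50),
                        itemSd = 1, commonAmp = 1, signalAmplitude = 1) {
    new("GroundTruth", gainAttended = gainAttended, gainIgnored = gainIgnored,
        gainBaseline = gainBaseline, gainRetroEncoding = gainRetroEncoding,
        ignoredRoiScale = ignoredRoiScale, repulsionRho = repulsionRho,
        behaviorHitMeans = behaviorHitMeans, falseAlarmRate = falseAlarmRate,
        confHighProb = confHighProb, itemSd = itemSd,
        commonAmp = commonAmp, signalAmplitude = signalAmplitude)
}

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth: gains att(pro/retro) =",
        paste(object@gainAttended, collapse = "/"),
        " ign =", paste(object@gainIgnored, collapse = "/"),
        " BL =", object@gainBaseline, "\n")
    cat("  repulsion rho:", paste(sprintf("%s=%.2f", names(object@repulsionRho),
        object@repulsionRho), collapse = ", "), "\n")
    cat("  hit means:", paste(sprintf("%s=%.2f", names(object@behaviorHitMeans),
        object@behaviorHitMeans), collapse = ", "),
        " FA =", object@falseAlarmRate, "\n")
})

#' ROI-restricted BOLD run
#'
#' A voxel x timepoint matrix for one run within one ROI, stored as a
#' \code{SummarizedExperiment} (assay \code{"bold"}) whose column data carry
#' the frame times, six rigid-body motion traces and the per-volume
#' framewise displacement (FD, mm). Metadata record the ROI label, run id,
#' task and TR.
#'
#' @exportClass BoldRun
setClass("BoldRun", contains = "SummarizedExperiment")

setValidity("BoldRun", function(object) {
    msg <- character()
    if (!"bold" %in% SummarizedExperiment::assayNames(object))
        return("assay 'bold' is required")
    x <- SummarizedExperiment::assay(object, "bold")
    if (!all(is.finite(x))) msg <- c(msg, "bold data must be finite")
    cd <- colData(object)
    need <- c("frameTime", "fd", paste0("motion", 1:6))
    if (!all(need %in% colnames(cd)))
        msg <- c(msg, "colData must contain frameTime, fd and motion1..motion6")
    else if (any(cd$fd < 0)) msg <- c(msg, "fd must be >= 0")
    md <- metadata(object)
    if (!all(c("roi", "run", "task", "tr") %in% names(md)))
        msg <- c(msg, "metadata must contain roi, run, task, tr")
    else if (md$tr <= 0) msg <- c(msg, "tr must be positive")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' @param data voxel x timepoint numeric matrix
#' @param tr repetition time (s)
#' @param roi ROI label
#' @param run run identifier
#' @param task task label (\code{"attention"}, \code{"localizer"},
#'   \code{"recognition"}, ...)
#' @param motion timepoint x 6 matrix of rigid-body motion traces
#' @param fd per-timepoint framewise displacement (mm)
#' @return \code{boldRun()} returns a \code{BoldRun}.
#' @rdname BoldRun-class
#' @export
boldRun <- function(data, tr, roi, run, task, motion = NULL, fd = NULL) {
    data <- as.matrix(data)
    nT <- ncol(data)
    if (is.null(motion)) motion <- matrix(0, nT, 6)
    if (is.null(fd)) fd <- numeric(nT)
    stopifnot(nrow(motion) == nT, length(fd) == nT)
    cd <- DataFrame(frameTime = (seq_len(nT) - 1) * tr, fd = fd)
    for (j in 1:6) cd[[paste0("motion", j)]] <- motion[, j]
    se <- SummarizedExperiment(assays = list(bold = data), colData = cd)
    metadata(se) <- list(roi = roi, run = run, task = task, tr = tr)
    new("BoldRun", se)
}

setMethod("show", "BoldRun", function(object) {
    md <- metadata(object)
    cat(sprintf("BoldRun: ROI %s, %s run %s — %d voxels x %d volumes (TR %g s), %d censorable (FD > 0.3 mm)\n",
                md$roi, md$task, as.character(md$run), nrow(object),
                ncol(object), md$tr, sum(colData(object)$fd > 0.3)))
})

#' Single-trial pattern set
#'
#' Voxel x trial matrix of single-trial t-statistics for one ROI, stored as
#' a \code{SummarizedExperiment} (assay \code{"tstat"}); column data carry
#' the trial/item metadata and an \code{ok} flag (FALSE when the trial was
#' fully censored and its pattern is missing).
#'
#' @exportClass TrialPatternSet
setClass("TrialPatternSet", contains = "SummarizedExperiment")

setValidity("TrialPatternSet", function(object) {
    if (!"tstat" %in% SummarizedExperiment::assayNames(object))
        return("assay 'tstat' is required")
    cd <- colData(object)
    if (!all(c("item", "ok") %in% colnames(cd)))
        return("colData must contain 'item' and 'ok'")
    x <- SummarizedExperiment::assay(object, "tstat")
    bad <- !is.finite(x[, cd$ok, drop = FALSE])
    if (any(bad)) return("patterns flagged ok must be finite")
    TRUE
})

#' @param values voxel x trial matrix of t-statistics
#' @param info data.frame of per-trial metadata (must contain \code{item});
#'   an \code{ok} column is added if absent
#' @param roi ROI label
#' @param coef optional voxel x trial matrix of raw GLM coefficients,
#'   stored as a second assay
#' @return \code{trialPatternSet()} returns a \code{TrialPatternSet}.
#' @rdname TrialPatternSet-class
#' @export
trialPatternSet <- function(values, info, roi, coef = NULL) {
    values <- as.matrix(values)
    info <- as.data.frame(info)
    if (is.null(info$ok)) info$ok <- apply(is.finite(values), 2, all)
    assays <- list(tstat = values)
    if (!is.null(coef)) assays$coef <- as.matrix(coef)
    se <- SummarizedExperiment(assays = assays,
                               colData = DataFrame(info))
    metadata(se) <- list(roi = roi)
    new("TrialPatternSet", se)
}

setMethod("show", "TrialPatternSet", function(object) {
    cat(sprintf("TrialPatternSet: ROI %s — %d voxels x %d trials (%d missing)\n",
                metadata(object)$roi, nrow(object), ncol(object),
                sum(!colData(object)$ok)))
})

#' First-level design matrix
#'
#' Timepoint x regressor matrix with named columns and per-column roles
#' (\code{"task"}, \code{"nuisance"}, \code{"censor"}).
#'
#' @slot matrix timepoint x regressor numeric matrix
#' @slot frameTimes volume acquisition times (s)
#' @slot role named character vector of column roles
#'
#' @exportClass DesignMatrix
setClass("DesignMatrix", representation(
    matrix = "matrix", frameTimes = "numeric", role = "character"))

setValidity("DesignMatrix", function(object) {
    msg <- character()
    X <- object@matrix
    if (is.null(colnames(X)) || anyDuplicated(colnames(X)))
        msg <- c(msg, "columns must be uniquely named")
    if (length(object@frameTimes) != nrow(X))
        msg <- c(msg, "frameTimes must match row count")
    if (!identical(names(object@role), colnames(X)))
        msg <- c(msg, "role must be named by the columns")
    cen <- which(object@role == "censor")
    for (j in cen) {
        cj <- X[, j]
        if (!(sum(cj == 1) == 1 && sum(cj == 0) == nrow(X) - 1))
            msg <- c(msg, sprintf("censor column '%s' must be one-hot", colnames(X)[j]))
    }
    task <- which(object@role == "task")
    if (length(task) && any(colSums(abs(X[, task, drop = FALSE])) == 0))
        msg <- c(msg, "task columns must not be all zero")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

setMethod("show", "DesignMatrix", function(object) {
    tab <- table(factor(object@role, c("task", "nuisance", "censor")))
    cat(sprintf("DesignMatrix: %d volumes x %d regressors (%d task, %d nuisance, %d censor)\n",
                nrow(object@matrix), ncol(object@matrix),
                tab["task"], tab["nuisance"], tab["censor"]))
})

#' One-vs-rest L2-regularized logistic classifier
#'
#' Four binary one-vs-rest logistic classifiers (3 picture categories +
#' the Gabor/rest class) with L2 penalty; the inverse-regularization
#' constant C multiplies the data-fit term (liblinear convention).
#'
#' @slot classes class labels (length 4 in the standard pipeline)
#' @slot weights voxel x class weight matrix
#' @slot intercepts per-class intercepts
#' @slot cost inverse-regularization constant C (> 0)
#' @slot center,scale per-voxel task-level z-scoring parameters estimated on
#'   the training volumes (step 4 of the normalization chain)
#'
#' @exportClass ClassifierModel
setClass("ClassifierModel", representation(
    classes = "character", weights = "matrix", intercepts = "numeric",
    cost = "numeric", center = "numeric", scale = "numeric"))

setValidity("ClassifierModel", function(object) {
    msg <- character()
    if (object@cost <= 0) msg <- c(msg, "C must be > 0")
    if (ncol(object@weights) != length(object@classes))
        msg <- c(msg, "one weight vector per class required")
    if (length(object@intercepts) != length(object@classes))
        msg <- c(msg, "one intercept per class required")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

setMethod("show", "ClassifierModel", function(object) {
    cat(sprintf("ClassifierModel: %d classes (%s), %d voxels, C = %g\n",
                length(object@classes), paste(object@classes, collapse = ", "),
                nrow(object@weights), object@cost))
})
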