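# Synthetic ROI-level BOLD generation. The neural response of every trial
# is an HRF-convolved boxcar scaled by the attentional gain of the trial's
# phase, multiplying (category prototype + item component); motion-coupled
# nuisance and Gaussian noise are added on top. Recognition-task signals
# additionally carry pair-specific repulsion: the component of an old
# item's signal parallel to its co-presented partner is shrunk by
# (1 - rho) for the trial's cue condition.

#' Subject-level voxel patterns
#'
#' Generates, deterministically from the configuration seed, the per-ROI
#' category prototypes (columns scaled to a common norm so categories are
#' equally decodable, plus a Gabor prototype) and the item-specific
#' components for every item id used by the three tasks. Item components
#' are fixed per item across repetitions and tasks, so item identity is
#' decodable in principle.
#'
#' @param config a \code{\linkS4class{SimulationConfig}}
#' @param truth a \code{\linkS4class{GroundTruth}}
#' @param subject subject index
#' @return list with one element per ROI, each containing
#'   \code{prototypes} (voxel x (categories + gabor) matrix) and
#'   \code{items} (voxel x item matrix, columns named by item id).
#' @export
subjectPatterns <- function(config, truth, subject = 1L) {
    validObject(config); validObject(truth)
    nCat <- config@nCategories
    m <- config@nItemsPerCondition %/% nCat
    ids <- character()
    for (g in c("BL", "PA", "PI", "RA", "RI"))
        ids <- c(ids, .itemId(g, rep(seq_len(nCat), each = m),
                              rep(seq_len(m), nCat)))
    nOld <- length(ids)
    foilCat <- rep(seq_len(nCat), length.out = nOld)
    ids <- c(ids, .itemId("NOV", foilCat,
                          stats::ave(foilCat, foilCat, FUN = seq_along)))
    ids <- c(ids, .itemId("LOC", rep(seq_len(nCat), each = 30L),
                          rep(1:30, nCat)))
    f <- config@catchFraction
    perCondPerRun <- config@nItemsPerCondition %/% (config@nRunsAttention %/% 2L)
    nCatch <- as.integer(floor(3 * perCondPerRun * f / (1 - f))) *
        config@nRunsAttention
    ctIdx <- c(seq_len(max(nCatch, 1L)), 1000L + seq_len(max(nCatch, 1L)))
    ids <- c(ids, .itemId("CT", rep(seq_len(nCat), each = length(ctIdx)),
                          rep(ctIdx, nCat)))
    V <- config@nVoxels
    out <- list()
    for (roi in config@roiNames) {
        seed <- .seedFor(config, subject, paste0("patterns-", roi))
        out[[roi]] <- .withSeed(seed, {
            proto <- matrix(stats::rnorm(V * (nCat + 1L)), V, nCat + 1L)
            proto <- sweep(proto, 2, sqrt(colSums(proto^2)) / sqrt(V), "/")
            colnames(proto) <- c(.categoryNames(config), "gabor")
            items <- matrix(stats::rnorm(V * length(ids), sd = truth@itemSd),
                            V, length(ids))
            colnames(items) <- ids
            common <- stats::rnorm(V)
            common <- common / sqrt(sum(common^2)) * sqrt(V) *
                truth@commonAmp
            list(prototypes = proto, items = items, common = common)
        })
    }
    out
}

# full (un-repulsed) signal pattern of one item in one ROI; every
# stimulus carries the shared stimulus-evoked component
.itemPattern <- function(pat, id, config) {
    if (identical(id, "GABOR")) return(pat$common + pat$prototypes[, "gabor"])
    cat <- itemCategory(id, config)
    pat$common + pat$prototypes[, cat] + pat$items[, id]
}

# Motion traces (AR(1) with occasional spikes) and the framewise
# displacement derived from them: FD = sum |d trans| + 50 mm * sum |d rot|.
.simulateMotion <- function(nT, config, seed) {
    .withSeed(seed, {
        mot <- matrix(0, nT, 6)
        sds <- c(rep(0.03, 3), rep(0.0005, 3))
        for (j in 1:6) {
            x <- numeric(nT)
            for (t in seq_len(nT)[-1])
                x[t] <- 0.95 * x[t - 1] + stats::rnorm(1, sd = sds[j])
            mot[, j] <- x
        }
        spikes <- which(stats::runif(nT) < config@fdSpikeRate)
        for (v in spikes[spikes > 1]) {
            j <- sample(1:3, 1)
            mot[v:nT, j] <- mot[v:nT, j] +
                sample(c(-1, 1), 1) * stats::runif(1, 0.31, 0.6)
        }
        d <- abs(diff(mot))
        fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
                   50 * rowSums(d[, 4:6, drop = FALSE]))
        list(motion = mot, fd = fd)
    })
}

# Assemble one run's BOLD data for every ROI. sigOnset/sigDuration define
# the boxcars (shared across ROIs); sigPatterns[[roi]] is the voxel x
# event matrix of amplitude-scaled patterns.
.synthesizeRun <- function(sigOnset, sigDuration, sigPatterns, nT, config,
                           task, runId, subject) {
    ft <- (seq_len(nT) - 1) * config@tr
    nE <- length(sigOnset)
    regs <- if (nE > 0) .convolveEach(sigOnset, sigDuration, ft, config@hrf)
            else matrix(0, nT, 1L)
    mseed <- .seedFor(config, subject, sprintf("motion-%s-%d", task, runId))
    mo <- .simulateMotion(nT, config, mseed)
    motStd <- scale(mo$motion)
    motStd[!is.finite(motStd)] <- 0
    runs <- list()
    for (roi in config@roiNames) {
        signal <- if (nE > 0) sigPatterns[[roi]] %*% t(regs)
                  else matrix(0, config@nVoxels, nT)
        nseed <- .seedFor(config, subject,
                          sprintf("noise-%s-%s-%d", task, roi, runId))
        noise <- .withSeed(nseed, {
            L <- matrix(stats::rnorm(config@nVoxels * 6,
                                     sd = config@motionCoupling),
                        config@nVoxels, 6)
            L %*% t(motStd) +
                matrix(stats::rnorm(config@nVoxels * nT, sd = config@noiseSd),
                       config@nVoxels, nT)
        })
        runs[[roi]] <- boldRun(signal + noise, tr = config@tr, roi = roi,
                               run = runId, task = task,
                               motion = mo$motion, fd = mo$fd)
    }
    runs
}

# gains of one attention trial by sub-epoch; returns rows (onset, duration,
# item, gain, roiScaled) describing the trial's signal events
.attentionTrialSignals <- function(ev, config, truth) {
    tt <- config@trialTiming
    encOn <- ev$onset + tt["fixation"] + tt["cue"]
    maiOn <- encOn + tt["encode"]
    amp <- truth@signalAmplitude
    rows <- list()
    add <- function(on, du, item, gain, roiScaled = FALSE) {
        if (!is.na(item) && gain > 0)
            rows[[length(rows) + 1L]] <<- data.frame(
                onset = on, duration = du, item = item,
                gain = amp * gain, roiScaled = roiScaled)
        rows
    }
    if (ev$condition == "baseline") {
        rows <- add(encOn, tt["encode"] + tt["maintain"], ev$item_attended,
                    truth@gainBaseline)
    } else if (ev$condition == "prospective") {
        g <- truth@gainAttended["prospective"]
        gi <- truth@gainIgnored["prospective"]
        rows <- add(encOn, tt["encode"] + tt["maintain"], ev$item_attended, g)
        rows <- add(encOn, tt["encode"] + tt["maintain"], ev$item_ignored,
                    gi, roiScaled = TRUE)
    } else {
        rows <- add(encOn, tt["encode"], ev$item_attended,
                    truth@gainRetroEncoding)
        rows <- add(encOn, tt["encode"], ev$item_ignored,
                    truth@gainRetroEncoding)
        rows <- add(maiOn, tt["maintain"], ev$item_attended,
                    truth@gainAttended["retrospective"])
        rows <- add(maiOn, tt["maintain"], ev$item_ignored,
                    truth@gainIgnored["retrospective"])
    }
    if (ev$is_catch)   # probe picture after maintenance
        rows <- add(ev$onset + sum(tt), 4, ev$item_attended, 1)
    if (length(rows)) do.call(rbind, rows) else NULL
}

# pair-specific repulsion: shrink the component of each old item's signal
# parallel to its co-presented partner(s) by the condition's rho
.repulsedPatterns <- function(config, truth, patterns, attEvents) {
    pairs <- attEvents[!attEvents$is_catch &
                       attEvents$condition != "baseline", ]
    out <- list()
    for (roi in config@roiNames) {
        pat <- patterns[[roi]]
        base <- new.env(); repl <- new.env()
        getBase <- function(id) {
            if (!exists(id, envir = base, inherits = FALSE))
                assign(id, .itemPattern(pat, id, config), envir = base)
            get(id, envir = base, inherits = FALSE)
        }
        for (i in seq_len(nrow(pairs))) {
            rho <- truth@repulsionRho[[pairs$condition[i]]]
            if (rho == 0) next
            a <- pairs$item_attended[i]; b <- pairs$item_ignored[i]
            sa <- getBase(a); sb <- getBase(b)
            if (!exists(a, envir = repl, inherits = FALSE))
                assign(a, sa, envir = repl)
            if (!exists(b, envir = repl, inherits = FALSE))
                assign(b, sb, envir = repl)
            ub <- sb / sqrt(sum(sb^2)); ua <- sa / sqrt(sum(sa^2))
            assign(a, get(a, envir = repl) - rho * sum(sa * ub) * ub,
                   envir = repl)
            assign(b, get(b, envir = repl) - rho * sum(sb * ua) * ua,
                   envir = repl)
        }
        out[[roi]] <- list(getBase = getBase, repl = repl)
    }
    out
}

.recognitionPattern <- function(rp, pat, id, config) {
    if (exists(id, envir = rp$repl, inherits = FALSE))
        get(id, envir = rp$repl, inherits = FALSE)
    else rp$getBase(id)
}

#' Simulate one subject's BOLD runs for a task
#'
#' Generates the event schedule (unless supplied) and synthesizes the
#' ROI-restricted BOLD runs for the attention task, the localizer or the
#' recognition test. Attention-task signal amplitudes follow the
#' ground-truth gains per cue condition and phase (with the
#' prospective-ignored gain scaled per ROI); recognition signals carry the
#' pair-specific repulsion; localizer mini-blocks and Gabor blocks carry
#' their category/Gabor patterns at unit gain.
#'
#' @param config a \code{\linkS4class{SimulationConfig}}
#' @param truth a \code{\linkS4class{GroundTruth}}
#' @param task \code{"attention"}, \code{"localizer"} or
#'   \code{"recognition"}
#' @param subject subject index
#' @param events optional pre-built schedule for this task/subject
#' @param patterns optional result of \code{subjectPatterns}
#' @return list with \code{events} (the schedule) and \code{runs}, a list
#'   indexed as \code{runs[[roi]][[run]]} of \code{\linkS4class{BoldRun}}.
#' @export
simulateTaskRuns <- function(config, truth,
                             task = c("attention", "localizer",
                                      "recognition"),
                             subject = 1L, events = NULL, patterns = NULL) {
    task <- match.arg(task)
    validObject(config); validObject(truth)
    if (is.null(patterns)) patterns <- subjectPatterns(config, truth, subject)
    if (is.null(events))
        events <- switch(task,
                         attention = attentionEvents(config, subject),
                         localizer = localizerEvents(config, subject),
                         recognition = recognitionEvents(config, subject))
    runsOut <- lapply(config@roiNames, function(r) list())
    names(runsOut) <- config@roiNames
    runIds <- sort(unique(events$run))

    rp <- NULL
    if (task == "recognition" ||
        (task == "attention" && config@repulsionAtEncoding)) {
        attEv <- if (task == "attention") events
                 else attentionEvents(config, subject)
        rp <- .repulsedPatterns(config, truth, patterns, attEv)
    }

    for (runId in runIds) {
        ev <- events[events$run == runId, , drop = FALSE]
        if (task == "attention") {
            sig <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i)
                .attentionTrialSignals(ev[i, ], config, truth)))
            runEnd <- max(ev$onset) + sum(config@trialTiming) + 12 +
                4 * any(ev$is_catch)
        } else if (task == "localizer") {
            sig <- data.frame(onset = ev$onset, duration = ev$duration,
                              item = ev$item,
                              gain = truth@signalAmplitude,
                              roiScaled = FALSE)
            runEnd <- max(ev$onset + ev$duration) + 12
        } else {
            sig <- data.frame(onset = ev$picture_onset,
                              duration = ev$duration, item = ev$item,
                              gain = truth@signalAmplitude,
                              roiScaled = FALSE)
            runEnd <- max(ev$picture_onset + ev$duration) + 12
        }
        nT <- as.integer(ceiling(runEnd / config@tr))
        sigPatterns <- list()
        for (roi in config@roiNames) {
            scl <- truth@ignoredRoiScale
            roiScale <- if (roi %in% names(scl)) scl[[roi]] else 1
            P <- matrix(0, config@nVoxels, if (is.null(sig)) 0L else nrow(sig))
            for (e in seq_len(ncol(P))) {
                p <- if (task == "recognition" ||
                         (!is.null(rp) && task == "attention"))
                         .recognitionPattern(rp[[roi]], patterns[[roi]],
                                             sig$item[e], config)
                     else .itemPattern(patterns[[roi]], sig$item[e], config)
                g <- sig$gain[e] * if (sig$roiScaled[e]) roiScale else 1
                P[, e] <- g * p
            }
            sigPatterns[[roi]] <- P
        }
        rr <- .synthesizeRun(if (is.null(sig)) numeric() else sig$onset,
                             if (is.null(sig)) numeric() else sig$duration,
                             sigPatterns, nT, config, task, runId, subject)
        for (roi in config@roiNames)
            runsOut[[roi]][[as.character(runId)]] <- rr[[roi]]
    }
    list(events = events, runs = runsOut)
}

#' Simulate the recognition-test behavioral table
#'
#' One row per subject x item: old items are judged old (response 1 or 2)
#' with the probability given by their cue-attention group's hit mean,
#' novel items with the false-alarm rate; the confidence level of a
#' correct "old" response is high (response 1) with the group's
#' high-confidence probability. A small fraction of trials carry no
#' response (NA).
#'
#' @param config a \code{\linkS4class{SimulationConfig}}
#' @param truth a \code{\linkS4class{GroundTruth}}
#' @param subjects subject indices to simulate
#' @return data.frame with columns \code{subject}, \code{item},
#'   \code{cue_group} (BL/PA/PI/RA/RI/NOV), \code{condition},
#'   \code{attention_status}, \code{category}, \code{response} (1-4 or NA).
#' @export
simulateBehavior <- function(config, truth,
                             subjects = seq_len(config@nSubjects)) {
    validObject(config); validObject(truth)
    if (!all(.CUE_GROUPS %in% names(truth@behaviorHitMeans)))
        stop("behaviorHitMeans must define all cue-attention conditions")
    out <- list()
    for (s in subjects) {
        ev <- recognitionEvents(config, s)
        grp <- ev$cue_group
        pOld <- ifelse(grp == "NOV", truth@falseAlarmRate,
                       truth@behaviorHitMeans[grp])
        pHigh <- ifelse(grp == "NOV", 0.5, truth@confHighProb[grp])
        resp <- .withSeed(.seedFor(config, s, "behavior"), {
            old <- stats::runif(nrow(ev)) < pOld
            high <- stats::runif(nrow(ev)) <
                ifelse(old, pHigh, 0.5)   # confidence of "new" responses
            r <- ifelse(old, ifelse(high, 1L, 2L), ifelse(high, 4L, 3L))
            r[stats::runif(nrow(ev)) < config@noResponseRate] <- NA_integer_
            r
        })
        status <- c(BL = "attended", PA = "attended", PI = "ignored",
                    RA = "attended", RI = "ignored", NOV = "none")[grp]
        out[[s]] <- data.frame(subject = s, item = ev$item, cue_group = grp,
                               condition = ev$condition,
                               attention_status = unname(status),
                               category = ev$category, response = resp)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Simulate a full cohort
#'
#' Convenience wrapper generating, per subject, the three event schedules,
#' the behavioral table and the ROI-level BOLD runs for the requested
#' tasks.
#'
#' @param config a \code{\linkS4class{SimulationConfig}}
#' @param truth a \code{\linkS4class{GroundTruth}}
#' @param tasks which tasks to synthesize BOLD for (events and behavior
#'   are always generated)
#' @return list with elements \code{config}, \code{truth}, \code{behavior}
#'   (cohort table) and \code{subjects}, a per-subject list of
#'   \code{events} (by task) and \code{runs} (by task, then ROI, then run).
#' @export
simulateCohort <- function(config, truth = groundTruth(),
                           tasks = c("attention", "localizer",
                                     "recognition")) {
    validObject(config); validObject(truth)
    subjects <- list()
    for (s in seq_len(config@nSubjects)) {
        patterns <- subjectPatterns(config, truth, s)
        ev <- list(); runs <- list()
        for (task in c("attention", "localizer", "recognition")) {
            if (task %in% tasks) {
                sim <- simulateTaskRuns(config, truth, task, s,
                                        patterns = patterns)
                ev[[task]] <- sim$events
                runs[[task]] <- sim$runs
            } else {
                ev[[task]] <- switch(task,
                    attention = attentionEvents(config, s),
                    localizer = localizerEvents(config, s),
                    recognition = recognitionEvents(config, s))
            }
        }
        subjects[[s]] <- list(events = ev, runs = runs)
    }
    list(config = config, truth = truth,
         behavior = simulateBehavior(config, truth), subjects = subjects)
}
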