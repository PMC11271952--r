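# Classifier-evidence decoding of the attention task: normalized class
# probabilities are sorted per trial into attended / ignored / other /
# rest roles according to the trial's cued and distractor categories.

#' Decode attention-task volumes and sort evidence into roles
#'
#' Applies the localizer-trained classifier to the selected attention-task
#' volumes of one ROI (normalization steps 1-2 per run, phase selection,
#' then the task-level z across the selected attention volumes) and maps
#' the four class probabilities onto trial roles: the cued category is
#' \code{attended}, the co-presented distractor's category \code{ignored},
#' the remaining picture category \code{other} and the Gabor class
#' \code{rest}. Baseline trials have no distractor, so both non-presented
#' picture categories fold into \code{other}. Catch trials are excluded.
#'
#' @param model a \code{\linkS4class{ClassifierModel}} trained on the same
#'   ROI's localizer data
#' @param runs list of attention-task \code{\linkS4class{BoldRun}} for the
#'   ROI
#' @param events attention schedule (\code{\link{attentionEvents}})
#' @param phase \code{"encoding"}, \code{"maintenance"} (the two selected
#'   TRs are averaged before classification) or \code{"per-tr"}
#' @param config the \code{\linkS4class{SimulationConfig}} (category
#'   labels)
#' @param renorm \code{"all"} renormalizes over all four classes before
#'   role extraction (default); \code{"pictures"} renormalizes over the
#'   three picture categories only, in which case \code{rest} is 0
#' @return data.frame of evidence records: \code{subject}, \code{roi},
#'   \code{run}, \code{trial}, \code{phase}, \code{condition},
#'   \code{item_attended}, \code{item_ignored}, and role probabilities
#'   \code{attended}, \code{ignored} (NA for baseline), \code{other},
#'   \code{rest}, summing to 1 per record.
#' @export
decodeAttention <- function(model, runs, events, phase = "encoding",
                            config, renorm = c("all", "pictures")) {
    stopifnot(is(model, "ClassifierModel"))
    renorm <- match.arg(renorm)
    events <- as.data.frame(events)
    tr <- repetitionTime(runs[[1]])
    sel <- selectPhaseVolumes(events, tr = tr, phase = phase)
    # volume indices are within-run; events carry run-relative onsets
    sel$run <- events$run[sel$row]
    nv <- normalizeChain(runs, sel, step4 = TRUE)
    probs <- predictEvidence(model, nv@data, applyModelZ = FALSE)
    cats <- .categoryNames(config)
    if (renorm == "pictures") {
        probs <- probs[, cats, drop = FALSE] /
            rowSums(probs[, cats, drop = FALSE])
        probs <- cbind(probs, gabor = 0)
    }
    out <- events[sel$row, c("subject", "run", "trial", "condition",
                             "attended_category", "ignored_category",
                             "item_attended", "item_ignored")]
    out$roi <- roiLabel(runs[[1]])
    out$phase <- sel$phase
    aCat <- cats[out$attended_category]
    iCat <- cats[out$ignored_category]
    n <- nrow(out)
    att <- probs[cbind(seq_len(n), match(aCat, colnames(probs)))]
    ign <- rep(NA_real_, n)
    hasIgn <- !is.na(iCat)
    ign[hasIgn] <- probs[cbind(which(hasIgn),
                               match(iCat[hasIgn], colnames(probs)))]
    rest <- probs[, "gabor"]
    other <- 1 - att - ifelse(hasIgn, ign, 0) - rest
    out$attended <- att; out$ignored <- ign
    out$other <- other; out$rest <- rest
    rownames(out) <- NULL
    out[, c("subject", "roi", "run", "trial", "phase", "condition",
            "item_attended", "item_ignored", "attended", "ignored",
            "other", "rest")]
}

#' Condition means, contrasts and subsequent-memory splits of classifier
#' evidence
#'
#' Averages each picture's two presentations, then computes per subject x
#' ROI x phase the mean evidence of the five cue-attention roles (PA, PI,
#' PO, RA, RI, RO, BL, BO), the standard contrasts (attended minus
#' ignored, ignored minus other, attended minus other, baseline minus
#' attended) and, when a behavioral table is supplied, the subsequent
#' memory effect (remembered minus forgotten evidence within each
#' cue-attention group).
#'
#' @param records evidence records from \code{\link{decodeAttention}}
#' @param behavior optional behavioral table
#'   (\code{\link{simulateBehavior}}) for the SME split
#' @param averageRepetitions average the two presentations of each picture
#'   before condition averaging
#' @return list with \code{groups} (wide per subject x roi x phase:
#'   PA/PI/PO/RA/RI/RO/BL/BO), \code{contrasts} (long: contrast, value)
#'   and \code{sme} (long: cue group, remembered/forgotten means and
#'   difference; NA when a cell is empty).
#' @export
evidenceContrasts <- function(records, behavior = NULL,
                              averageRepetitions = TRUE) {
    records <- as.data.frame(records)
    key <- c("subject", "roi", "phase")
    # per-trial role rows -> long (item, role, evidence)
    long <- list()
    for (role in c("attended", "ignored", "other")) {
        item <- if (role == "ignored") records$item_ignored
                else records$item_attended
        keep <- !is.na(records[[role]])
        long[[role]] <- data.frame(
            records[keep, key], condition = records$condition[keep],
            item = item[keep], role = role,
            evidence = records[[role]][keep])
    }
    long <- do.call(rbind, long)
    if (averageRepetitions)
        long <- stats::aggregate(
            evidence ~ subject + roi + phase + condition + item + role,
            long, mean)

    grpOf <- function(condition, role)
        ifelse(condition == "baseline", ifelse(role == "attended", "BL", "BO"),
        ifelse(condition == "prospective",
               c(attended = "PA", ignored = "PI", other = "PO")[role],
               c(attended = "RA", ignored = "RI", other = "RO")[role]))
    long$group <- grpOf(long$condition, long$role)
    means <- stats::aggregate(evidence ~ subject + roi + phase + group,
                              long, mean)
    groups <- stats::reshape(means, idvar = key, timevar = "group",
                             direction = "wide")
    colnames(groups) <- sub("^evidence\\.", "", colnames(groups))
    defs <- list(PA_minus_PI = c("PA", "PI"), RA_minus_RI = c("RA", "RI"),
                 PI_minus_PO = c("PI", "PO"), RI_minus_RO = c("RI", "RO"),
                 PA_minus_PO = c("PA", "PO"), RA_minus_RO = c("RA", "RO"),
                 BL_minus_PA = c("BL", "PA"), BL_minus_RA = c("BL", "RA"))
    contrasts <- do.call(rbind, lapply(names(defs), function(nm) {
        a <- defs[[nm]][1]; b <- defs[[nm]][2]
        data.frame(groups[, key], contrast = nm,
                   value = groups[[a]] - groups[[b]])
    }))
    sme <- NULL
    if (!is.null(behavior)) {
        beh <- behavior[!is.na(behavior$response), ]
        beh$hit <- beh$response %in% 1:2
        m <- merge(long, beh[, c("subject", "item", "hit")],
                   by = c("subject", "item"))
        # evidence of an item's own role only (attended role for targets,
        # ignored role for distractors)
        m <- m[(m$group %in% c("PA", "RA", "BL") & m$role == "attended") |
               (m$group %in% c("PI", "RI") & m$role == "ignored"), ]
        agg <- stats::aggregate(evidence ~ subject + roi + phase + group + hit,
                                m, mean)
        rem <- agg[agg$hit, ]; forg <- agg[!agg$hit, ]
        sme <- merge(rem[, c(key, "group", "evidence")],
                     forg[, c(key, "group", "evidence")],
                     by = c(key, "group"), all = TRUE,
                     suffixes = c("_remembered", "_forgotten"))
        sme$sme <- sme$evidence_remembered - sme$evidence_forgotten
    }
    rownames(groups) <- rownames(contrasts) <- NULL
    list(groups = groups, contrasts = contrasts, sme = sme)
}
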