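# Cohort-level orchestration: localizer training + attention decoding,
# and the recognition LSS -> matched-pair similarity chain.

#' Decode a simulated cohort
#'
#' For every subject and ROI: normalize the localizer runs (steps 1-3),
#' train the four-class one-vs-rest classifier (step 4 inside), decode
#' the attention task at the requested phases and sort the evidence into
#' roles.
#'
#' @param cohort result of \code{\link{simulateCohort}} (attention and
#'   localizer runs required)
#' @param phases phases to decode
#' @param C inverse-regularization constant
#' @param rois subset of ROI labels (default all)
#' @return list with \code{records} (row-bound evidence records) and
#'   \code{cvAccuracy} (per subject x ROI leave-one-run-out localizer
#'   accuracy).
#' @export
decodeCohort <- function(cohort, phases = c("encoding", "maintenance"),
                         C = 0.01, rois = cohort$config@roiNames) {
    config <- cohort$config
    records <- list(); cvrows <- list()
    for (s in seq_along(cohort$subjects)) {
        subj <- cohort$subjects[[s]]
        locEv <- subj$events$localizer
        attEv <- subj$events$attention
        for (roi in rois) {
            locRuns <- subj$runs$localizer[[roi]]
            attRuns <- subj$runs$attention[[roi]]
            lv <- localizerVolumes(locRuns, locEv)
            cv <- loroCrossValidate(lv$volumesByRun, lv$labelsByRun, C = C)
            cvrows[[length(cvrows) + 1L]] <- data.frame(
                subject = s, roi = roi, accuracy = cv$meanAccuracy)
            model <- trainClassifier(do.call(rbind, lv$volumesByRun),
                                     unlist(lv$labelsByRun), C = C)
            for (ph in phases)
                records[[length(records) + 1L]] <-
                    decodeAttention(model, attRuns, attEv, phase = ph,
                                    config = config)
        }
    }
    list(records = do.call(rbind, records),
         cvAccuracy = do.call(rbind, cvrows))
}

#' Pattern-similarity analysis of a simulated cohort
#'
#' For every subject and ROI: estimate single-trial recognition t-maps by
#' the least-squares separate method, enumerate within-trial pairs with
#' their matched between-trial pairs, and correlate patterns. Returns the
#' WT/BT similarity records ready for \code{\link{wtBtStatistic}}.
#'
#' @param cohort result of \code{\link{simulateCohort}} (recognition runs
#'   required)
#' @param lagTol recognition-lag matching tolerance (trials)
#' @param rois subset of ROI labels
#' @return row-bound similarity records with a \code{subject} column.
#' @export
rsaCohort <- function(cohort, lagTol = 10, rois = cohort$config@roiNames) {
    config <- cohort$config
    out <- list()
    for (s in seq_along(cohort$subjects)) {
        subj <- cohort$subjects[[s]]
        recEv <- subj$events$recognition
        lssEv <- recognitionLssEvents(recEv, cohort$behavior,
                                      epoch = config@lssEpoch)
        pairs <- buildMatchedPairs(subj$events$attention, cohort$behavior,
                                   recEv, lagTol = lagTol,
                                   seed = .seedFor(config, s, "pair-match"))
        if (is.null(pairs)) next
        for (roi in rois) {
            pat <- lssSingleTrial(lssEv, subj$runs$recognition[[roi]],
                                  hrf = config@hrf)
            rec <- pairwiseSimilarity(pat, pairs)
            if (!is.null(rec) && nrow(rec)) {
                rec$subject <- s
                out[[length(out) + 1L]] <- rec
            }
        }
    }
    do.call(rbind, out)
}
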