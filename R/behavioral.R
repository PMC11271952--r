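# Behavioral recognition measures: hit/false-alarm rates, confidence of
# remembered items, attentional modulation and memory capacity. Responses
# use the 4-point scale 1 = definitely old ... 4 = definitely novel; old
# items judged 1 or 2 are hits. Trials without a response are excluded
# from numerator and denominator.

.checkBehavioralTable <- function(table) {
    table <- as.data.frame(table)
    need <- c("subject", "cue_group", "response")
    if (!all(need %in% colnames(table)))
        stop("behavioral table needs columns: ", paste(need, collapse = ", "))
    ok <- is.na(table$response) | table$response %in% 1:4
    if (!all(ok)) stop("responses must be in 1..4 or NA")
    if (any(table$cue_group == "NOV" &
            !is.na(table$attention_status) &
            table$attention_status != "none"))
        stop("novel items must have attention_status 'none'")
    table
}

#' Hit and false-alarm rates
#'
#' Hit rate per subject and cue-attention group (fraction of old items
#' with response 1 or 2) and the false-alarm rate (fraction of novel items
#' judged old). Missing responses are excluded from the denominator; an
#' empty denominator yields NA, never 0.
#'
#' @param table behavioral table as returned by
#'   \code{\link{simulateBehavior}} (columns \code{subject},
#'   \code{cue_group} with levels BL/PA/PI/RA/RI/NOV, \code{response})
#' @return data.frame with columns \code{subject}, \code{measure} (the
#'   cue-attention group, or \code{"FA"}), \code{n} (responded trials) and
#'   \code{rate}.
#' @export
hitFaRates <- function(table) {
    table <- .checkBehavioralTable(table)
    table <- table[!is.na(table$response), ]
    out <- list()
    for (s in unique(table$subject)) {
        ts <- table[table$subject == s, ]
        for (g in .CUE_GROUPS) {
            tg <- ts[ts$cue_group == g, ]
            out[[length(out) + 1L]] <- data.frame(
                subject = s, measure = g, n = nrow(tg),
                rate = if (nrow(tg)) mean(tg$response %in% 1:2) else NA_real_)
        }
        tn <- ts[ts$cue_group == "NOV", ]
        out[[length(out) + 1L]] <- data.frame(
            subject = s, measure = "FA", n = nrow(tn),
            rate = if (nrow(tn)) mean(tn$response %in% 1:2) else NA_real_)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Mean confidence of remembered items
#'
#' Among hits only, "definitely old" (response 1) scores 2 and "probably
#' old" (response 2) scores 1; the mean lies in [1, 2]. Cells without hits
#' yield NA.
#'
#' @inheritParams hitFaRates
#' @return data.frame with columns \code{subject}, \code{cue_group},
#'   \code{nHits}, \code{confidence}.
#' @export
confidenceRemembered <- function(table) {
    table <- .checkBehavioralTable(table)
    hits <- table[!is.na(table$response) & table$response %in% 1:2 &
                  table$cue_group %in% .CUE_GROUPS, ]
    out <- list()
    for (s in unique(table$subject)) for (g in .CUE_GROUPS) {
        h <- hits[hits$subject == s & hits$cue_group == g, ]
        out[[length(out) + 1L]] <- data.frame(
            subject = s, cue_group = g, nHits = nrow(h),
            confidence = if (nrow(h)) mean(ifelse(h$response == 1, 2, 1))
                         else NA_real_)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

.rateWide <- function(rates) {
    wide <- stats::reshape(rates[, c("subject", "measure", "rate")],
                           idvar = "subject", timevar = "measure",
                           direction = "wide")
    colnames(wide) <- sub("^rate\\.", "", colnames(wide))
    wide
}

#' Attentional modulation
#'
#' hit(attended) - hit(ignored) per subject for the prospective and
#' retrospective conditions; positive values mean better target memory.
#' Missing input rates propagate to NA.
#'
#' @param rates output of \code{\link{hitFaRates}}
#' @return data.frame with columns \code{subject}, \code{condition},
#'   \code{modulation}.
#' @export
attentionalModulation <- function(rates) {
    w <- .rateWide(rates)
    res <- rbind(
        data.frame(subject = w$subject, condition = "prospective",
                   modulation = w$PA - w$PI),
        data.frame(subject = w$subject, condition = "retrospective",
                   modulation = w$RA - w$RI))
    res[order(res$subject), ]
}

#' Memory capacity
#'
#' Long-term analogue of working-memory K: for the two-item conditions,
#' capacity = hit(attended) + hit(ignored) - 2 * false-alarm rate (maximum
#' 2); for baseline, capacity = hit(baseline) - false-alarm rate (maximum
#' 1). No clipping is applied.
#'
#' @param rates output of \code{\link{hitFaRates}}
#' @return data.frame with columns \code{subject}, \code{condition},
#'   \code{capacity}.
#' @export
memoryCapacity <- function(rates) {
    w <- .rateWide(rates)
    res <- rbind(
        data.frame(subject = w$subject, condition = "prospective",
                   capacity = w$PA + w$PI - 2 * w$FA),
        data.frame(subject = w$subject, condition = "retrospective",
                   capacity = w$RA + w$RI - 2 * w$FA),
        data.frame(subject = w$subject, condition = "baseline",
                   capacity = w$BL - w$FA))
    res[order(res$subject), ]
}

#' Per-subject behavioral summary
#'
#' Combines hit/false-alarm rates, confidence for remembered items,
#' attentional modulation and memory capacity into one table per subject
#' and condition.
#'
#' @inheritParams hitFaRates
#' @return data.frame with one row per subject x condition
#'   (prospective/retrospective/baseline) carrying \code{hit_attended},
#'   \code{hit_ignored}, \code{false_alarm}, \code{conf_attended},
#'   \code{conf_ignored}, \code{modulation}, \code{capacity}.
#' @export
behavioralSummary <- function(table) {
    rates <- hitFaRates(table)
    conf <- confidenceRemembered(table)
    mod <- attentionalModulation(rates)
    cap <- memoryCapacity(rates)
    w <- .rateWide(rates)
    cw <- stats::reshape(conf[, c("subject", "cue_group", "confidence")],
                         idvar = "subject", timevar = "cue_group",
                         direction = "wide")
    colnames(cw) <- sub("^confidence\\.", "c", colnames(cw))
    out <- list()
    for (s in w$subject) {
        ws <- w[w$subject == s, ]; cs <- cw[cw$subject == s, ]
        grab <- function(df, cond, col)
            df[df$subject == s & df$condition == cond, col]
        out[[length(out) + 1L]] <- data.frame(
            subject = s,
            condition = c("prospective", "retrospective", "baseline"),
            hit_attended = c(ws$PA, ws$RA, ws$BL),
            hit_ignored = c(ws$PI, ws$RI, NA),
            false_alarm = ws$FA,
            conf_attended = c(cs$cPA, cs$cRA, cs$cBL),
            conf_ignored = c(cs$cPI, cs$cRI, NA),
            modulation = c(grab(mod, "prospective", "modulation"),
                           grab(mod, "retrospective", "modulation"), NA),
            capacity = c(grab(cap, "prospective", "capacity"),
                         grab(cap, "retrospective", "capacity"),
                         grab(cap, "baseline", "capacity")))
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
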