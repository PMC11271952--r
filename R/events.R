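# Event schedules for the three tasks. All randomness is drawn through
# .withSeed so regenerating with the same SimulationConfig seed is
# bit-identical and does not disturb the caller's RNG state.

.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
    }
    set.seed(seed)
    force(expr)
}

.seedFor <- function(config, subject, what) {
    code <- sum(utf8ToInt(what))
    as.integer((as.double(config@seed) * 100003 + subject * 7919 + code) %%
               2147483647)
}

.CATEGORIES <- c("face", "scene", "object")

.categoryNames <- function(config) {
    if (config@nCategories == 3L) .CATEGORIES
    else paste0("cat", seq_len(config@nCategories))
}

.itemId <- function(group, cat, k) sprintf("%s_c%d_%02d", group, cat, k)

#' Item metadata from item identifiers
#'
#' Item ids are structured as \code{GROUP_c<category>_<index>}; these
#' helpers recover the cue-attention group (BL/PA/PI/RA/RI/NOV/LOC/CT) and
#' the category label.
#'
#' @param id character vector of item ids
#' @param config a \code{\linkS4class{SimulationConfig}} (for category
#'   labels)
#' @return character vector of groups / categories.
#' @export
itemGroup <- function(id) sub("_.*$", "", id)

#' @rdname itemGroup
#' @export
itemCategory <- function(id, config) {
    cats <- .categoryNames(config)
    cats[as.integer(sub("^.*_c([0-9]+)_.*$", "\\1", id))]
}

.groupCondition <- function(group) {
    c(BL = "baseline", PA = "prospective", PI = "prospective",
      RA = "retrospective", RI = "retrospective", NOV = "novel")[group]
}

#' Selective-attention task schedule
#'
#' Builds the trial list for one subject: each non-baseline picture appears
#' exactly twice (once per screen side, same attention status, paired with
#' a different-category partner each time; the two repetitions fall in
#' different runs), baseline pictures appear twice alone, and catch trials
#' carrying a post-maintenance probe are inserted so that the configured
#' fraction of all trials are catch trials. Trial epochs follow the 1-s
#' fixation / 1-s cue / 2-s encoding / 4-s maintenance timing.
#'
#' @param config a \code{\linkS4class{SimulationConfig}}
#' @param subject subject index
#' @return data.frame with one row per trial: \code{subject}, \code{run},
#'   \code{trial}, \code{onset} (s, trial start on the TR grid),
#'   \code{duration} (epoch length, 8 s), \code{condition},
#'   \code{attended_category}, \code{ignored_category},
#'   \code{attended_side}, \code{item_attended}, \code{item_ignored},
#'   \code{round}, \code{is_catch}.
#' @export
attentionEvents <- function(config, subject = 1L) {
    validObject(config)
    if (config@nCategories < 3L)
        stop("attention pairing requires at least 3 categories")
    nCat <- config@nCategories
    m <- config@nItemsPerCondition %/% nCat
    runsPerRound <- config@nRunsAttention %/% 2L
    perCondPerRun <- config@nItemsPerCondition %/% runsPerRound

    trials <- list()
    cc <- rep(seq_len(nCat), each = m)
    k <- rep(seq_len(m), nCat)
    for (r in 1:2) {
        side1 <- ifelse(k %% 2 == 1, "left", "right")
        side <- if (r == 1) side1 else ifelse(side1 == "left", "right",
                                              "left")
        ic <- if (r == 1) (cc %% nCat) + 1L else ((cc + 1L) %% nCat) + 1L
        for (cond in c("prospective", "retrospective")) {
            ga <- if (cond == "prospective") "PA" else "RA"
            gi <- if (cond == "prospective") "PI" else "RI"
            trials[[length(trials) + 1L]] <- data.frame(
                condition = cond, attended_category = cc,
                ignored_category = ic, attended_side = side,
                item_attended = .itemId(ga, cc, k),
                item_ignored = .itemId(gi, ic, k),
                round = r, is_catch = FALSE)
        }
        trials[[length(trials) + 1L]] <- data.frame(
            condition = "baseline", attended_category = cc,
            ignored_category = NA_integer_, attended_side = side,
            item_attended = .itemId("BL", cc, k),
            item_ignored = NA_character_, round = r, is_catch = FALSE)
    }
    trials <- do.call(rbind, trials)

    f <- config@catchFraction
    nCatchPerRun <- as.integer(floor(3 * perCondPerRun * f / (1 - f)))

    .withSeed(.seedFor(config, subject, "attention-events"), {
        out <- list(); catchIdx <- 0L
        used <- rep(FALSE, nrow(trials))
        for (r in 1:2) for (ri in seq_len(runsPerRound)) {
            runId <- (r - 1L) * runsPerRound + ri
            block <- list()
            for (cond in .CONDITIONS) {
                pool <- which(trials$round == r & trials$condition == cond &
                              !used)
                pick <- if (length(pool) == 1L) pool
                        else sample(pool, perCondPerRun)
                used[pick] <- TRUE
                block[[cond]] <- trials[pick, , drop = FALSE]
            }
            block <- do.call(rbind, block)
            for (ci in seq_len(nCatchPerRun)) {
                catchIdx <- catchIdx + 1L
                cond <- .CONDITIONS[(catchIdx - 1L) %% 3L + 1L]
                cc <- sample(config@nCategories, 1)
                ic <- if (cond == "baseline") NA_integer_
                      else sample(setdiff(seq_len(config@nCategories), cc), 1)
                block <- rbind(block, data.frame(
                    condition = cond, attended_category = cc,
                    ignored_category = ic,
                    attended_side = sample(c("left", "right"), 1),
                    item_attended = .itemId("CT", cc, catchIdx),
                    item_ignored = if (is.na(ic)) NA_character_
                                   else .itemId("CT", ic, catchIdx + 1000L),
                    round = r, is_catch = TRUE))
            }
            block <- block[sample(nrow(block)), , drop = FALSE]
            epoch <- sum(config@trialTiming)
            dur <- ifelse(block$is_catch, epoch + 4, epoch) + config@itiSeconds
            block$onset <- cumsum(c(0, dur[-nrow(block)]))
            block$duration <- epoch
            block$run <- runId
            block$trial <- seq_len(nrow(block))
            out[[runId]] <- block
        }
        ev <- do.call(rbind, out)
    })
    ev$subject <- subject
    rownames(ev) <- NULL
    ev[, c("subject", "run", "trial", "onset", "duration", "condition",
           "attended_category", "ignored_category", "attended_side",
           "item_attended", "item_ignored", "round", "is_catch")]
}

#' Block localizer schedule
#'
#' Nine mini-blocks per run (three per category, order shuffled), each
#' showing 10 pictures for 2 s; an 8-s Gabor block (4 Gabor events of 2 s)
#' separates consecutive mini-blocks.
#'
#' @inheritParams attentionEvents
#' @return data.frame with one row per picture/Gabor event: \code{subject},
#'   \code{run}, \code{block}, \code{onset}, \code{duration},
#'   \code{category} (a picture category or \code{"gabor"}), \code{item}.
#' @export
localizerEvents <- function(config, subject = 1L) {
    validObject(config)
    cats <- .categoryNames(config)
    nBlocksPerCat <- 3L
    .withSeed(.seedFor(config, subject, "localizer-events"), {
        out <- list()
        for (runId in seq_len(config@nRunsLocalizer)) {
            order <- sample(rep(seq_len(config@nCategories), nBlocksPerCat))
            t <- 0
            for (b in seq_along(order)) {
                cc <- order[b]
                ks <- sample(10L * nBlocksPerCat, 10L)
                out[[length(out) + 1L]] <- data.frame(
                    subject = subject, run = runId, block = b,
                    onset = t + (0:9) * 2, duration = 2,
                    category = cats[cc], item = .itemId("LOC", cc, ks))
                t <- t + 20
                if (b < length(order)) {
                    out[[length(out) + 1L]] <- data.frame(
                        subject = subject, run = runId, block = b,
                        onset = t + (0:3) * 2, duration = 2,
                        category = "gabor", item = "GABOR")
                    t <- t + 8
                }
            }
        }
        ev <- do.call(rbind, out)
    })
    rownames(ev) <- NULL
    ev
}

#' Recognition-test schedule
#'
#' All old items (the five cue-attention groups) plus an equal number of
#' novel foils, presented once each in a seeded pseudorandom order split
#' across runs; each trial is a 2-s fixation followed by a 4-s picture.
#'
#' @inheritParams attentionEvents
#' @return data.frame with one row per trial: \code{subject}, \code{run},
#'   \code{trial}, \code{position} (global order, for lag matching),
#'   \code{onset} (trial start), \code{picture_onset}, \code{duration}
#'   (picture duration, 4 s), \code{item}, \code{category},
#'   \code{cue_group}, \code{condition}, \code{old}.
#' @export
recognitionEvents <- function(config, subject = 1L) {
    validObject(config)
    nCat <- config@nCategories
    m <- config@nItemsPerCondition %/% nCat
    oldIds <- unlist(lapply(c("BL", "PA", "PI", "RA", "RI"), function(g)
        .itemId(g, rep(seq_len(nCat), each = m), rep(seq_len(m), nCat))))
    # foils: same total count as old items, spread over categories
    foilCat <- rep(seq_len(nCat), length.out = length(oldIds))
    foilIdx <- stats::ave(foilCat, foilCat, FUN = seq_along)
    ids <- c(oldIds, .itemId("NOV", foilCat, foilIdx))

    .withSeed(.seedFor(config, subject, "recognition-events"), {
        ord <- sample(ids)
    })
    n <- length(ord)
    perRun <- ceiling(n / config@nRunsRecognition)
    run <- rep(seq_len(config@nRunsRecognition), each = perRun)[seq_len(n)]
    trial <- stats::ave(seq_len(n), run, FUN = seq_along)
    onset <- (trial - 1) * 6
    grp <- itemGroup(ord)
    data.frame(subject = subject, run = run, trial = trial,
               position = seq_len(n), onset = onset,
               picture_onset = onset + 2, duration = 4, item = ord,
               category = itemCategory(ord, config), cue_group = grp,
               condition = unname(.groupCondition(grp)), old = grp != "NOV")
}
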