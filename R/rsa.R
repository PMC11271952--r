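# Pair-specific pattern similarity at retrieval: within-trial (WT) pairs
# were co-presented in the attention task; each WT pair is matched to a
# between-trial (BT) pair of items never shown together, agreeing exactly
# on the category pair, the side assignment of the defining trials, both
# members' memory outcomes and (within tolerance) the recognition lag.

#' Build LSS event table for the recognition runs
#'
#' Joins the recognition schedule with the behavioral table to label each
#' trial for the single-trial GLM: responded old items become LSS targets
#' (\code{class = "trial"}), foils \code{"foil"} and unanswered trials
#' \code{"noresponse"}.
#'
#' @param recogEvents recognition schedule
#'   (\code{\link{recognitionEvents}}) for one subject
#' @param behavior behavioral table covering that subject
#' @param epoch which 2-s window the target regressor models:
#'   \code{"trial"} (from trial start) or \code{"stimulus"} (first 2 s of
#'   the picture)
#' @return data.frame with columns \code{onset}, \code{duration},
#'   \code{item}, \code{run}, \code{class}.
#' @export
recognitionLssEvents <- function(recogEvents, behavior,
                                 epoch = c("trial", "stimulus")) {
    epoch <- match.arg(epoch)
    ev <- as.data.frame(recogEvents)
    beh <- behavior[behavior$subject == ev$subject[1],
                    c("item", "response")]
    m <- merge(ev, beh, by = "item", sort = FALSE)
    m <- m[order(m$position), ]
    cls <- ifelse(is.na(m$response), "noresponse",
                  ifelse(m$old, "trial", "foil"))
    onset <- if (epoch == "trial") m$onset else m$picture_onset
    data.frame(onset = onset, duration = 2, item = m$item, run = m$run,
               class = cls)
}

#' Enumerate within-trial pairs and matched between-trial pairs
#'
#' WT pairs are the (attended, ignored) item pairs of non-catch
#' prospective/retrospective trials. For each WT pair, BT candidates are
#' (attended item, ignored item) combinations never co-presented with
#' each other, drawn from trials with the same attended/ignored category
#' pair and the same attended side (and the same cue condition when
#' \code{sameCue}), whose members have the same memory outcomes as the WT
#' members and whose recognition lag differs by at most \code{lagTol}
#' trials. One BT pair is chosen per WT pair by seeded greedy selection
#' (smallest lag difference first, ties broken reproducibly); WT pairs
#' without any eligible candidate are excluded from both sides.
#'
#' @param attEvents attention schedule for one subject
#' @param behavior behavioral table covering that subject
#' @param recogEvents recognition schedule (defines the lag order)
#' @param lagTol maximum absolute difference in recognition lag
#' @param sameCue restrict BT candidates to the WT pair's cue condition
#' @param seed integer seed for tie-breaking
#' @return data.frame of pairs: \code{pair} id, \code{kind}
#'   (\code{within_trial}/\code{between_trial}), \code{item_a} (attended),
#'   \code{item_b} (ignored), \code{condition}, \code{cat_a},
#'   \code{cat_b}, \code{side}, \code{hit_a}, \code{hit_b}, \code{lag},
#'   \code{matched_to} (the WT pair id; NA for WT rows).
#' @export
buildMatchedPairs <- function(attEvents, behavior, recogEvents,
                              lagTol = 10, sameCue = TRUE, seed = 1) {
    ev <- attEvents[!attEvents$is_catch &
                    attEvents$condition != "baseline", , drop = FALSE]
    beh <- behavior[behavior$subject == ev$subject[1], ]
    hit <- stats::setNames(beh$response %in% 1:2 & !is.na(beh$response),
                           beh$item)
    answered <- stats::setNames(!is.na(beh$response), beh$item)
    pos <- stats::setNames(recogEvents$position, recogEvents$item)

    # one row per co-presentation; features of the defining trial
    trials <- data.frame(item_a = ev$item_attended, item_b = ev$item_ignored,
                         condition = ev$condition,
                         cat_a = ev$attended_category,
                         cat_b = ev$ignored_category,
                         side = ev$attended_side)
    # drop trials whose members were not answered in recognition
    keep <- answered[trials$item_a] & answered[trials$item_b]
    trials <- trials[keep, , drop = FALSE]
    trials$hit_a <- unname(hit[trials$item_a])
    trials$hit_b <- unname(hit[trials$item_b])
    trials$lag <- abs(pos[trials$item_a] - pos[trials$item_b])
    # unique WT pairs (each co-presented pair appears in exactly one trial)
    wt <- trials[!duplicated(paste(trials$item_a, trials$item_b)), ,
                 drop = FALSE]
    wt$pair <- paste0("WT", seq_len(nrow(wt)))

    coPresented <- paste(trials$item_a, trials$item_b)
    sidesA <- tapply(trials$side, trials$item_a, unique)
    sidesB <- tapply(trials$side, trials$item_b, unique)
    # all (attended item, ignored item) combinations with their features,
    # computed once; per-WT filtering below is vectorized over this table
    cand0 <- expand.grid(a = unique(trials$item_a),
                         b = unique(trials$item_b),
                         stringsAsFactors = FALSE)
    cand0 <- cand0[!paste(cand0$a, cand0$b) %in% coPresented, , drop = FALSE]
    aInfo0 <- trials[match(cand0$a, trials$item_a), ]
    bInfo0 <- trials[match(cand0$b, trials$item_b), ]
    cand0$cat_a <- aInfo0$cat_a; cand0$cat_b <- bInfo0$cat_b
    cand0$hit_a <- aInfo0$hit_a; cand0$hit_b <- bInfo0$hit_b
    cand0$cond_a <- aInfo0$condition; cand0$cond_b <- bInfo0$condition
    cand0$lag <- abs(pos[cand0$a] - pos[cand0$b])
    # an item was attended/ignored on a fixed set of sides across its
    # presentations; the candidate must cover the WT trial's side
    covers <- function(tab, items, side)
        vapply(tab[items], function(ss) side %in% ss, TRUE)
    sideCover <- list(
        left = covers(sidesA, cand0$a, "left") &
            covers(sidesB, cand0$b, "left"),
        right = covers(sidesA, cand0$a, "right") &
            covers(sidesB, cand0$b, "right"))
    out <- list(); used <- character()
    ordIdx <- .withSeed(seed, sample(nrow(wt)))
    for (i in ordIdx) {
        w <- wt[i, ]
        keep <- cand0$cat_a == w$cat_a & cand0$cat_b == w$cat_b &
            sideCover[[w$side]] &
            cand0$hit_a == w$hit_a & cand0$hit_b == w$hit_b
        # neither candidate item may ever have been co-presented with a
        # member of the WT pair
        keep <- keep &
            !(cand0$a %in% c(w$item_a, trials$item_a[trials$item_b == w$item_b])) &
            !(cand0$b %in% c(w$item_b, trials$item_b[trials$item_a == w$item_a]))
        if (sameCue)
            keep <- keep & cand0$cond_a == w$condition &
                cand0$cond_b == w$condition
        keep <- keep & !is.na(keep) & abs(cand0$lag - w$lag) <= lagTol
        cand <- cand0[keep, , drop = FALSE]
        cand <- cand[!paste(cand$a, cand$b) %in% used, , drop = FALSE]
        if (nrow(cand) == 0) next
        cand <- cand[order(abs(cand$lag - w$lag), cand$a, cand$b), ,
                     drop = FALSE]
        pick <- cand[1, ]
        used <- c(used, paste(pick$a, pick$b))
        bt <- data.frame(pair = paste0("BT", sub("WT", "", w$pair)),
                         kind = "between_trial", item_a = pick$a,
                         item_b = pick$b, condition = w$condition,
                         cat_a = w$cat_a, cat_b = w$cat_b, side = w$side,
                         hit_a = w$hit_a, hit_b = w$hit_b, lag = pick$lag,
                         matched_to = w$pair)
        wtRow <- data.frame(pair = w$pair, kind = "within_trial",
                            item_a = w$item_a, item_b = w$item_b,
                            condition = w$condition, cat_a = w$cat_a,
                            cat_b = w$cat_b, side = w$side, hit_a = w$hit_a,
                            hit_b = w$hit_b, lag = w$lag,
                            matched_to = NA_character_)
        out[[length(out) + 1L]] <- rbind(wtRow, bt)
    }
    if (!length(out)) return(NULL)
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Pairwise pattern similarity with Fisher z
#'
#' Pearson correlation across voxels between the two members' retrieval
#' t-maps, followed by the Fisher z (atanh) transform; r is clipped to
#' +/- (1 - 1e-7) so z stays finite on degenerate inputs. Pairs with a
#' missing or zero-variance pattern yield missing records with a warning.
#'
#' @param patterns a \code{\linkS4class{TrialPatternSet}} of recognition
#'   t-maps (columns named or indexed by item via \code{patternInfo})
#' @param pairs pair table from \code{\link{buildMatchedPairs}}
#' @return data.frame: pair columns plus \code{r} and \code{z}.
#' @export
pairwiseSimilarity <- function(patterns, pairs) {
    if (is.null(pairs) || nrow(pairs) == 0)
        return(data.frame())
    info <- patternInfo(patterns)
    X <- patternData(patterns)
    idx <- function(item) match(item, info$item)
    r <- rep(NA_real_, nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
        ia <- idx(pairs$item_a[i]); ib <- idx(pairs$item_b[i])
        if (is.na(ia) || is.na(ib)) next
        if (!info$ok[ia] || !info$ok[ib]) next
        a <- X[, ia]; b <- X[, ib]
        if (stats::sd(a) == 0 || stats::sd(b) == 0) {
            warning("zero-variance pattern for pair ", pairs$pair[i])
            next
        }
        r[i] <- stats::cor(a, b)
    }
    res <- cbind(pairs, r = r,
                 z = atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)))
    res$roi <- roiLabel(patterns)
    if (any(is.na(r)))
        message(sum(is.na(r)), " pair(s) without usable patterns dropped")
    res[!is.na(res$r), , drop = FALSE]
}

#' Within-trial minus between-trial similarity statistic
#'
#' Per subject x ROI x condition, the mean Fisher-z within-trial
#' similarity minus the mean z of the matched between-trial pairs
#' (negative values indicate representational repulsion), with a group
#' paired t-test across subjects and BH-FDR over the ROI x condition
#' family.
#'
#' @param records row-bound \code{\link{pairwiseSimilarity}} outputs with
#'   a \code{subject} column
#' @return list with \code{subjectStats} (subject, roi, condition,
#'   meanZ_wt, meanZ_bt, wt_minus_bt) and \code{groupStats} (roi,
#'   condition, mean difference, t, df, p, p_fdr).
#' @export
wtBtStatistic <- function(records) {
    records <- as.data.frame(records)
    agg <- stats::aggregate(z ~ subject + roi + condition + kind, records,
                            mean)
    wide <- stats::reshape(agg, idvar = c("subject", "roi", "condition"),
                           timevar = "kind", direction = "wide")
    colnames(wide) <- sub("^z\\.", "", colnames(wide))
    wide$wt_minus_bt <- wide$within_trial - wide$between_trial
    cells <- unique(wide[, c("roi", "condition")])
    grp <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
        w <- wide[wide$roi == cells$roi[i] &
                  wide$condition == cells$condition[i], ]
        ok <- stats::complete.cases(w[, c("within_trial", "between_trial")])
        w <- w[ok, ]
        if (nrow(w) < 3 || stats::sd(w$wt_minus_bt) == 0)
            return(data.frame(roi = cells$roi[i],
                              condition = cells$condition[i],
                              mean_diff = mean(w$wt_minus_bt),
                              t = NA_real_, df = NA_real_, p = NA_real_))
        tt <- stats::t.test(w$within_trial, w$between_trial, paired = TRUE)
        data.frame(roi = cells$roi[i], condition = cells$condition[i],
                   mean_diff = unname(tt$estimate), t = unname(tt$statistic),
                   df = unname(tt$parameter), p = tt$p.value)
    }))
    grp$p_fdr <- NA_real_
    ok <- !is.na(grp$p)
    if (any(ok)) grp$p_fdr[ok] <- fdrBH(grp$p[ok])
    sub <- wide[, c("subject", "roi", "condition", "within_trial",
                    "between_trial", "wt_minus_bt")]
    colnames(sub)[4:5] <- c("meanZ_wt", "meanZ_bt")
    list(subjectStats = sub, groupStats = grp)
}

#' Brain-behavior correlation with a robust check
#'
#' Pearson correlation between a per-subject neural statistic (e.g. the
#' pair-specific WT-BT similarity) and a behavioral measure (e.g. the
#' mean hit rate of targets and distractors), reported alongside a
#' robust linear fit (iteratively reweighted least squares with bisquare
#' weights, tuning constant 4.685) whose slope t-statistic down-weights
#' outliers.
#'
#' @param statistic per-subject neural values
#' @param behavior per-subject behavioral values (same order)
#' @return one-row data.frame: \code{n}, \code{r}, \code{p},
#'   \code{slope_ols}, \code{slope_robust}, \code{t_robust},
#'   \code{p_robust}; all NA (with n) when fewer than 5 complete pairs or
#'   either variable has zero variance.
#' @export
brainBehaviorCorrelation <- function(statistic, behavior) {
    ok <- is.finite(statistic) & is.finite(behavior)
    x <- statistic[ok]; y <- behavior[ok]
    empty <- data.frame(n = length(x), r = NA_real_, p = NA_real_,
                        slope_ols = NA_real_, slope_robust = NA_real_,
                        t_robust = NA_real_, p_robust = NA_real_)
    if (length(x) < 5) return(empty)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(empty)
    ct <- stats::cor.test(x, y)
    ols <- stats::lm(y ~ x)
    rob <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, c = 4.685,
                     maxit = 100)
    sr <- summary(rob)$coefficients
    tRob <- sr["x", "t value"]
    dfRob <- length(x) - 2
    data.frame(n = length(x), r = unname(ct$estimate), p = ct$p.value,
               slope_ols = unname(stats::coef(ols)["x"]),
               slope_robust = unname(stats::coef(rob)["x"]),
               t_robust = tRob,
               p_robust = 2 * stats::pt(-abs(tRob), dfRob))
}
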