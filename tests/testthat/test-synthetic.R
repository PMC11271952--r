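# Synthetic cohort generator: schedules, reproducibility, catch fraction,
# repetition structure, signal content, behavior sampling.

test_that("configuration and ground-truth validity rules hold", {
    expect_error(simulationConfig(catchFraction = 1.2), "catchFraction")
    expect_error(simulationConfig(tr = 0), "tr")
    expect_error(simulationConfig(nItemsPerCondition = 7), "divisible")
    expect_error(simulationConfig(nRunsAttention = 3), "even")
    expect_error(groundTruth(gainBaseline = -1), ">= 0")
    expect_error(groundTruth(repulsionRho = c(prospective = 2,
                                              retrospective = 0)),
                 "repulsionRho")
    expect_error(groundTruth(falseAlarmRate = 1.5), "\\[0, 1\\]")
})

test_that("same seed regenerates identical events, behavior and runs", {
    cfg <- smallConfig(seed = 13)
    tru <- groundTruth()
    expect_identical(attentionEvents(cfg, 2), attentionEvents(cfg, 2))
    expect_identical(localizerEvents(cfg, 1), localizerEvents(cfg, 1))
    expect_identical(recognitionEvents(cfg, 1), recognitionEvents(cfg, 1))
    expect_identical(simulateBehavior(cfg, tru), simulateBehavior(cfg, tru))
    r1 <- simulateTaskRuns(cfg, tru, "localizer", 1)
    r2 <- simulateTaskRuns(cfg, tru, "localizer", 1)
    expect_identical(boldData(r1$runs[[1]][[1]]), boldData(r2$runs[[1]][[1]]))
    # different subjects differ
    expect_false(identical(attentionEvents(cfg, 1), attentionEvents(cfg, 2)))
})

test_that("catch fraction and per-run trial counts match the design", {
    cfg <- simulationConfig(nSubjects = 1, nVoxels = 4, seed = 11)
    ev <- attentionEvents(cfg, 1)
    for (r in unique(ev$run)) {
        evr <- ev[ev$run == r, ]
        expect_equal(nrow(evr), 36)           # 30 non-catch + 6 catch
        expect_equal(sum(evr$is_catch), floor(nrow(evr) / 6))
        expect_true(abs(sum(evr$is_catch) -
                        cfg@catchFraction * nrow(evr)) <= 1)
        # balanced conditions among non-catch trials
        expect_true(all(table(evr$condition[!evr$is_catch]) == 10))
        # onsets strictly increasing and on the TR grid
        expect_true(all(diff(evr$onset) > 0))
        expect_true(all(evr$onset %% cfg@tr == 0))
    }
})

test_that("every non-baseline picture appears twice, opposite sides, same status", {
    cfg <- smallConfig(seed = 5, nItemsPerCondition = 12,
                       nRunsAttention = 4)
    ev <- attentionEvents(cfg, 1)
    nb <- ev[!ev$is_catch, ]
    for (col in c("item_attended", "item_ignored")) {
        items <- nb[[col]][!is.na(nb[[col]])]
        expect_true(all(table(items) == 2))
    }
    # exhaustive scan: two runs, two sides, different partner, same status
    att <- nb[nb$condition != "baseline", ]
    for (it in unique(att$item_attended)) {
        pres <- att[att$item_attended == it, ]
        expect_equal(nrow(pres), 2)
        expect_setequal(pres$attended_side, c("left", "right"))
        expect_false(pres$run[1] == pres$run[2])
        expect_false(pres$item_ignored[1] == pres$item_ignored[2])
        expect_false(pres$ignored_category[1] == pres$ignored_category[2])
    }
    # attended and ignored categories never coincide
    expect_true(all(att$attended_category != att$ignored_category))
})

test_that("localizer blocks follow the 10 x 2 s + 8-s Gabor structure", {
    cfg <- smallConfig(seed = 2)
    ev <- localizerEvents(cfg, 1)
    for (r in unique(ev$run)) {
        evr <- ev[ev$run == r, ]
        pics <- evr[evr$category != "gabor", ]
        expect_equal(nrow(pics), 90)          # 9 blocks x 10 pictures
        expect_true(all(table(pics$category) == 30))
        expect_true(all(table(pics$block) == 10))
        gab <- evr[evr$category == "gabor", ]
        expect_equal(nrow(gab), 8 * 4)        # 8 gaps x 4 Gabors
        expect_true(all(pics$duration == 2))
    }
})

test_that("noise-free prospective encoding volumes point at the attended prototype", {
    cfg <- simulationConfig(nSubjects = 1, nVoxels = 30,
                            nItemsPerCondition = 3, nRunsAttention = 2,
                            itiSeconds = 32, noiseSd = 0,
                            motionCoupling = 0, fdSpikeRate = 0,
                            roiNames = "VTC", seed = 4)
    tru <- groundTruth(gainAttended = c(prospective = 1, retrospective = 1),
                       gainIgnored = c(prospective = 0, retrospective = 0),
                       itemSd = 0, commonAmp = 0,
                       ignoredRoiScale = c(VTC = 1))
    sim <- simulateTaskRuns(cfg, tru, "attention", 1)
    pats <- subjectPatterns(cfg, tru, 1)
    ev <- sim$events
    pro <- ev[!ev$is_catch & ev$condition == "prospective", ]
    sel <- selectPhaseVolumes(pro, tr = cfg@tr, phase = "encoding")
    cats <- c("face", "scene", "object")
    for (i in seq_len(nrow(sel))) {
        run <- sim$runs$VTC[[as.character(pro$run[sel$row[i]])]]
        v <- boldData(run)[, sel$v1[i]]
        proto <- pats$VTC$prototypes[, cats[pro$attended_category[sel$row[i]]]]
        cosine <- sum(v * proto) / sqrt(sum(v^2) * sum(proto^2))
        expect_equal(cosine, 1, tolerance = 1e-6)
    }
})

test_that("with equal gains and no item noise, PA and PI signals are symmetric", {
    cfg <- simulationConfig(nSubjects = 1, nVoxels = 30,
                            nItemsPerCondition = 3, nRunsAttention = 2,
                            itiSeconds = 32, noiseSd = 0,
                            motionCoupling = 0, fdSpikeRate = 0,
                            roiNames = "VTC", seed = 4)
    tru <- groundTruth(gainAttended = c(prospective = 0.7, retrospective = 0.7),
                       gainIgnored = c(prospective = 0.7, retrospective = 0.7),
                       itemSd = 0, ignoredRoiScale = c(VTC = 1))
    pats <- subjectPatterns(cfg, tru, 1)
    # prototypes share a common norm, so equal gains imply equal energy
    norms <- sqrt(colSums(pats$VTC$prototypes^2))
    expect_equal(unname(norms), rep(norms[[1]], length(norms)),
                 tolerance = 1e-9)
})

test_that("full repulsion makes a pair's signals orthogonal", {
    cfg <- smallConfig(seed = 9, roiNames = "vLPC", nItemsPerCondition = 6)
    tru <- groundTruth(repulsionRho = c(prospective = 1, retrospective = 1))
    pats <- subjectPatterns(cfg, tru, 1)
    att <- attentionEvents(cfg, 1)
    rp <- attnrep:::.repulsedPatterns(cfg, tru, pats, att)
    pairs <- att[!att$is_catch & att$condition != "baseline", ]
    # single-partner members of a pair must end up exactly orthogonal to
    # the partner's original signal
    w <- pairs[1, ]
    a1 <- attnrep:::.recognitionPattern(rp$vLPC, NULL, w$item_attended, cfg)
    b0 <- attnrep:::.itemPattern(pats$vLPC, w$item_ignored, cfg)
    # component along this partner is removed (item has 2 partners; check
    # projection onto this partner after removing the other's influence)
    aFresh <- attnrep:::.itemPattern(pats$vLPC, w$item_attended, cfg)
    u <- b0 / sqrt(sum(b0^2))
    onePartner <- aFresh - 1 * sum(aFresh * u) * u
    expect_lt(abs(sum(onePartner * u)), 1e-8)
})

test_that("FD traces exercise the censoring threshold", {
    cfg <- smallConfig(seed = 6, fdSpikeRate = 0.05)
    tru <- groundTruth()
    sim <- simulateTaskRuns(cfg, tru, "localizer", 1)
    fdAll <- unlist(lapply(sim$runs[[1]], framewiseDisplacement))
    expect_true(all(fdAll >= 0))
    expect_gt(sum(fdAll > 0.3), 0)
    expect_gt(mean(fdAll <= 0.3), 0.8)
})

test_that("degenerate behavioral probabilities give deterministic outcomes", {
    cfg <- smallConfig(seed = 8, nSubjects = 1)
    tru1 <- groundTruth(behaviorHitMeans = c(BL = 1, PA = 1, PI = 1,
                                             RA = 1, RI = 1),
                        falseAlarmRate = 0)
    cfg@noResponseRate <- 0
    beh <- simulateBehavior(cfg, tru1)
    old <- beh[beh$cue_group != "NOV", ]
    nov <- beh[beh$cue_group == "NOV", ]
    expect_true(all(old$response %in% 1:2))
    expect_true(all(nov$response %in% 3:4))
    # all-null case: hit - FA centered on zero over many subjects
    truN <- groundTruth(behaviorHitMeans = c(BL = .4, PA = .4, PI = .4,
                                             RA = .4, RI = .4),
                        falseAlarmRate = .4)
    cfgN <- smallConfig(seed = 9, nSubjects = 60)
    behN <- simulateBehavior(cfgN, truN)
    s <- behavioralSummary(behN)
    expect_lt(abs(mean(s$hit_attended - s$false_alarm, na.rm = TRUE)), 0.03)
})

test_that("events and runs round-trip through TSV and NIfTI", {
    cfg <- smallConfig(seed = 3, nVoxels = 10)
    tru <- groundTruth()
    ev <- attentionEvents(cfg, 1)
    tf <- tempfile(fileext = ".tsv")
    writeEventsTsv(ev, tf)
    back <- readEventsTsv(tf)
    expect_equal(back$onset, ev$onset)
    expect_equal(back$item_attended, ev$item_attended)
    expect_equal(sum(is.na(back$item_ignored)), sum(is.na(ev$item_ignored)))
    sim <- simulateTaskRuns(cfg, tru, "localizer", 1)
    run <- sim$runs[[1]][[1]]
    pre <- file.path(tempdir(), "run1")
    writeBoldRun(run, pre)
    rt <- readBoldRun(pre, roi = roiLabel(run), runId = runLabel(run),
                      task = taskLabel(run))
    expect_equal(boldData(rt), unname(boldData(run)), tolerance = 1e-6)
    expect_equal(framewiseDisplacement(rt), framewiseDisplacement(run),
                 tolerance = 1e-6)
    expect_equal(repetitionTime(rt), 2)
    # config/ground-truth YAML round trip
    yf <- tempfile(fileext = ".yaml")
    writeSimulationYaml(cfg, tru, yf)
    back2 <- readSimulationYaml(yf)
    expect_equal(back2$config@nVoxels, cfg@nVoxels)
    expect_equal(back2$truth@behaviorHitMeans, tru@behaviorHitMeans)
    expect_equal(back2$config@hrf@peakDelay, cfg@hrf@peakDelay)
})
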