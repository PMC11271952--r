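# Normalization chain, TR selection, classifier training, cross-validation
# and evidence sorting.

test_that("normalization chain steps produce the stated z-properties", {
    set.seed(1)
    runs <- lapply(1:2, function(r)
        plainRun(matrix(rnorm(12 * 40), 12, 40), run = r,
                 task = "localizer"))
    nv <- normalizeChain(runs, selection = NULL, step4 = TRUE)
    x <- nv@data
    # step 4: every voxel mean 0, sd 1 across retained volumes
    expect_lt(max(abs(colMeans(x))), 1e-9)
    expect_lt(max(abs(apply(x, 2, sd) - 1)), 1e-9)
    # step 2 inspected directly: per-volume z across voxels
    z12 <- attnrep:::.runZ(runs[[1]])
    expect_lt(max(abs(rowMeans(z12))), 1e-9)
    expect_lt(max(abs(apply(z12, 1, sd) - 1)), 1e-9)
    # fewer than 2 volumes errors
    expect_error(normalizeChain(list(plainRun(matrix(1:4, 4, 1)))),
                 "2 volumes")
})

test_that("the chain is idempotent on its fixed points and zeroes constants", {
    set.seed(2)
    run <- plainRun(matrix(rnorm(10 * 30), 10, 30), run = 1)
    z1 <- attnrep:::.runZ(run)
    # feeding back data that already satisfy steps 1-2 leaves them intact
    # up to the voxel-wise re-z of step 1 (already satisfied columnwise)
    runFix <- plainRun(t(attnrep:::.zcols(z1)), run = 1)
    z2 <- attnrep:::.runZ(runFix)
    expect_equal(z2, attnrep:::.runZ(runFix), tolerance = 1e-12)
    # constant voxel maps to zeros at step 1, with a warning
    x <- matrix(rnorm(5 * 20), 5, 20); x[3, ] <- 7
    expect_warning(z1c <- attnrep:::.zcols(t(x), warn = TRUE), "constant")
    expect_true(all(z1c[, 3] == 0))
    expect_warning(attnrep:::.runZ(plainRun(x, run = 1)), "constant")
})

test_that("phase-volume selection follows the hand-built timeline", {
    # trial starting at t = 20 s: picture onset 22 s (vol 12, 1-based),
    # encoding volume = onset vol + 2 -> t = 26 s -> index 14;
    # maintenance = the 2 TRs covering [28, 32) -> indices 15, 16
    ev <- data.frame(subject = 1, run = 1, trial = 1, onset = 20,
                     duration = 8, condition = "prospective",
                     attended_category = 1, ignored_category = 2,
                     attended_side = "left", item_attended = "PA_c1_01",
                     item_ignored = "PI_c2_01", round = 1,
                     is_catch = FALSE)
    enc <- selectPhaseVolumes(ev, tr = 2, phase = "encoding")
    expect_equal(enc$v1, 14)
    mai <- selectPhaseVolumes(ev, tr = 2, phase = "maintenance")
    expect_equal(c(mai$v1, mai$v2), c(15, 16))
    ptr <- selectPhaseVolumes(ev, tr = 2, phase = "per-tr")
    expect_equal(ptr$v1, 11 + 2 + 0:3)
    expect_equal(ptr$phase, paste0("TR", 0:3))
    # localizer: third TR after picture onset; 10 pictures -> 10 volumes
    loc <- data.frame(onset = 40 + (0:9) * 2, duration = 2, run = 1,
                      item = paste0("LOC_c1_", 1:10), category = "face")
    selL <- selectPhaseVolumes(loc, tr = 2, phase = "localizer")
    expect_equal(nrow(selL), 10)
    expect_equal(selL$v1, (40 + (0:9) * 2) / 2 + 3)
    # off-grid onset errors with the trial named
    evBad <- ev; evBad$onset <- 21
    expect_error(selectPhaseVolumes(evBad, tr = 2, phase = "encoding"),
                 "TR grid")
    # catch trials are skipped
    ev2 <- rbind(ev, transform(ev, onset = 40, trial = 2, is_catch = TRUE))
    expect_equal(nrow(selectPhaseVolumes(ev2, tr = 2, "encoding")), 1)
})

test_that("classifier separates separable data and is duplication-invariant", {
    set.seed(3)
    n <- 40
    x <- rbind(matrix(rnorm(n, mean = 3), n / 2, 2),
               matrix(rnorm(n, mean = -3), n / 2, 2))
    y <- rep(c("a", "b"), each = n / 2)
    m <- trainClassifier(x, y, C = 1, step4 = FALSE)
    p <- predictEvidence(m, x)
    expect_equal(mean(m@classes[max.col(p)] == y), 1)
    # duplicating every example scales the data-fit term but leaves the
    # optimum of the rescaled problem unchanged: same boundary as C doubled
    m2 <- trainClassifier(rbind(x, x), c(y, y), C = 0.5, step4 = FALSE)
    mC <- trainClassifier(x, y, C = 1, step4 = FALSE)
    expect_equal(m2@weights, mC@weights, tolerance = 1e-6)
    expect_equal(m2@intercepts, mC@intercepts, tolerance = 1e-6)
    # missing class errors
    expect_error(trainClassifier(x, c(rep("a", n - 1), "b"), C = 1),
                 "2 examples")
})

test_that("the Newton solver sits at the penalized-likelihood optimum", {
    set.seed(4)
    x <- matrix(rnorm(60 * 5), 60, 5)
    y <- ifelse(rowSums(x[, 1:2]) + rnorm(60) > 0, 1, -1)
    fit <- attnrep:::.l2Logistic(x, y, C = 0.01)
    obj <- function(w, b) {
        z <- y * (drop(x %*% w) + b)
        0.5 * sum(w^2) + 0.01 * sum(log1p(exp(-z)))
    }
    f0 <- obj(fit$w, fit$b)
    # random perturbations never improve the objective
    for (i in 1:50) {
        dw <- rnorm(5, sd = 1e-3); db <- rnorm(1, sd = 1e-3)
        expect_gte(obj(fit$w + dw, fit$b + db), f0 - 1e-10)
    }
})

test_that("renormalized probabilities conserve mass", {
    set.seed(5)
    m <- trainClassifier(matrix(rnorm(40 * 6), 40, 6),
                         rep(c("face", "scene", "object", "gabor"), 10),
                         C = 0.01, step4 = FALSE)
    p <- predictEvidence(m, matrix(rnorm(25 * 6), 25, 6))
    expect_lt(max(abs(rowSums(p) - 1)), 1e-9)
    # equal raw outputs renormalize to exactly 1/4 each
    m0 <- m
    m0@weights[] <- 0; m0@intercepts[] <- 0.2
    p0 <- predictEvidence(m0, matrix(rnorm(5 * 6), 5, 6))
    expect_equal(unname(p0), matrix(0.25, 5, 4), tolerance = 1e-12)
})

test_that("leave-one-run-out reports one fold per run and skips degenerate folds", {
    set.seed(6)
    mk <- function() matrix(rnorm(20 * 4), 20, 4)
    vols <- list(mk(), mk(), mk())
    labs <- list(rep(c("a", "b"), 10), rep(c("a", "b"), 10),
                 rep(c("a", "b"), 10))
    cv <- loroCrossValidate(vols, labs, C = 0.1)
    expect_equal(cv$nFolds, 3)
    expect_length(cv$foldAccuracy, 3)
    labs1 <- labs; labs1[[2]] <- rep("a", 20)
    expect_warning(cv1 <- loroCrossValidate(vols, labs1, C = 0.1),
                   "single class")
    expect_equal(cv1$nFolds, 2)
    expect_error(loroCrossValidate(vols[1], labs[1]), ">= 2 runs")
})

test_that("strong signal decodes above 0.9, shuffled labels at chance", {
    # volume-level oracle with known separability: class prototypes plus
    # small noise must cross-validate near ceiling
    set.seed(30)
    V <- 30; cls <- c("face", "scene", "object", "gabor")
    protos <- matrix(rnorm(V * 4), V, 4)
    mkRun <- function() {
        lab <- rep(cls, each = 10)
        x <- t(protos[, match(lab, cls)]) + matrix(rnorm(40 * V, sd = 0.3),
                                                   40, V)
        list(x = x, lab = lab)
    }
    runs <- lapply(1:3, function(i) mkRun())
    cvS <- loroCrossValidate(lapply(runs, `[[`, "x"),
                             lapply(runs, `[[`, "lab"))
    expect_gt(cvS$meanAccuracy, 0.9)
    # full BOLD path at prototype SNR >> 1: accuracy is capped slightly
    # lower because block-edge volumes mix neighboring conditions through
    # the hemodynamic lag, as in the real block design
    cfg <- smallConfig(seed = 31, nSubjects = 1, nVoxels = 30,
                       noiseSd = 1)
    tru <- groundTruth(itemSd = 0.2)
    sim <- simulateTaskRuns(cfg, tru, "localizer", 1)
    lv <- localizerVolumes(sim$runs[[1]], sim$events)
    cv <- loroCrossValidate(lv$volumesByRun, lv$labelsByRun)
    expect_gt(cv$meanAccuracy, 0.8)
    # label shuffling (fixed seeds) lands inside the binomial chance band
    set.seed(99)
    accs <- replicate(12, {
        shuf <- lapply(lv$labelsByRun, sample)
        loroCrossValidate(lv$volumesByRun, shuf)$meanAccuracy
    })
    nTest <- length(unlist(lv$labelsByRun))
    se <- sqrt(0.25 * 0.75 / (nTest * 12))
    expect_lt(abs(mean(accs) - 0.25), 4 * se + 0.02)
})

test_that("decoding pipeline is invariant to a consistent voxel permutation", {
    cfg <- smallConfig(seed = 17, nSubjects = 1, nVoxels = 16,
                       roiNames = "VTC")
    tru <- groundTruth(ignoredRoiScale = c(VTC = 1))
    loc <- simulateTaskRuns(cfg, tru, "localizer", 1)
    att <- simulateTaskRuns(cfg, tru, "attention", 1)
    decode <- function(locRuns, attRuns) {
        lv <- localizerVolumes(locRuns, loc$events)
        m <- trainClassifier(do.call(rbind, lv$volumesByRun),
                             unlist(lv$labelsByRun))
        decodeAttention(m, attRuns, att$events, "encoding", cfg)
    }
    perm <- sample(cfg@nVoxels)
    permRun <- function(r) boldRun(boldData(r)[perm, ],
                                   tr = repetitionTime(r),
                                   roi = roiLabel(r), run = runLabel(r),
                                   task = taskLabel(r),
                                   motion = motionParams(r),
                                   fd = framewiseDisplacement(r))
    r1 <- decode(loc$runs$VTC, att$runs$VTC)
    r2 <- decode(lapply(loc$runs$VTC, permRun),
                 lapply(att$runs$VTC, permRun))
    expect_equal(r1$attended, r2$attended, tolerance = 1e-8)
    expect_equal(r1$ignored, r2$ignored, tolerance = 1e-8)
})

test_that("evidence sorting maps categories onto roles correctly", {
    cfg <- smallConfig(seed = 23, nSubjects = 1, nVoxels = 16,
                       roiNames = "VTC")
    tru <- groundTruth(ignoredRoiScale = c(VTC = 1))
    loc <- simulateTaskRuns(cfg, tru, "localizer", 1)
    att <- simulateTaskRuns(cfg, tru, "attention", 1)
    lv <- localizerVolumes(loc$runs$VTC, loc$events)
    m <- trainClassifier(do.call(rbind, lv$volumesByRun),
                         unlist(lv$labelsByRun))
    rec <- decodeAttention(m, att$runs$VTC, att$events, "encoding", cfg)
    # conservation including the rest class
    tot <- rec$attended + ifelse(is.na(rec$ignored), 0, rec$ignored) +
        rec$other + rec$rest
    expect_lt(max(abs(tot - 1)), 1e-9)
    # baseline trials carry no ignored role
    expect_true(all(is.na(rec$ignored[rec$condition == "baseline"])))
    expect_true(all(!is.na(rec$ignored[rec$condition != "baseline"])))
    # 3-class renormalization mode: no rest mass
    rec3 <- decodeAttention(m, att$runs$VTC, att$events, "encoding", cfg,
                            renorm = "pictures")
    expect_true(all(rec3$rest == 0))
    tot3 <- rec3$attended + ifelse(is.na(rec3$ignored), 0, rec3$ignored) +
        rec3$other
    expect_lt(max(abs(tot3 - 1)), 1e-9)
    # contrasts: identical evidence in all roles -> all contrasts zero
    fake <- rec
    fake$attended <- 0.25; fake$other <- 0.25; fake$rest <- 0.25
    fake$ignored <- ifelse(is.na(fake$ignored), NA, 0.25)
    ec <- evidenceContrasts(fake)
    expect_true(all(abs(ec$contrasts$value) < 1e-12 |
                    is.na(ec$contrasts$value)))
})

test_that("SME splits join item memory outcomes to their own role evidence", {
    cfg <- smallConfig(seed = 27, nSubjects = 1, nVoxels = 12,
                       roiNames = "VTC", nItemsPerCondition = 6)
    tru <- groundTruth(ignoredRoiScale = c(VTC = 1))
    att <- attentionEvents(cfg, 1)
    # fabricate evidence records deterministically coupled to items
    nb <- att[!att$is_catch, ]
    rec <- data.frame(subject = 1, roi = "VTC", run = nb$run,
                      trial = nb$trial, phase = "encoding",
                      condition = nb$condition,
                      item_attended = nb$item_attended,
                      item_ignored = nb$item_ignored,
                      attended = 0.5, ignored = ifelse(
                          is.na(nb$item_ignored), NA, 0.2),
                      other = 0.2, rest = 0.1)
    beh <- simulateBehavior(cfg, tru)
    beh <- beh[beh$subject == 1, ]
    # force remembered PA items to carry higher attended evidence
    hits <- beh$item[beh$response %in% 1:2]
    rec$attended <- ifelse(rec$item_attended %in% hits, 0.7, 0.3)
    ec <- evidenceContrasts(rec, behavior = beh)
    sme <- ec$sme
    pa <- sme[sme$group == "PA", ]
    expect_equal(pa$sme, 0.7 - 0.3, tolerance = 1e-9)
})
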