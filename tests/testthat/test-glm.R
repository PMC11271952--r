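# HRF, design construction, GLM estimation and the least-squares-separate
# single-trial path.

test_that("double-gamma kernel peaks where dense evaluation says it should", {
    # independent dense evaluation of the difference-of-gammas formula
    t <- seq(0, 32, by = 0.001)
    p <- hrfParams()
    dense <- dgamma(t, shape = 6, scale = 1) -
        dgamma(t, shape = 16, scale = 1) / 6
    peakT <- t[which.max(dense)]
    expect_gt(peakT, 4); expect_lt(peakT, 7)
    h <- doubleGammaHrf(p, tr = 0.1)
    expect_equal(max(h), 1)
    expect_equal(attr(h, "times")[which.max(h)], peakT, tolerance = 0.1)
    # huge ratio: undershoot vanishes, kernel non-negative
    h2 <- doubleGammaHrf(hrfParams(peakUndershootRatio = 1e9), tr = 0.5)
    expect_true(all(h2 >= -1e-12))
    expect_error(doubleGammaHrf(p, tr = -1), "positive")
    expect_error(hrfParams(peakDelay = -6), "positive")
})

test_that("convolution is causal and preserves signal length", {
    ft <- seq(0, 100, by = 2)
    reg <- attnrep:::.convolveEvents(20, 2, 1, ft, hrfParams())
    expect_length(reg, length(ft))
    expect_true(all(abs(reg[ft < 20]) < 1e-12))
    expect_gt(max(reg), 0)
})

test_that("censor columns are one-hot and track the strict FD threshold", {
    nT <- 50
    fd <- rep(0.1, nT); fd[c(5, 20, 33)] <- c(0.31, 0.9, 0.5)
    fd[10] <- 0.3   # equality is NOT censored
    run <- plainRun(matrix(rnorm(4 * nT), 4, nT), fd = fd)
    ev <- data.frame(onset = c(0, 30), duration = 8,
                     regressor = c("a", "b"))
    des <- buildDesign(ev, run)
    roles <- columnRoles(des)
    cen <- which(roles == "censor")
    expect_length(cen, 3)
    X <- designMatrix(des)
    for (j in cen) expect_equal(sum(X[, j]), 1)
    expect_setequal(colnames(X)[cen], paste0("censor_", c(5, 20, 33)))
    # no FD above threshold -> no censor columns
    run0 <- plainRun(matrix(rnorm(4 * nT), 4, nT))
    des0 <- buildDesign(ev, run0)
    expect_length(which(columnRoles(des0) == "censor"), 0)
    # events past the run end error
    expect_error(buildDesign(data.frame(onset = 200, duration = 2,
                                        regressor = "x"), run0),
                 "run end")
})

test_that("single-event task column equals HRF x boxcar", {
    nT <- 60
    run <- plainRun(matrix(rnorm(4 * nT), 4, nT))
    des <- buildDesign(data.frame(onset = 0, duration = 8,
                                  regressor = "trial"), run)
    ft <- frameTimes(des)
    oracle <- attnrep:::.convolveEvents(0, 8, 1, ft, hrfParams())
    expect_equal(designMatrix(des)[, "trial"], oracle, tolerance = 1e-12)
})

test_that("GLM recovers known coefficients and matches brute-force t", {
    set.seed(1)
    nT <- 80
    ev <- data.frame(onset = c(0, 30, 60), duration = 8,
                     regressor = c("a", "b", "a"))
    run <- plainRun(matrix(0, 3, nT))
    des <- buildDesign(ev, run)
    X <- designMatrix(des)
    b <- c(2, -1, 0.5, 0.2, -0.3, 0.1, 0.05, -0.1, 0.7, 3)[seq_len(ncol(X))]
    y <- drop(X %*% b)
    runY <- plainRun(rbind(y, y * 2, y - 1), fd = framewiseDisplacement(run))
    fit <- fitGlm(des, runY)
    expect_equal(unname(fit$coef["a", 1]), b[1], tolerance = 1e-8)
    expect_equal(unname(fit$coef["b", 1]), b[2], tolerance = 1e-8)
    # noisy voxel: t equals the normal-equation oracle
    yn <- y + rnorm(nT)
    fitN <- fitGlm(des, plainRun(matrix(yn, 1)))
    expect_equal(unname(fitN$tstat[, 1]), unname(bruteOlsT(X, yn)),
                 tolerance = 1e-8)
    # residual df = timepoints - rank
    expect_equal(fitN$df, nT - qr(X)$rank)
    # rank deficiency names the collinear column
    Xev <- data.frame(onset = c(0, 0), duration = 8,
                      regressor = c("a", "acopy"))
    expect_error(fitGlm(buildDesign(Xev, run), runY), "acopy|collinear")
})

test_that("t-statistics are invariant to per-voxel affine rescaling", {
    set.seed(2)
    nT <- 60
    ev <- data.frame(onset = c(4, 30), duration = 4, regressor = "a")
    run <- plainRun(matrix(rnorm(2 * nT), 2, nT))
    des <- buildDesign(ev, run)
    f1 <- fitGlm(des, run)
    scaled <- boldData(run) * 7 + 100
    f2 <- fitGlm(des, plainRun(scaled))
    expect_equal(f1$tstat["a", ], f2$tstat["a", ], tolerance = 1e-9)
    flipped <- boldData(run) * -3
    f3 <- fitGlm(des, plainRun(flipped))
    expect_equal(f1$tstat["a", ], -f3$tstat["a", ], tolerance = 1e-9)
})

test_that("pure-noise t-statistics are Student-t distributed", {
    set.seed(3)
    nT <- 100
    V <- 5000
    ev <- data.frame(onset = c(10, 50), duration = 8, regressor = "a")
    run <- plainRun(matrix(rnorm(V * nT), V, nT))
    fit <- fitGlm(buildDesign(ev, run), run)
    ks <- ks.test(fit$tstat["a", ], pt, df = fit$df)
    expect_gt(ks$p.value, 0.01)
})

test_that("censored volumes are fully ignored by the estimates", {
    set.seed(4)
    nT <- 70
    fd <- runif(nT, 0.01, 0.1); fd[c(12, 13, 40)] <- 1
    x <- matrix(rnorm(3 * nT), 3, nT)
    ev <- data.frame(onset = c(8, 40), duration = 8, regressor = "a")
    run1 <- plainRun(x, fd = fd)
    f1 <- fitGlm(buildDesign(ev, run1), run1)
    x2 <- x; x2[, c(12, 13, 40)] <- 999
    run2 <- plainRun(x2, fd = fd)
    f2 <- fitGlm(buildDesign(ev, run2), run2)
    expect_equal(f1$coef["a", ], f2$coef["a", ], tolerance = 1e-8)
    expect_equal(f1$tstat["a", ], f2$tstat["a", ], tolerance = 1e-8)
})

# helper: recognition-style event table on one run
lssEvents <- function(onsets, cls = NULL, run = 1, duration = 2) {
    n <- length(onsets)
    if (is.null(cls)) cls <- rep("trial", n)
    data.frame(onset = onsets, duration = duration,
               item = paste0("it", seq_len(n)), run = run, class = cls)
}

test_that("LSS with a single trial reduces to the ordinary GLM", {
    set.seed(5)
    nT <- 50
    x <- matrix(rnorm(4 * nT), 4, nT)
    run <- plainRun(x, run = 1, task = "recognition")
    ev <- lssEvents(10)
    pat <- suppressWarnings(lssSingleTrial(ev, list(run)))
    des <- buildDesign(data.frame(onset = 10, duration = 2,
                                  regressor = "target"), run)
    ref <- fitGlm(des, run)
    expect_equal(unname(patternData(pat)[, 1]),
                 unname(ref$tstat["target", ]), tolerance = 1e-8)
})

test_that("LSS equals the brute-force all-trials GLM on non-overlapping designs", {
    set.seed(6)
    nT <- 130
    onsets <- c(10, 54, 98)   # HRF support 32 s: no temporal overlap
    x <- matrix(rnorm(5 * nT), 5, nT)
    run <- plainRun(x, run = 1, task = "recognition")
    ev <- lssEvents(onsets)
    pat <- lssSingleTrial(ev, list(run))
    # oracle: one GLM with a separate regressor per trial, solved by
    # brute-force normal equations; coefficients must agree
    des <- buildDesign(data.frame(onset = onsets, duration = 2,
                                  regressor = paste0("tr", seq_along(onsets))),
                       run)
    X <- designMatrix(des)
    XtX <- t(X) %*% X
    lssCoef <- SummarizedExperiment::assay(pat, "coef")
    for (v in seq_len(nrow(x))) {
        bFull <- drop(solve(XtX, t(X) %*% x[v, ]))
        expect_equal(unname(lssCoef[v, ]),
                     unname(bFull[seq_along(onsets)]), tolerance = 1e-8)
    }
})

test_that("widely spaced trials recover ground-truth amplitudes", {
    set.seed(7)
    nT <- 300
    onsets <- seq(10, 560, by = 40)  # gaps >= 20 s
    amps <- runif(length(onsets), 0.5, 3)
    ft <- (seq_len(nT) - 1) * 2
    y <- numeric(nT)
    for (i in seq_along(onsets))
        y <- y + amps[i] * attnrep:::.convolveEvents(onsets[i], 2, 1, ft,
                                                     hrfParams())
    V <- 6
    x <- matrix(rep(y, each = V), V, nT) *
        matrix(runif(V, 0.5, 2), V, nT) +
        matrix(rnorm(V * nT, sd = 0.05), V, nT)
    run <- plainRun(x, run = 1, task = "recognition")
    pat <- lssSingleTrial(lssEvents(onsets), list(run))
    est <- colMeans(patternData(pat))
    expect_gt(cor(est, amps, method = "spearman"), 0.95)
})

test_that("two overlapping equal-amplitude trials give equal estimates", {
    nT <- 60
    ft <- (seq_len(nT) - 1) * 2
    y <- attnrep:::.convolveEvents(20, 2, 1, ft, hrfParams()) +
        attnrep:::.convolveEvents(24, 2, 1, ft, hrfParams())
    # the two target models span the same columns, so equal true
    # amplitudes must give equal (and exact) coefficient estimates
    run <- plainRun(matrix(y, 1), run = 1, task = "recognition")
    pat <- lssSingleTrial(lssEvents(c(20, 24)), list(run))
    co <- SummarizedExperiment::assay(pat, "coef")
    expect_equal(co[1, 1], co[1, 2], tolerance = 1e-8)
    expect_equal(unname(co[1, 1]), 1, tolerance = 1e-8)
})

test_that("a fully censored target is flagged missing", {
    nT <- 60
    set.seed(8)
    fd <- runif(nT, 0.01, 0.1)
    fd[11:16] <- 1      # covers t in [20, 30)
    x <- matrix(rnorm(3 * nT), 3, nT)
    run <- plainRun(x, fd = fd, run = 1, task = "recognition")
    ev <- lssEvents(c(20, 40))
    pat <- lssSingleTrial(ev, list(run))
    info <- patternInfo(pat)
    expect_false(info$ok[info$item == "it1"])
    expect_true(info$ok[info$item == "it2"])
    expect_true(all(is.na(patternData(pat)[, !info$ok])))
})
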