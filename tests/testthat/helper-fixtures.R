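# Shared desk-scale fixtures built in code. Sizes are kept small so the
# whole suite runs quickly; scientific conditions (timing, gains,
# orderings) follow the package defaults.

smallConfig <- function(seed = 1, ...) {
    args <- list(nSubjects = 2, nVoxels = 20, nItemsPerCondition = 6,
                 nRunsAttention = 2, nRunsLocalizer = 3,
                 nRunsRecognition = 2, seed = seed)
    args[names(list(...))] <- list(...)
    do.call(simulationConfig, args)
}

# a quiet BoldRun with injectable data for GLM-level tests
plainRun <- function(data, tr = 2, fd = NULL, motion = NULL, roi = "VTC",
                     run = 1, task = "test") {
    boldRun(data, tr = tr, roi = roi, run = run, task = task,
            motion = motion, fd = fd)
}

# independent sums-of-squares decomposition for a fully within-subject
# two-factor design (oracle for rmAnova2way)
bruteRmAnovaAcc <- function(d) {
    g <- mean(d$y)
    mS <- tapply(d$y, d$subject, mean)
    mA <- tapply(d$y, d$A, mean)
    mB <- tapply(d$y, d$B, mean)
    mAB <- tapply(d$y, list(d$A, d$B), mean)
    mSA <- tapply(d$y, list(d$subject, d$A), mean)
    mSB <- tapply(d$y, list(d$subject, d$B), mean)
    a <- nlevels(factor(d$A)); b <- nlevels(factor(d$B))
    n <- nlevels(factor(d$subject))
    ssA <- n * b * sum((mA - g)^2)
    ssB <- n * a * sum((mB - g)^2)
    ssAB <- n * sum((mAB - outer(mA - g, mB - g, "+") - g)^2)
    errA <- b * sum((mSA - outer(mS, mA, "+") + g)^2)
    errB <- a * sum((mSB - outer(mS, mB, "+") + g)^2)
    full <- tapply(d$y, list(d$subject, d$A, d$B), mean)
    errAB <- 0
    for (i in seq_len(n)) for (j in seq_len(a)) for (k in seq_len(b))
        errAB <- errAB + (full[i, j, k] - mSA[i, j] - mSB[i, k] -
                          mAB[j, k] + mS[i] + mA[j] + mB[k] - g)^2
    data.frame(
        effect = c("A", "B", "A:B"),
        F = c((ssA / (a - 1)) / (errA / ((n - 1) * (a - 1))),
              (ssB / (b - 1)) / (errB / ((n - 1) * (b - 1))),
              (ssAB / ((a - 1) * (b - 1))) /
                  (errAB / ((n - 1) * (a - 1) * (b - 1)))))
}

# brute-force OLS + t oracle (normal equations), independent of fitGlm
bruteOlsT <- function(X, y) {
    XtX <- t(X) %*% X
    beta <- solve(XtX, t(X) %*% y)
    res <- y - X %*% beta
    df <- nrow(X) - qr(X)$rank
    s2 <- sum(res^2) / df
    se <- sqrt(diag(solve(XtX)) * s2)
    drop(beta / se)
}
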