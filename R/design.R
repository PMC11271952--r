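#' Build a first-level design matrix
#'
#' Turns a table of events into HRF-convolved task regressors and appends
#' the nuisance block (six motion traces, the FD trace, an intercept) and
#' one one-hot censor column per volume whose framewise displacement
#' exceeds the threshold (strictly greater than 0.3 mm by default;
#' equality is not censored).
#'
#' @param events data.frame with columns \code{onset}, \code{duration}
#'   (seconds), \code{regressor} (column name; events sharing a name are
#'   summed into one boxcar regressor) and optionally \code{amplitude}
#'   (default 1) and \code{role} (\code{"task"} or \code{"nuisance"},
#'   default task)
#' @param run a \code{\linkS4class{BoldRun}}
#' @param hrf \code{\linkS4class{HrfParams}} for the convolution
#' @param fdThreshold censoring threshold in mm (volumes with FD strictly
#'   greater are censored)
#' @param addNuisance append motion/FD/intercept columns
#' @param highpass if TRUE, append a discrete-cosine drift basis
#'   (100-s cutoff) as nuisance columns
#' @return a \code{\linkS4class{DesignMatrix}}. Conditions named in
#'   \code{events} but with zero events are omitted, recorded in attribute
#'   \code{"omitted"} with a warning.
#' @export
buildDesign <- function(events, run, hrf = hrfParams(), fdThreshold = 0.3,
                        addNuisance = TRUE, highpass = FALSE) {
    stopifnot(is(run, "BoldRun"))
    tr <- repetitionTime(run)
    nT <- ncol(run)
    ft <- colData(run)$frameTime
    runEnd <- nT * tr
    events <- as.data.frame(events)
    if (is.null(events$amplitude)) events$amplitude <- 1
    if (is.null(events$role)) events$role <- "task"
    late <- events$onset >= runEnd
    if (any(late))
        stop(sprintf("%d event(s) start at/after run end (%g s)",
                     sum(late), runEnd))

    regNames <- unique(events$regressor)
    cols <- list(); roles <- character(); omitted <- character()
    for (rn in regNames) {
        ev <- events[events$regressor == rn, , drop = FALSE]
        if (nrow(ev) == 0L) { omitted <- c(omitted, rn); next }
        cols[[rn]] <- .convolveEvents(ev$onset, ev$duration, ev$amplitude,
                                      ft, hrf)
        roles[rn] <- ev$role[1]
    }
    if (length(omitted))
        warning("omitting empty condition column(s): ",
                paste(omitted, collapse = ", "))

    if (addNuisance) {
        mot <- motionParams(run)
        # all-zero confound traces (e.g. motion-free synthetic runs) carry
        # no information and would make the design singular
        for (j in 1:6) {
            if (all(mot[, j] == 0)) next
            cols[[paste0("motion", j)]] <- mot[, j]
            roles[paste0("motion", j)] <- "nuisance"
        }
        fdv <- framewiseDisplacement(run)
        if (!all(fdv == 0)) { cols[["fd"]] <- fdv; roles["fd"] <- "nuisance" }
        cols[["intercept"]] <- rep(1, nT)
        roles["intercept"] <- "nuisance"
    }
    if (highpass) {
        K <- max(0L, floor(2 * runEnd / 100))
        for (k in seq_len(K)) {
            nm <- paste0("dct", k)
            cols[[nm]] <- cos(pi * k * (seq_len(nT) - 0.5) / nT)
            roles[nm] <- "nuisance"
        }
    }
    cen <- which(framewiseDisplacement(run) > fdThreshold)
    for (v in cen) {
        nm <- paste0("censor_", v)
        col <- numeric(nT); col[v] <- 1
        cols[[nm]] <- col
        roles[nm] <- "censor"
    }
    X <- do.call(cbind, cols)
    colnames(X) <- names(cols)
    dm <- new("DesignMatrix", matrix = X, frameTimes = ft,
              role = roles[colnames(X)])
    attr(dm, "omitted") <- omitted
    dm
}

#' Fit an ordinary-least-squares GLM per voxel
#'
#' @param design a \code{\linkS4class{DesignMatrix}}
#' @param run a \code{\linkS4class{BoldRun}} (or voxel x timepoint matrix)
#' @return list with \code{coef} and \code{tstat} (regressor x voxel
#'   matrices), residual \code{df} (timepoints minus design rank) and
#'   per-voxel residual standard deviation \code{sigma}. t = coefficient /
#'   standard error.
#' @export
fitGlm <- function(design, run) {
    Y <- if (is(run, "BoldRun")) t(boldData(run)) else t(as.matrix(run))
    .olsFit(designMatrix(design), Y)
}

.olsFit <- function(X, Y) {
    if (nrow(X) != nrow(Y))
        stop("design rows must equal run timepoints")
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
        drop <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
        stop("rank-deficient design; collinear column(s): ",
             paste(drop, collapse = ", "))
    }
    beta <- qr.coef(qx, Y)
    res <- Y - X %*% beta
    df <- nrow(X) - qx$rank
    sigma2 <- colSums(res^2) / df
    R <- qr.R(qx)
    XtXinv <- chol2inv(R)[order(qx$pivot), order(qx$pivot), drop = FALSE]
    se <- sqrt(outer(diag(XtXinv), sigma2))
    tstat <- beta / se
    rownames(beta) <- rownames(tstat) <- colnames(X)
    list(coef = beta, tstat = tstat, df = df, sigma = sqrt(sigma2))
}

#' Least-squares-separate single-trial estimation
#'
#' For each target trial fits its own GLM containing (i) the target-trial
#' regressor, (ii) one regressor pooling all other non-catch trials,
#' (iii) separate foil and no-response regressors when present, and
#' (iv) nuisance and censor columns; the target column's t-map is the
#' trial's pattern. Iterated over all target trials and runs.
#'
#' @param events data.frame with columns \code{onset}, \code{duration},
#'   \code{item}, \code{run} and \code{class}; rows with
#'   \code{class == "trial"} are the LSS targets, \code{"foil"} and
#'   \code{"noresponse"} rows become their own pooled regressors, any other
#'   class (e.g. catch) is excluded from the trial pool but still modeled
#'   as nuisance
#' @param runs list of \code{\linkS4class{BoldRun}} for one ROI, named or
#'   ordered to match \code{events$run}
#' @param hrf \code{\linkS4class{HrfParams}}
#' @param fdThreshold censoring threshold (mm)
#' @return a \code{\linkS4class{TrialPatternSet}} (voxels x target trials).
#'   A target whose regressor mass falls entirely on censored volumes is
#'   flagged \code{ok = FALSE} with NA values.
#' @export
lssSingleTrial <- function(events, runs, hrf = hrfParams(),
                           fdThreshold = 0.3) {
    events <- as.data.frame(events)
    stopifnot(all(c("onset", "duration", "item", "run", "class") %in%
                  colnames(events)))
    if (!is.list(runs)) runs <- list(runs)
    runIds <- vapply(runs, function(r) as.character(runLabel(r)), "")
    pats <- list(); coefs <- list(); info <- list()
    for (ri in seq_along(runs)) {
        run <- runs[[ri]]
        ev <- events[as.character(events$run) == runIds[ri], , drop = FALSE]
        ft <- colData(run)$frameTime
        fd <- framewiseDisplacement(run)
        nT <- ncol(run)
        Y <- t(boldData(run))
        # one convolved regressor per event, batched into a single FFT
        R <- .convolveEach(ev$onset, ev$duration, ft, hrf)
        nuis <- cbind(motionParams(run), fd = fd, intercept = 1)
        colnames(nuis) <- c(paste0("motion", 1:6), "fd", "intercept")
        nuis <- nuis[, colnames(nuis) == "intercept" |
                       colSums(nuis != 0) > 0, drop = FALSE]
        cen <- which(fd > fdThreshold)
        C <- matrix(0, nT, length(cen))
        if (length(cen)) {
            C[cbind(cen, seq_along(cen))] <- 1
            colnames(C) <- paste0("censor_", cen)
        }
        pool <- function(cls) {
            j <- which(ev$class == cls)
            if (length(j)) rowSums(R[, j, drop = FALSE]) else NULL
        }
        foils <- pool("foil"); noresp <- pool("noresponse")
        extraCls <- setdiff(unique(ev$class),
                            c("trial", "foil", "noresponse"))
        extras <- do.call(cbind, c(list(NULL),
            lapply(extraCls, function(cl) pool(cl))))
        if (!is.null(extras)) colnames(extras) <- paste0("nuis_", extraCls)
        trialIdx <- which(ev$class == "trial")
        for (ti in trialIdx) {
            key <- paste0(runIds[ri], "_", ev$item[ti])
            # target counts as fully censored when every volume from its
            # onset to the hemodynamic peak of its epoch is censored
            support <- which(ft >= ev$onset[ti] &
                             ft < ev$onset[ti] + ev$duration[ti] + 8)
            if (length(support) && all(fd[support] > fdThreshold)) {
                pats[[key]] <- coefs[[key]] <- rep(NA_real_, nrow(run))
                info[[key]] <- data.frame(item = ev$item[ti],
                                          run = runIds[ri], ok = FALSE)
                next
            }
            oth <- setdiff(trialIdx, ti)
            cols <- list(target = R[, ti])
            if (length(oth)) cols$others <- rowSums(R[, oth, drop = FALSE])
            if (!is.null(foils)) cols$foils <- foils
            if (!is.null(noresp)) cols$noresponse <- noresp
            X <- cbind(do.call(cbind, cols), extras, nuis, C)
            colnames(X)[seq_along(cols)] <- names(cols)
            fit <- .olsFit(X, Y)
            pats[[key]] <- fit$tstat["target", ]
            coefs[[key]] <- fit$coef["target", ]
            info[[key]] <- data.frame(item = ev$item[ti], run = runIds[ri],
                                      ok = TRUE)
        }
    }
    values <- do.call(cbind, pats)
    colnames(values) <- names(pats)
    coefValues <- do.call(cbind, coefs)
    colnames(coefValues) <- names(coefs)
    trialPatternSet(values, do.call(rbind, info), roi = roiLabel(runs[[1]]),
                    coef = coefValues)
}
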