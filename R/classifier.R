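# One-vs-rest L2-regularized logistic regression. The binary subproblem
# minimizes 0.5 * ||w||^2 + C * sum_i log(1 + exp(-y_i (x_i'w + b)))
# (liblinear-style convention: C multiplies the data-fit term; the
# intercept is not penalized). The problem is strictly convex, so Newton
# iterations converge to the unique optimum deterministically.

.l2Logistic <- function(X, y, C, tol = 1e-10, maxit = 200) {
    n <- nrow(X); p <- ncol(X)
    Xb <- cbind(X, 1)
    theta <- numeric(p + 1)
    pen <- c(rep(1, p), 0)            # intercept unpenalized
    for (it in seq_len(maxit)) {
        eta <- drop(Xb %*% theta)
        mu <- 1 / (1 + exp(-eta))
        grad <- pen * theta + C * drop(crossprod(Xb, mu - (y + 1) / 2))
        if (max(abs(grad)) < tol) break
        wgt <- pmax(mu * (1 - mu), 1e-10)
        H <- C * crossprod(Xb * wgt, Xb) + diag(pen)
        step <- solve(H, grad)
        # damped Newton: halve until the objective decreases
        obj <- function(th) {
            z <- y * drop(Xb %*% th)
            # stable log(1 + exp(-z))
            loss <- ifelse(z > 0, log1p(exp(-z)), -z + log1p(exp(z)))
            0.5 * sum(pen * th^2) + C * sum(loss)
        }
        f0 <- obj(theta)
        lam <- 1
        repeat {
            cand <- theta - lam * step
            if (obj(cand) <= f0 + 1e-12 || lam < 1e-8) break
            lam <- lam / 2
        }
        theta <- theta - lam * step
    }
    list(w = theta[seq_len(p)], b = theta[p + 1])
}

.applyTaskZ <- function(x, center, scale) {
    if (!length(center)) return(x)
    s <- scale
    s[!is.finite(s) | s == 0] <- Inf
    scale(x, center = center, scale = s)[, , drop = FALSE]
}

#' Train the one-vs-rest category classifier
#'
#' Fits one binary L2-penalized logistic classifier per class (the three
#' picture categories plus the Gabor/rest class in the standard pipeline)
#' on localizer volumes that have passed steps 1-3 of the normalization
#' chain. The task-level per-voxel z (step 4) is estimated on the training
#' volumes, applied before fitting, and stored in the model so held-out
#' data can be normalized identically.
#'
#' @param x volume x voxel matrix (normalization steps 1-3 applied)
#' @param labels class label per volume
#' @param C inverse-regularization constant; multiplies the data-fit term
#' @param step4 estimate and apply the task-level z before fitting
#' @return a \code{\linkS4class{ClassifierModel}}.
#' @export
trainClassifier <- function(x, labels, C = 0.01, step4 = TRUE) {
    x <- as.matrix(x)
    labels <- as.character(labels)
    stopifnot(nrow(x) == length(labels))
    classes <- sort(unique(labels))
    counts <- table(labels)
    if (any(counts < 2))
        stop("need >= 2 examples per class; short: ",
             paste(names(counts)[counts < 2], collapse = ", "))
    center <- numeric(); scl <- numeric()
    if (step4) {
        center <- colMeans(x)
        scl <- apply(x, 2, stats::sd)
        x <- .applyTaskZ(x, center, scl)
    }
    W <- matrix(0, ncol(x), length(classes),
                dimnames = list(NULL, classes))
    b <- stats::setNames(numeric(length(classes)), classes)
    for (cl in classes) {
        y <- ifelse(labels == cl, 1, -1)
        fit <- .l2Logistic(x, y, C)
        W[, cl] <- fit$w
        b[cl] <- fit$b
    }
    new("ClassifierModel", classes = classes, weights = W,
        intercepts = unname(b), cost = C, center = center, scale = scl)
}

#' Class-probability evidence
#'
#' Sigmoid outputs of the binary one-vs-rest classifiers, renormalized by
#' the sum over classes so each volume's probabilities sum to 1.
#'
#' @param model a \code{\linkS4class{ClassifierModel}}
#' @param x volume x voxel matrix on the same normalization footing as the
#'   training data
#' @param applyModelZ apply the model's stored task-level z parameters
#'   (used for held-out localizer runs in cross-validation; attention-task
#'   volumes are z-scored within their own task instead)
#' @return volume x class matrix of renormalized probabilities.
#' @export
predictEvidence <- function(model, x, applyModelZ = FALSE) {
    x <- as.matrix(x)
    if (ncol(x) != nrow(model@weights))
        stop("voxel dimension mismatch between model and data")
    if (applyModelZ) x <- .applyTaskZ(x, model@center, model@scale)
    eta <- sweep(x %*% model@weights, 2, model@intercepts, "+")
    p <- 1 / (1 + exp(-eta))
    p / rowSums(p)
}

#' Leave-one-run-out cross-validation
#'
#' Holds out each localizer run in turn, refits the data-dependent
#' normalization (the task-level z of step 4) and the classifier on the
#' remaining runs, and scores classification accuracy on the held-out run.
#' Folds whose held-out run contains fewer than two classes are skipped
#' with a warning.
#'
#' @param volumesByRun list (one element per run) of volume x voxel
#'   matrices after normalization steps 1-3
#' @param labelsByRun list of label vectors matching \code{volumesByRun}
#' @param C inverse-regularization constant
#' @return list with \code{foldAccuracy} (named per held-out run),
#'   \code{meanAccuracy} and \code{nFolds}.
#' @export
loroCrossValidate <- function(volumesByRun, labelsByRun, C = 0.01) {
    stopifnot(length(volumesByRun) == length(labelsByRun))
    if (length(volumesByRun) < 2) stop("need >= 2 runs")
    runs <- names(volumesByRun)
    if (is.null(runs)) runs <- as.character(seq_along(volumesByRun))
    acc <- stats::setNames(rep(NA_real_, length(runs)), runs)
    for (k in seq_along(runs)) {
        testLab <- labelsByRun[[k]]
        if (length(unique(testLab)) < 2) {
            warning("fold ", runs[k], " skipped: held-out run has a single class")
            next
        }
        trainX <- do.call(rbind, volumesByRun[-k])
        trainLab <- unlist(labelsByRun[-k])
        model <- trainClassifier(trainX, trainLab, C = C, step4 = TRUE)
        p <- predictEvidence(model, volumesByRun[[k]], applyModelZ = TRUE)
        pred <- model@classes[max.col(p, ties.method = "first")]
        acc[k] <- mean(pred == testLab)
    }
    list(foldAccuracy = acc, meanAccuracy = mean(acc, na.rm = TRUE),
         nFolds = sum(!is.na(acc)))
}

#' Localizer training volumes and labels
#'
#' Applies normalization steps 1-3 to the localizer runs of one ROI using
#' the third-TR-after-onset selection, returning per-run matrices and
#' labels ready for \code{\link{trainClassifier}} or
#' \code{\link{loroCrossValidate}}.
#'
#' @param runs list of localizer \code{\linkS4class{BoldRun}} for one ROI
#' @param events localizer schedule (\code{\link{localizerEvents}})
#' @return list with \code{volumesByRun}, \code{labelsByRun}.
#' @export
localizerVolumes <- function(runs, events) {
    runIds <- vapply(runs, function(r) as.character(runLabel(r)), "")
    vols <- list(); labs <- list()
    for (i in seq_along(runs)) {
        ev <- events[as.character(events$run) == runIds[i], , drop = FALSE]
        sel <- selectPhaseVolumes(ev, tr = repetitionTime(runs[[i]]),
                                  phase = "localizer")
        sel$run <- runIds[i]
        nv <- normalizeChain(runs[i], sel, step4 = FALSE)
        vols[[runIds[i]]] <- nv@data
        labs[[runIds[i]]] <- ev$category[sel$row]
    }
    list(volumesByRun = vols, labelsByRun = labs)
}
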