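# Group inference utilities shared by all stages: paired t-tests,
# within-subject two-way ANOVA, BH-FDR and within-subject error bars.

#' Paired t-test
#'
#' Classical two-sided paired t-test across subjects, df = n - 1.
#'
#' @param a,b numeric vectors by subject (pairs with a missing member are
#'   dropped)
#' @param contrast label for the output row
#' @return one-row data.frame: \code{contrast}, \code{t}, \code{df},
#'   \code{p}, \code{mean_diff}, \code{n}.
#' @export
pairedT <- function(a, b, contrast = "a_minus_b") {
    ok <- is.finite(a) & is.finite(b)
    a <- a[ok]; b <- b[ok]
    if (length(a) < 3) stop("need >= 3 complete pairs")
    if (stats::sd(a - b) == 0) {
        if (all(a == b))
            return(data.frame(contrast = contrast, t = 0,
                              df = length(a) - 1, p = 1,
                              mean_diff = 0, n = length(a)))
        stop("zero variance of paired differences")
    }
    tt <- stats::t.test(a, b, paired = TRUE)
    data.frame(contrast = contrast, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               mean_diff = unname(tt$estimate), n = length(a))
}

#' Two-way repeated-measures ANOVA
#'
#' Fully within-subject two-factor ANOVA (e.g. cue x attention) fitted via
#' \code{aov} with \code{Error(subject/(A*B))} strata; each effect is
#' tested against its own subject-by-factor error term.
#'
#' @param data data.frame in long format
#' @param subject,factorA,factorB,value column names
#' @return data.frame with rows for the two main effects and the
#'   interaction: \code{effect}, \code{F}, \code{df1}, \code{df2},
#'   \code{p}.
#' @export
rmAnova2way <- function(data, subject = "subject", factorA = "A",
                        factorB = "B", value = "y") {
    d <- data.frame(subject = factor(data[[subject]]),
                    A = factor(data[[factorA]]),
                    B = factor(data[[factorB]]),
                    y = data[[value]])
    if (any(!stats::complete.cases(d)))
        stop("missing cells are not allowed (no imputation)")
    counts <- table(d$subject, d$A, d$B)
    if (any(counts != 1))
        stop("design must be complete with one observation per subject x A x B cell")
    fit <- stats::aov(y ~ A * B + Error(subject / (A * B)), data = d)
    s <- summary(fit)
    pull <- function(stratum, term) {
        tab <- s[[stratum]][[1]]
        i <- grep(paste0("^", term, "\\s*$"), trimws(rownames(tab)))
        data.frame(effect = term, F = tab[i, "F value"],
                   df1 = tab[i, "Df"],
                   df2 = tab[grep("Residuals", rownames(tab)), "Df"],
                   p = tab[i, "Pr(>F)"])
    }
    res <- rbind(pull("Error: subject:A", "A"),
                 pull("Error: subject:B", "B"),
                 pull("Error: subject:A:B", "A:B"))
    rownames(res) <- NULL
    res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values within one declared comparison family;
#' monotone and capped at 1.
#'
#' @param p raw p-values (all in [0, 1])
#' @return adjusted p-values, same order as the input.
#' @export
fdrBH <- function(p) {
    if (!length(p)) stop("empty p-value family")
    if (any(!is.finite(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Within-subject standard errors
#'
#' Cousineau-normalized error bars with the Morey bias correction: each
#' value is centered on its subject's mean (plus the grand mean), the
#' per-condition SEM of the centered values is scaled by
#' sqrt(c / (c - 1)) for c conditions. With a single condition the plain
#' SEM is returned.
#'
#' @param data long data.frame
#' @param subject,condition,value column names
#' @return data.frame per condition: \code{condition}, \code{mean},
#'   \code{wse}, \code{n}.
#' @export
withinSubjectSem <- function(data, subject = "subject",
                             condition = "condition", value = "y") {
    d <- data.frame(subject = factor(data[[subject]]),
                    condition = factor(data[[condition]]),
                    y = data[[value]])
    if (any(!stats::complete.cases(d))) stop("complete data required")
    if (any(table(d$subject, d$condition) != 1))
        stop("one value per subject x condition required")
    cN <- nlevels(d$condition)
    subjMean <- stats::ave(d$y, d$subject)
    centered <- d$y - subjMean + mean(d$y)
    corr <- if (cN > 1) sqrt(cN / (cN - 1)) else 1
    res <- do.call(rbind, lapply(levels(d$condition), function(cc) {
        yy <- centered[d$condition == cc]
        data.frame(condition = cc, mean = mean(d$y[d$condition == cc]),
                   wse = corr * stats::sd(yy) / sqrt(length(yy)),
                   n = length(yy))
    }))
    rownames(res) <- NULL
    res
}

#' Group summary table for figure-style reporting
#'
#' Combines per-condition means, Cousineau-Morey within-subject standard
#' errors and (optionally) a paired test per named contrast into one tidy
#' table, ready to write as CSV for a figure panel.
#'
#' @param data long data.frame of per-subject values
#' @param subject,condition,value column names
#' @param contrasts optional named list; each element is a length-2
#'   character vector of condition levels to compare by paired t-test,
#'   with BH-FDR across the listed contrasts
#' @return list with \code{cells} (condition, mean, wse, n) and
#'   \code{tests} (contrast, t, df, p, p_fdr; NULL when no contrasts).
#' @export
groupSummaryTable <- function(data, subject = "subject",
                              condition = "condition", value = "y",
                              contrasts = NULL) {
    cells <- withinSubjectSem(data, subject, condition, value)
    tests <- NULL
    if (!is.null(contrasts)) {
        s <- data[[subject]]; cc <- data[[condition]]; y <- data[[value]]
        subjects <- sort(unique(s))
        pick <- function(lev)
            y[match(paste(subjects, lev), paste(s, cc))]
        tests <- do.call(rbind, lapply(names(contrasts), function(nm) {
            ab <- contrasts[[nm]]
            pairedT(pick(ab[1]), pick(ab[2]), contrast = nm)
        }))
        tests$p_fdr <- fdrBH(tests$p)
    }
    list(cells = cells, tests = tests)
}
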