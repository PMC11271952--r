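#' Double-gamma hemodynamic response function
#'
#' Samples the canonical double-gamma HRF — the difference of two gamma
#' densities, the undershoot scaled by \code{1/peakUndershootRatio} — on a
#' regular grid and normalizes the kernel to unit peak.
#'
#' @param params an \code{\linkS4class{HrfParams}} object
#' @param tr sampling interval (s); must be > 0
#' @return numeric kernel sampled at \code{0, tr, 2*tr, ...} over the
#'   kernel duration, peak value 1, with attribute \code{"times"}.
#' @examples
#' h <- doubleGammaHrf(hrfParams(), tr = 0.1)
#' attr(h, "times")[which.max(h)]  # peaks near 5 s
#' @export
doubleGammaHrf <- function(params = hrfParams(), tr = 2) {
    if (!is.numeric(tr) || tr <= 0) stop("tr must be positive")
    validObject(params)
    times <- seq(0, params@duration, by = tr)
    h <- .hrfShape(times, params)
    h <- h / max(h)
    attr(h, "times") <- times
    h
}

.hrfShape <- function(t, params) {
    a1 <- params@peakDelay / params@peakDispersion
    a2 <- params@undershootDelay / params@undershootDispersion
    stats::dgamma(t, shape = a1, scale = params@peakDispersion) -
        stats::dgamma(t, shape = a2, scale = params@undershootDispersion) /
            params@peakUndershootRatio
}

# Convolve a set of boxcars with the HRF on a fine grid and sample at the
# requested frame times. Returns a length(frameTimes) regressor.
.convolveEvents <- function(onsets, durations, amplitudes, frameTimes,
                            params = hrfParams(), dt = 0.1) {
    stopifnot(length(onsets) == length(durations),
              length(onsets) == length(amplitudes))
    L <- floor(max(frameTimes) / dt + 1e-9) + 1L
    stim <- matrix(0, L, 1)
    grid <- (seq_len(L) - 1) * dt
    for (i in seq_along(onsets)) {
        idx <- which(grid >= onsets[i] & grid < onsets[i] + durations[i])
        stim[idx, 1] <- stim[idx, 1] + amplitudes[i]
    }
    drop(.fftConvolveSample(stim, frameTimes, params, dt))
}

# one boxcar regressor per event, convolved in a single batched FFT
.convolveEach <- function(onsets, durations, frameTimes,
                          params = hrfParams(), dt = 0.1) {
    L <- floor(max(frameTimes) / dt + 1e-9) + 1L
    stim <- matrix(0, L, length(onsets))
    for (e in seq_along(onsets)) {
        i0 <- floor(onsets[e] / dt + 1e-9) + 1
        i1 <- min(L, ceiling((onsets[e] + durations[e]) / dt - 1e-9))
        grid0 <- (i0:i1 - 1) * dt
        keep <- grid0 >= onsets[e] & grid0 < onsets[e] + durations[e]
        stim[(i0:i1)[keep], e] <- 1
    }
    .fftConvolveSample(stim, frameTimes, params, dt)
}

.fftConvolveSample <- function(stim, frameTimes, params, dt) {
    kern <- .hrfShape(seq(0, params@duration, by = dt), params)
    kern <- kern / max(kern)
    L <- nrow(stim); K <- length(kern)
    n <- stats::nextn(L + K, 2)
    fk <- stats::fft(c(kern, numeric(n - K)))
    fs <- stats::mvfft(rbind(stim, matrix(0, n - L, ncol(stim))))
    conv <- Re(stats::mvfft(fs * fk, inverse = TRUE)) / n * dt
    conv[pmin(L, round(frameTimes / dt) + 1), , drop = FALSE]
}
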