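#' Band-pass filter a recording
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass, default
#' 500-5000 Hz, the band used to isolate action potentials from raw
#' extracellular signals. Zero-phase filtering preserves spike latencies;
#' the pass band removes DC.
#'
#' @param rec a \linkS4class{Recording}.
#' @param low,high band edges (Hz); the sampling rate must exceed
#'   \code{2 * high}.
#' @return the filtered \linkS4class{Recording}.
#' @export
bandpassFilter <- function(rec, low = 500, high = 5000) {
    stopifnot(is(rec, "Recording"))
    if (rec@rate <= 2 * high)
        stop("sampling rate must exceed twice the upper band edge",
             call. = FALSE)
    bf <- signal::butter(4, c(low, high) / (rec@rate / 2), type = "pass")
    rec@signal <- as.numeric(signal::filtfilt(bf, rec@signal))
    rec
}

#' Detect spikes by baseline-derived threshold
#'
#' The detection threshold is the mean plus \code{k} (default 3) standard
#' deviations of the background signal in a stimulus-free baseline window.
#' Detection runs on the negative-going signal by default (extracellular
#' convention); threshold exceedances are grouped into events (one spike per
#' suprathreshold run, timed at its peak), and events closer than the
#' refractory period are merged into the earlier one.
#'
#' @param rec a (typically band-pass filtered) \linkS4class{Recording}.
#' @param baselineWindow two-element window (s) containing no stimuli.
#' @param polarity \code{"negative"}, \code{"positive"} or
#'   \code{"absolute"}.
#' @param refractory minimum inter-spike interval (s).
#' @param k threshold multiplier on the baseline SD.
#' @param minAmplitude optional amplitude floor (uV, detection polarity);
#'   events below it are discarded. Used for single-unit isolation, the
#'   automated counterpart of trial-by-trial waveform verification.
#' @return a \linkS4class{SpikeTrain}.
#' @export
detectSpikes <- function(rec, baselineWindow = c(0, 0.4),
                         polarity = c("negative", "positive", "absolute"),
                         refractory = 0.001, k = 3, minAmplitude = NULL) {
    stopifnot(is(rec, "Recording"))
    polarity <- match.arg(polarity)
    bw <- baselineWindow
    if (length(bw) != 2L || bw[2] <= bw[1])
        stop("'baselineWindow' must be an increasing 2-element window",
             call. = FALSE)
    if (any(rec@stimTimes >= bw[1] & rec@stimTimes <= bw[2]))
        stop("'baselineWindow' must contain no stimuli", call. = FALSE)
    x <- switch(polarity,
                negative = -rec@signal,
                positive = rec@signal,
                absolute = abs(rec@signal - mean(rec@signal)))
    i0 <- max(1L, floor(bw[1] * rec@rate) + 1L)
    i1 <- min(length(x), ceiling(bw[2] * rec@rate))
    if (i1 <= i0) stop("empty baseline window", call. = FALSE)
    base <- x[i0:i1]
    thr <- mean(base) + k * stats::sd(base)

    above <- x > thr
    if (!any(above))
        return(new("SpikeTrain", times = numeric(), amplitudes = numeric(),
                   threshold = thr, baselineWindow = bw,
                   refractory = refractory))
    d <- diff(c(FALSE, above, FALSE))
    starts <- which(d == 1L); ends <- which(d == -1L) - 1L
    peaks <- mapply(function(s, e) s - 1L + which.max(x[s:e]), starts, ends)
    amps <- x[peaks]
    ## merge events within the refractory period into the earlier one
    keep <- logical(length(peaks))
    last <- -Inf
    gap <- refractory * rec@rate
    for (j in seq_along(peaks)) {
        if (peaks[j] - last >= gap) {
            keep[j] <- TRUE
            last <- peaks[j]
        }
    }
    times <- (peaks[keep] - 1L) / rec@rate
    amps <- amps[keep]
    if (!is.null(minAmplitude)) {
        ok <- amps >= minAmplitude
        times <- times[ok]; amps <- amps[ok]
    }
    new("SpikeTrain", times = times, amplitudes = amps, threshold = thr,
        baselineWindow = bw, refractory = refractory)
}

#' Match spikes to stimuli
#'
#' Builds the per-stimulus response table: for each stimulus, the
#' largest-amplitude spike inside the post-stimulus response window is taken
#' as the unit's response and recorded with its latency and amplitude.
#' Using the amplitude maximum (rather than the first crossing) is the
#' automated stand-in for visual verification of the action-potential
#' waveform on every trial.
#'
#' @param spikes a \linkS4class{SpikeTrain}.
#' @param stim either a \linkS4class{Recording} (stimulus times and
#'   frequencies are taken from it) or a numeric vector of stimulus times
#'   (s).
#' @param window response window (ms post-stimulus), default 0.5-10 ms;
#'   the lower edge blanks the stimulus artifact. The window must not reach
#'   the next stimulus.
#' @param stimFreq per-stimulus train frequency (Hz) when \code{stim} is a
#'   plain vector.
#' @return a \linkS4class{StimResponseTable}.
#' @export
buildResponseTable <- function(spikes, stim, window = c(0.5, 10),
                               stimFreq = NA_real_) {
    stopifnot(is(spikes, "SpikeTrain"))
    if (is(stim, "Recording")) {
        stimT <- stim@stimTimes
        stimF <- if (length(stim@stimFreq)) stim@stimFreq else
            rep(NA_real_, length(stimT))
    } else {
        stimT <- stim
        stimF <- rep_len(stimFreq, length(stimT))
    }
    if (length(stimT) == 0) stop("no stimuli", call. = FALSE)
    if (length(stimT) > 1L && window[2] / 1000 > min(diff(stimT)))
        stop("response window exceeds the inter-stimulus interval",
             call. = FALSE)
    st <- spikes@times; sa <- spikes@amplitudes
    n <- length(stimT)
    responded <- logical(n); latency <- rep(NA_real_, n)
    amplitude <- rep(NA_real_, n)
    for (i in seq_len(n)) {
        rel <- (st - stimT[i]) * 1000
        inWin <- which(rel >= window[1] & rel <= window[2])
        if (length(inWin)) {
            j <- inWin[which.max(sa[inWin])]
            responded[i] <- TRUE
            latency[i] <- rel[j]
            amplitude[i] <- sa[j]
        }
    }
    new("StimResponseTable",
        table = data.frame(stim_time = stimT, responded = responded,
                           latency = latency, amplitude = amplitude,
                           stim_freq = stimF, collided = NA),
        window = window)
}

#' Peristimulus time histogram
#'
#' Spike counts in half-open bins \code{[t, t + bin)} of time relative to
#' stimulus onset, accumulated across stimuli and normalized to the
#' percentage of stimuli per bin.
#'
#' @param spikes a \linkS4class{SpikeTrain} or numeric spike times (s).
#' @param stimTimes stimulus times (s), at least one.
#' @param binWidth bin width (ms), default 1.
#' @param window pre/post window (ms), default \code{c(-20, 50)}.
#' @return a \linkS4class{PSTH}.
#' @export
computePSTH <- function(spikes, stimTimes, binWidth = 1,
                        window = c(-20, 50)) {
    st <- if (is(spikes, "SpikeTrain")) spikes@times else spikes
    if (length(stimTimes) == 0) stop("no stimuli", call. = FALSE)
    breaks <- seq(window[1], window[2], by = binWidth)
    if (abs(breaks[length(breaks)] - window[2]) > 1e-9)
        stop("'window' must be a whole number of bins", call. = FALSE)
    rel <- as.numeric(outer(st * 1000, stimTimes * 1000, "-"))
    rel <- rel[rel >= window[1] & rel < window[2]]
    counts <- tabulate(floor((rel - window[1]) / binWidth) + 1L,
                       length(breaks) - 1L)
    n <- length(stimTimes)
    new("PSTH", breaks = breaks, counts = as.numeric(counts),
        normalized = counts / n * 100, nStimuli = n, binWidth = binWidth)
}

#' Response efficiency
#'
#' Percentage of stimuli that evoked a time-locked response.
#'
#' @param responses a \linkS4class{StimResponseTable}.
#' @return efficiency in [0, 100].
#' @export
responseEfficiency <- function(responses) {
    stopifnot(is(responses, "StimResponseTable"))
    tab <- responses@table
    if (nrow(tab) == 0) stop("no stimuli", call. = FALSE)
    100 * mean(tab$responded)
}
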