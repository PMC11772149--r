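#' Simulate the full stimulation protocol for one unit
#'
#' Reproduces the sequential protocol used to identify antidromically
#' activated units: a low-frequency train (latency/amplitude
#' characterization), a high-frequency train (frequency following), and a
#' low-frequency train recorded with spontaneous orthodromic activity (the
#' collision assay). The scenario label encodes the programmed ground
#' truth: \code{"antidromic"} (tight latency, follows high frequency,
#' collision blocking on), \code{"synaptic"} (variable latency, unreliable
#' following, no collision blocking) or \code{"unresponsive"}.
#'
#' @param label ground-truth class of the simulated unit.
#' @param latency antidromic latency (ms).
#' @param jitter latency jitter SD (ms).
#' @param p response probability.
#' @param snr spike amplitude over noise SD; \code{Inf} for a noise-free
#'   recording.
#' @param seed RNG seed (three sub-seeds are derived from it).
#' @param nLow,nColl stimulus counts of the low-frequency and collision
#'   trains.
#' @param lowFreq,highFreq train frequencies (Hz).
#' @param spontRate spontaneous firing rate (Hz) during the collision
#'   assay.
#' @return list with elements \code{low}, \code{high}, \code{coll} (each a
#'   \code{\link{genRecording}} result), \code{label} and \code{params}.
#' @export
simulateUnitStudy <- function(label = c("antidromic", "synaptic",
                                        "unresponsive"),
                              latency = 3, jitter = 0.05, p = 1, snr = Inf,
                              seed = 1, nLow = 60, nColl = 150,
                              lowFreq = 4, highFreq = 100,
                              spontRate = 20) {
    label <- match.arg(label)
    amp <- 100
    noise <- if (is.finite(snr)) amp / snr else 0
    if (label == "unresponsive") p <- 0
    blocking <- label != "synaptic"
    jitter <- if (label == "synaptic") max(jitter, 1) else jitter
    base <- list(rate = 20000, unitLatency = latency,
                 latencyJitterSD = jitter, spikeAmplitude = amp,
                 noiseSD = noise, responseProb = p,
                 collisionBlocking = blocking)
    low <- do.call(genRecording, c(base, list(
        stimFreq = lowFreq, nStim = nLow, seed = seed * 10 + 1)))
    high <- do.call(genRecording, c(base, list(
        stimFreq = highFreq, nStim = 50, seed = seed * 10 + 2)))
    coll <- do.call(genRecording, c(base, list(
        stimFreq = lowFreq, nStim = nColl, spontRate = spontRate,
        seed = seed * 10 + 3)))
    list(low = low, high = high, coll = coll, label = label,
         params = c(base, list(seed = seed, snr = snr)))
}

#' Validation scenario grid for the antidromic pipeline
#'
#' The simulation study design used to validate parameter recovery and
#' classification: twenty units spanning antidromic latencies of 1-8 ms,
#' latency jitters of 0-0.5 ms and response probabilities of 0.2-1, split
#' into twelve antidromically activated units, four synaptically driven
#' mimics (variable latency, unreliable high-frequency following, no
#' collision blocking) and four unresponsive sites.
#'
#' @return data.frame with columns \code{label}, \code{latency} (ms),
#'   \code{jitter} (ms) and \code{p}.
#' @export
validationScenarios <- function() {
    rbind(
        data.frame(label = "antidromic",
                   latency = seq(1, 8, length.out = 12),
                   jitter = c(0, 0.05, 0.1, 0.15, 0.2, 0.25,
                              0.25, 0.2, 0.4, 0.1, 0, 0.05),
                   p = c(1, 1, 0.95, 1, 0.9, 1, 0.95, 1, 1, 0.9, 1, 0.95)),
        data.frame(label = "synaptic",
                   latency = c(6, 7, 7.5, 8),
                   jitter = c(1, 1.5, 1.5, 2),
                   p = c(0.2, 0.4, 0.5, 0.6)),
        data.frame(label = "unresponsive",
                   latency = c(2, 3, 5, 7), jitter = 0, p = 0))
}

#' Detect and isolate a single unit
#'
#' Two-stage detection: band-pass filtering and mean + 3 SD threshold
#' crossing, followed by an amplitude floor that isolates the unit — the
#' larger of \code{ampFactor} times the detection threshold and
#' \code{isoFrac} times the largest detected event amplitude. The floor
#' discards near-threshold noise crossings and filter ringing, playing the
#' role of the trial-by-trial visual verification of the action-potential
#' waveform.
#'
#' @param rec a raw \linkS4class{Recording}.
#' @param baselineWindow stimulus-free window (s) for the threshold.
#' @param ampFactor floor as a multiple of the detection threshold.
#' @param isoFrac floor as a fraction of the largest event amplitude.
#' @param ... passed to \code{\link{detectSpikes}}.
#' @return a \linkS4class{SpikeTrain} of the isolated unit.
#' @export
detectUnit <- function(rec, baselineWindow = c(0, 0.4), ampFactor = 1.8,
                       isoFrac = 0.5, ...) {
    f <- bandpassFilter(rec)
    det <- detectSpikes(f, baselineWindow = baselineWindow, ...)
    if (length(det@amplitudes) == 0) return(det)
    floorAmp <- max(ampFactor * det@threshold,
                    isoFrac * max(det@amplitudes))
    detectSpikes(f, baselineWindow = baselineWindow,
                 minAmplitude = floorAmp, ...)
}

#' Antidromic identification panel
#'
#' Runs the complete identification pipeline on the three protocol
#' recordings of a unit: band-pass filtering, mean + 3 SD spike detection
#' with an amplitude floor for single-unit isolation, response-table
#' construction, and the three antidromic criteria, returning the verdict
#' together with the intermediate tables.
#'
#' @param low,high,coll \linkS4class{Recording} objects for the
#'   low-frequency, high-frequency and collision protocols (\code{high} and
#'   \code{coll} optional).
#' @param responseWindow response window (ms) for the low-frequency train;
#'   for the high-frequency train the upper edge is clipped to the
#'   inter-stimulus interval.
#' @param ampFactor amplitude floor as a multiple of the detection
#'   threshold.
#' @param baselineWindow stimulus-free baseline (s) for the threshold.
#' @param latencySDTol,amplitudeCVTol,minEfficiency,latencyTol criterion
#'   tolerances, see the individual criterion functions.
#' @return list with \code{verdict} (an \linkS4class{AntidromicVerdict}),
#'   \code{efficiency} (low-frequency response efficiency, percent),
#'   \code{meanLatency} (ms), and the response tables.
#' @export
antidromicPanel <- function(low, high = NULL, coll = NULL,
                            responseWindow = c(0.5, 10), ampFactor = 1.8,
                            baselineWindow = c(0, 0.4),
                            latencySDTol = 0.3, amplitudeCVTol = 0.3,
                            minEfficiency = 90, latencyTol = 0.5) {
    analyze <- function(rec, window) {
        det <- detectUnit(rec, baselineWindow = baselineWindow,
                          ampFactor = ampFactor)
        list(spikes = det,
             table = buildResponseTable(det, rec, window = window))
    }
    lowA <- analyze(low, responseWindow)
    lowTab <- lowA$table
    cl <- checkConstantLatency(lowTab, latencySDTol, amplitudeCVTol)

    highTab <- NULL; ff <- NA
    if (!is.null(high)) {
        isi <- if (length(high@stimTimes) > 1)
            min(diff(high@stimTimes)) * 1000 else Inf
        win <- c(responseWindow[1], min(responseWindow[2], isi - 0.5))
        highA <- analyze(high, win)
        highTab <- highA$table
        ff <- checkFrequencyFollowing(highTab,
                                      minEfficiency = minEfficiency)
    }

    collTab <- NULL; cp <- NA
    if (!is.null(coll)) {
        collA <- analyze(coll, responseWindow)
        collTab <- collA$table
        expLat <- if (any(lowTab@table$responded))
            stats::median(lowTab@table$latency[lowTab@table$responded]) else
            NULL
        cp <- if (is.null(expLat)) NA else
            collisionTest(collTab, spikeTimes(collA$spikes),
                          expectedLatency = expLat,
                          latencyTol = latencyTol)
    }

    verdict <- classifyAntidromic(cl, ff, cp, responses = lowTab)
    resp <- lowTab@table$responded
    list(verdict = verdict,
         efficiency = responseEfficiency(lowTab),
         meanLatency = if (any(resp))
             mean(lowTab@table$latency[resp]) else NA_real_,
         lowTable = lowTab, highTable = highTab, collTable = collTab)
}
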