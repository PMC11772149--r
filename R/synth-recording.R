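#' Biphasic extracellular spike template
#'
#' A 1 ms biphasic waveform (negative lobe first, the extracellular
#' convention) sampled at the recording rate. Its spectral content lies in
#' the 500-5000 Hz analysis passband.
#'
#' @param rate sampling rate (Hz).
#' @param durationMs template duration (ms).
#' @return numeric vector of unit peak magnitude, with attribute
#'   \code{"peak"} giving the index of the (negative) peak sample.
#' @export
spikeTemplate <- function(rate, durationMs = 1) {
    nsmp <- round(rate * durationMs / 1000)
    if (nsmp < 4)
        stop("sampling rate too low to represent the spike template",
             call. = FALSE)
    t <- seq(0, 1, length.out = nsmp)
    w <- -sin(2 * pi * t) * sin(pi * t)    # biphasic, tapered to zero at ends
    w <- w / max(abs(w))
    structure(w, peak = which.min(w))
}

#' Simulate an extracellular recording with a stimulus-locked unit
#'
#' Builds a Gaussian-noise voltage trace containing a single antidromically
#' activated unit: each stimulus evokes, with probability
#' \code{responseProb}, a spike at \code{unitLatency} ms (plus Gaussian
#' jitter). Spontaneous orthodromic spikes fire at \code{spontRate}; when
#' collision blocking is on, any spontaneous spike falling within
#' \code{collisionWindow} ms before the expected antidromic arrival cancels
#' that trial's evoked spike (the trial is flagged \code{collided} in the
#' truth table). Stimulus and spike times are snapped to the sample grid.
#'
#' @param rate sampling rate (Hz), at least 8 kHz.
#' @param stimTimes stimulus times (s); alternatively give \code{stimFreq},
#'   \code{nStim} and \code{stimStart} to lay out a regular train.
#' @param stimFreq stimulation frequency (Hz) used to build the train and
#'   recorded per stimulus.
#' @param nStim number of stimuli when building a regular train.
#' @param stimStart onset of the train (s).
#' @param duration recording length (s); defaults to 50 ms past the last
#'   stimulus.
#' @param noiseSD background noise SD (uV).
#' @param unitLatency antidromic response latency (ms), > 0.
#' @param latencyJitterSD latency jitter SD (ms).
#' @param responseProb per-stimulus response probability in [0, 1].
#' @param spikeAmplitude spike peak amplitude (uV).
#' @param spontRate spontaneous (orthodromic) firing rate (Hz).
#' @param spontTimes optional explicit spontaneous spike times (s),
#'   overriding \code{spontRate}.
#' @param collisionWindow collision window (ms) before the expected
#'   antidromic arrival; default \code{unitLatency + 1} (latency plus a 1 ms
#'   refractory period).
#' @param collisionBlocking logical; disable to mimic a synaptically driven
#'   unit that does not collide.
#' @param artifactAmplitude optional square stimulus-artifact amplitude (uV),
#'   default off.
#' @param artifactMs artifact duration (ms).
#' @param stimSite \code{"rostral"} or \code{"caudal"}.
#' @param pathLength stimulation-to-soma path length (mm), for
#'   conduction-velocity work.
#' @param seed RNG seed.
#'
#' @return list with \code{recording} (a \linkS4class{Recording}),
#'   \code{truth} (per-stimulus data.frame: \code{stim_time},
#'   \code{responded}, \code{latency} in ms, \code{collided}),
#'   \code{spontTimes}, \code{template} and \code{params}.
#' @examples
#' sim <- genRecording(stimFreq = 2, nStim = 10, unitLatency = 3,
#'                     noiseSD = 0, seed = 1)
#' head(sim$truth)
#' @export
genRecording <- function(rate = 20000, stimTimes = NULL, stimFreq = 2,
                         nStim = 50, stimStart = 0.5, duration = NULL,
                         noiseSD = 10, unitLatency = 3, latencyJitterSD = 0,
                         responseProb = 1, spikeAmplitude = 80,
                         spontRate = 0, spontTimes = NULL,
                         collisionWindow = NULL, collisionBlocking = TRUE,
                         artifactAmplitude = 0, artifactMs = 0.3,
                         stimSite = "rostral", pathLength = NA_real_,
                         seed = 1) {
    if (rate < 8000)
        stop("sampling rate too low to represent the spike template",
             call. = FALSE)
    .checkScalar(unitLatency, "unitLatency", lower = 1e-9)
    .checkScalar(responseProb, "responseProb", 0, 1)
    .checkScalar(noiseSD, "noiseSD", 0)
    if (is.null(collisionWindow)) collisionWindow <- unitLatency + 1
    snap <- function(t) round(t * rate) / rate
    if (is.null(stimTimes))
        stimTimes <- stimStart + (seq_len(nStim) - 1) / stimFreq
    stimTimes <- snap(sort(stimTimes))
    if (is.null(duration)) duration <- max(stimTimes) + 0.05
    nsamp <- ceiling(duration * rate)
    tpl <- spikeTemplate(rate)
    tplPeak <- attr(tpl, "peak")

    withSeed(seed, {
        sig <- if (noiseSD > 0) stats::rnorm(nsamp, 0, noiseSD) else
            numeric(nsamp)

        if (is.null(spontTimes)) {
            spontTimes <- if (spontRate > 0) {
                nsp <- stats::rpois(1, spontRate * duration)
                st <- sort(stats::runif(nsp, 0, duration))
                st[c(TRUE, diff(st) > 0.002)]   # 2 ms refractory
            } else numeric()
        }
        spontTimes <- snap(sort(spontTimes))

        wouldRespond <- stats::runif(length(stimTimes)) < responseProb
        jit <- if (latencyJitterSD > 0)
            stats::rnorm(length(stimTimes), 0, latencyJitterSD) else
            numeric(length(stimTimes))
        arrival <- snap(stimTimes + (unitLatency + jit) / 1000)
        collided <- vapply(arrival, function(a)
            any(spontTimes > a - collisionWindow / 1000 & spontTimes < a),
            logical(1))
        responded <- wouldRespond & !(collided & collisionBlocking)
        latency <- ifelse(responded, (arrival - stimTimes) * 1000, NA_real_)

        addSpike <- function(sig, t, amp) {
            ctr <- round(t * rate) + 1L
            idx <- (ctr - tplPeak + 1L):(ctr - tplPeak + length(tpl))
            keep <- idx >= 1L & idx <= nsamp
            sig[idx[keep]] <- sig[idx[keep]] + amp * tpl[keep]
            sig
        }
        for (t in arrival[responded])
            sig <- addSpike(sig, t, spikeAmplitude)
        for (t in spontTimes)
            sig <- addSpike(sig, t, spikeAmplitude)
        if (artifactAmplitude > 0) {
            na <- max(1L, round(artifactMs / 1000 * rate))
            for (s in stimTimes) {
                i0 <- round(s * rate) + 1L
                idx <- i0:min(nsamp, i0 + na - 1L)
                sig[idx] <- sig[idx] + artifactAmplitude
            }
        }

        rec <- new("Recording", signal = sig, rate = rate,
                   stimTimes = stimTimes,
                   stimFreq = rep_len(stimFreq, length(stimTimes)),
                   stimSite = stimSite, pathLength = pathLength)
        list(recording = rec,
             truth = data.frame(stim_time = stimTimes, responded = responded,
                                latency = latency, collided = collided),
             spontTimes = spontTimes, template = tpl,
             params = list(rate = rate, noiseSD = noiseSD,
                           unitLatency = unitLatency,
                           latencyJitterSD = latencyJitterSD,
                           responseProb = responseProb,
                           spikeAmplitude = spikeAmplitude,
                           spontRate = spontRate,
                           collisionWindow = collisionWindow,
                           collisionBlocking = collisionBlocking,
                           seed = seed))
    })
}
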