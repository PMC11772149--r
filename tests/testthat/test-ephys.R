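mkRec <- function(signal, rate = 20000, stim = numeric(), freq = numeric())
    new("Recording", signal = signal, rate = rate, stimTimes = stim,
        stimFreq = freq)

test_that("band-pass keeps spike-band content and rejects LFP frequencies", {
    rate <- 20000; t <- (0:(rate * 2 - 1)) / rate
    lfp <- bandpassFilter(mkRec(sin(2 * pi * 50 * t)))@signal
    expect_lt(20 * log10(sd(lfp) / sd(sin(2 * pi * 50 * t))), -40)
    spk <- bandpassFilter(mkRec(sin(2 * pi * 1000 * t)))@signal
    expect_gt(20 * log10(sd(spk) / sd(sin(2 * pi * 1000 * t))), -3)
    expect_equal(bandpassFilter(mkRec(rep(0, rate)))@signal, rep(0, rate))
    expect_error(bandpassFilter(mkRec(rep(0, rate), rate = 8000)),
                 "twice the upper band edge")
})

test_that("planted spikes are detected at their times, flat signals give none", {
    g <- genRecording(stimFreq = 4, nStim = 20, unitLatency = 3,
                      responseProb = 1, noiseSD = 0, seed = 5)
    det <- detectUnit(g$recording)
    expect_length(spikeTimes(det), 20)
    expected <- g$truth$stim_time + g$truth$latency / 1000
    expect_true(all(abs(spikeTimes(det) - expected) <= 1 / 20000 + 1e-12))
    z <- detectSpikes(mkRec(rep(0, 20000)), baselineWindow = c(0, 0.5))
    expect_length(spikeTimes(z), 0)
})

test_that("threshold crossings on white noise match the Gaussian tail rate", {
    set.seed(9)
    n <- 200000
    det <- detectSpikes(mkRec(rnorm(n)), baselineWindow = c(0, 10))
    p <- 1 - pnorm(3)
    analytic <- n * p * (1 - p)   # run starts, before refractory grouping
    expect_gt(length(spikeTimes(det)), 0.6 * analytic)
    expect_lt(length(spikeTimes(det)), 1.2 * analytic)
})

test_that("response tables record first-window latencies per stimulus", {
    stim <- seq(0.5, 2.4, by = 0.1)
    spikes <- new("SpikeTrain", times = stim + 0.003,
                  amplitudes = rep(80, 20), threshold = 10,
                  baselineWindow = c(0, 0.4), refractory = 0.001)
    rt <- buildResponseTable(spikes, stim)
    expect_true(all(responseTable(rt)$responded))
    expect_equal(responseTable(rt)$latency, rep(3, 20))
    none <- buildResponseTable(new("SpikeTrain", times = numeric(),
                                   amplitudes = numeric(), threshold = 10,
                                   baselineWindow = c(0, 0.4),
                                   refractory = 0.001), stim)
    expect_false(any(responseTable(none)$responded))
    expect_error(buildResponseTable(spikes, stim, window = c(0.5, 200)),
                 "inter-stimulus")
})

test_that("PSTH bins are normalized to the stimulus count", {
    stim <- seq(0.5, 2.4, by = 0.1)
    p <- computePSTH(stim + 0.0032, stim)
    lower <- p@breaks[-length(p@breaks)]
    expect_equal(normalizedCounts(p)[lower == 3], 100)
    expect_equal(sum(p@counts), 20)
    ## 11 of 20 responses in one bin -> 55%
    p2 <- computePSTH(stim[1:11] + 0.0032, stim)
    expect_equal(normalizedCounts(p2)[lower == 3], 55)
    ## at most one spike per stimulus keeps the histogram under 100%
    expect_true(sum(normalizedCounts(p2)) <= 100)
    expect_error(computePSTH(1, numeric()), "no stimuli")
})

test_that("efficiency is the responded percentage", {
    mkRT <- function(responded) {
        n <- length(responded)
        new("StimResponseTable",
            table = data.frame(stim_time = seq_len(n), responded = responded,
                               latency = ifelse(responded, 3, NA),
                               amplitude = ifelse(responded, 80, NA),
                               stim_freq = 2, collided = NA),
            window = c(0.5, 10))
    }
    expect_equal(responseEfficiency(mkRT(rep(TRUE, 50))), 100)
    expect_equal(responseEfficiency(mkRT(rep(FALSE, 30))), 0)
    ## recovered efficiency equals the generator truth exactly
    g <- genRecording(stimFreq = 4, nStim = 500, unitLatency = 3,
                      responseProb = 0.47, noiseSD = 10, seed = 11)
    rt <- buildResponseTable(detectUnit(g$recording), g$recording)
    expect_equal(responseEfficiency(rt), 100 * mean(g$truth$responded))
})

rtWith <- function(lat, amp = rep(80, length(lat)), freq = 2) {
    n <- length(lat)
    new("StimResponseTable",
        table = data.frame(stim_time = seq_len(n),
                           responded = !is.na(lat), latency = lat,
                           amplitude = ifelse(is.na(lat), NA, amp),
                           stim_freq = freq, collided = NA),
        window = c(-10, 20))
}

test_that("constant-latency criterion compares SD and CV to tolerance", {
    expect_true(checkConstantLatency(rtWith(rep(3, 10))))
    set.seed(2)
    jittered <- rtWith(3 + rnorm(30, 0, 1.5))
    expect_false(checkConstantLatency(jittered, latencySDTol = 0.3))
    expect_true(is.na(checkConstantLatency(rtWith(c(3, 3, 3, 3, NA)))))
    wobblyAmp <- rtWith(rep(3, 10), amp = rep(c(20, 200), 5))
    expect_false(checkConstantLatency(wobblyAmp))
})

test_that("frequency-following requires high efficiency at >= 100 Hz", {
    hi <- rtWith(rep(3, 40), freq = 200)
    expect_true(checkFrequencyFollowing(hi))
    spotty <- rtWith(c(rep(3, 16), rep(NA, 24)), freq = 200)
    expect_false(checkFrequencyFollowing(spotty))
    lowOnly <- rtWith(rep(3, 40), freq = 5)
    expect_true(is.na(checkFrequencyFollowing(lowOnly)))
})

test_that("collision logic distinguishes blocked, unblocked and absent", {
    mkColl <- function(blocking) {
        ## spontaneous spikes 0.5 ms after every second stimulus: inside the
        ## critical window, clearly separated from the 3 ms response
        g <- genRecording(stimFreq = 2, nStim = 40, unitLatency = 3,
                          noiseSD = 0,
                          spontTimes = seq(0.5, 20, by = 1) + 0.0005,
                          collisionBlocking = blocking, seed = 3)
        det <- detectUnit(g$recording)
        rt <- buildResponseTable(det, g$recording)
        collisionTest(rt, spikeTimes(det), expectedLatency = 3)
    }
    expect_true(mkColl(TRUE))
    expect_false(mkColl(FALSE))
    g <- genRecording(stimFreq = 2, nStim = 20, unitLatency = 3,
                      noiseSD = 0, seed = 3)
    rt <- buildResponseTable(detectUnit(g$recording), g$recording)
    expect_true(is.na(collisionTest(rt, numeric(), expectedLatency = 3)))
})

test_that("two of three criteria define antidromic activation", {
    v <- classifyAntidromic(TRUE, TRUE, NA, hasResponses = TRUE)
    expect_equal(v@classification, "antidromic")
    expect_equal(v@nCriteriaMet, 2L)
    v2 <- classifyAntidromic(FALSE, FALSE, FALSE, hasResponses = TRUE)
    expect_equal(v2@classification, "synaptic")
    v3 <- classifyAntidromic(NA, FALSE, NA, hasResponses = FALSE)
    expect_equal(v3@classification, "unresponsive")
})

test_that("caudal responsiveness thresholds post bins on the baseline", {
    stim <- seq(1, 10.5, by = 0.5)
    p <- computePSTH(stim + 0.004, stim)   # silent baseline, locked response
    expect_true(caudalResponsiveness(p))
    pEmpty <- computePSTH(stim + 0.004, stim, window = c(-20, 0))
    expect_false(caudalResponsiveness(pEmpty))   # no post-stimulus bins
    pNoPre <- computePSTH(stim + 0.004, stim, window = c(0, 20))
    expect_error(caudalResponsiveness(pNoPre), "pre-stimulus")
})

test_that("caudal false-positive rate on Poisson nulls respects the bound", {
    ## rate-matched null: spikes independent of stimuli; k = 3 criterion
    set.seed(31)
    nbPost <- 50
    lambda <- 2
    fp <- 0; nsim <- 60
    for (i in 1:nsim) {
        counts <- rpois(70, lambda)
        p <- new("PSTH", breaks = seq(-20, 50), counts = counts,
                 normalized = counts / 40 * 100, nStimuli = 40,
                 binWidth = 1)
        if (caudalResponsiveness(p, k = 3)) fp <- fp + 1
    }
    thr <- lambda + 3 * sqrt(lambda)
    bound <- nbPost * ppois(floor(thr), lambda, lower.tail = FALSE)
    expect_lt(fp / nsim, min(1, bound) + 3 * sqrt(bound / nsim))
})

test_that("conduction velocity is path over latency", {
    expect_equal(conductionVelocity(1, 1), 1)
    expect_equal(conductionVelocity(57.3, 3), 19.1)
    expect_equal(conductionVelocity(57.0, 2), 28.5)
    expect_error(conductionVelocity(-1, 2), "positive")
    ## latency/velocity inverse consistency
    v <- 22.4; d <- 61.2
    expect_equal(conductionVelocity(d, d / v), v)
})

test_that("cohort summaries reproduce per-group means and percentages", {
    coh <- data.frame(
        group = rep(c("SCI+rGO", "SCI"), c(11, 4)),
        n_units = c(rep(4, 10), 5, rep(5, 4)),
        caudal_respondent = c(rep(TRUE, 3), rep(FALSE, 12)))
    s <- cohortSummary(coh)
    rgo <- s[s$group == "SCI+rGO", ]
    expect_equal(round(rgo$mean_units, 1), 4.1)
    expect_equal(s$mean_units[s$group == "SCI"], 5.0)
    expect_equal(round(rgo$pct_respondent, 1), 27.3)
    expect_equal(attr(s, "total_units"), 65)
    ## empty group: flagged
    coh2 <- rbind(coh, data.frame(group = factor("CTRL"), n_units = 0,
                                  caudal_respondent = FALSE))
    coh2$group <- factor(coh2$group, levels = c("SCI", "SCI+rGO", "CTRL"))
    s2 <- cohortSummary(coh2[coh2$group != "CTRL", ])
    expect_equal(attr(s2, "emptyGroups"), "CTRL")
})
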