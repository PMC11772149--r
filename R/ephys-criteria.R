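#' Constant-latency-and-amplitude criterion
#'
#' First antidromic criterion: across responded trials the latency SD must
#' not exceed \code{latencySDTol} and the amplitude coefficient of variation
#' must not exceed \code{amplitudeCVTol}. Indeterminate (\code{NA}) with
#' fewer than \code{minResponses} responses.
#'
#' @param responses a \linkS4class{StimResponseTable}.
#' @param latencySDTol latency SD tolerance (ms).
#' @param amplitudeCVTol amplitude CV tolerance (dimensionless).
#' @param minResponses minimum responded trials required.
#' @return \code{TRUE}, \code{FALSE} or \code{NA}.
#' @export
checkConstantLatency <- function(responses, latencySDTol = 0.3,
                                 amplitudeCVTol = 0.3, minResponses = 5) {
    stopifnot(is(responses, "StimResponseTable"))
    tab <- responses@table[responses@table$responded, ]
    if (nrow(tab) < minResponses) return(NA)
    latOK <- stats::sd(tab$latency) <= latencySDTol
    ampOK <- stats::sd(tab$amplitude) / mean(tab$amplitude) <= amplitudeCVTol
    latOK && ampOK
}

#' High-frequency-following criterion
#'
#' Second antidromic criterion: the unit must follow high-frequency
#' stimulation, i.e. its response efficiency over trials stimulated at or
#' above \code{minFreq} Hz must reach \code{minEfficiency} percent.
#' Indeterminate when no such trials exist.
#'
#' @param responses a \linkS4class{StimResponseTable} whose
#'   \code{stim_freq} column labels each trial's train frequency.
#' @param minFreq high-frequency cutoff (Hz), default 100.
#' @param minEfficiency required efficiency (percent), default 90.
#' @return \code{TRUE}, \code{FALSE} or \code{NA}.
#' @export
checkFrequencyFollowing <- function(responses, minFreq = 100,
                                    minEfficiency = 90) {
    stopifnot(is(responses, "StimResponseTable"))
    tab <- responses@table
    hi <- tab[!is.na(tab$stim_freq) & tab$stim_freq >= minFreq, ]
    if (nrow(hi) == 0) return(NA)
    100 * mean(hi$responded) >= minEfficiency
}

#' Collision test
#'
#' Third antidromic criterion: a spontaneous orthodromic action potential
#' travelling down the axon must collide with (and cancel) the antidromic
#' spike. Trials in which a spontaneous spike fell within the critical
#' window before the expected antidromic arrival are collision trials; the
#' test passes when the antidromic response (a spike at the expected
#' latency) is absent in at least \code{minBlockedFrac} of collision trials
#' while being present in the remaining trials. Indeterminate when no
#' collision trial is available.
#'
#' @param responses a \linkS4class{StimResponseTable}.
#' @param spontTimes spontaneous spike times (s) observed alongside the
#'   stimulation protocol.
#' @param expectedLatency expected antidromic latency (ms); default the
#'   median detected latency.
#' @param refractory refractory allowance (ms) extending the critical
#'   window before the stimulus.
#' @param latencyTol tolerance (ms) within which a response latency counts
#'   as the antidromic spike.
#' @param minBlockedFrac required fraction of blocked collision trials;
#'   the default 0.9 tolerates the occasional unrelated spontaneous spike
#'   landing at the antidromic latency by chance.
#' @return \code{TRUE}, \code{FALSE} or \code{NA}.
#' @export
collisionTest <- function(responses, spontTimes, expectedLatency = NULL,
                          refractory = 1, latencyTol = 0.5,
                          minBlockedFrac = 0.9) {
    stopifnot(is(responses, "StimResponseTable"))
    tab <- responses@table
    if (is.null(expectedLatency)) {
        if (!any(tab$responded)) return(NA)
        expectedLatency <- stats::median(tab$latency[tab$responded])
    }
    L <- expectedLatency
    ## critical window: from `refractory` ms before the stimulus up to just
    ## before the expected arrival
    isCollision <- vapply(tab$stim_time, function(s)
        any(spontTimes > s - refractory / 1000 &
            spontTimes < s + (L - latencyTol) / 1000),
        logical(1))
    if (!any(isCollision)) return(NA)
    ## the antidromic spike is present when either the matched response sits
    ## at the expected latency or any recorded spike does (the matched
    ## response may be the spontaneous spike itself)
    atLatency <- (tab$responded & !is.na(tab$latency) &
                  abs(tab$latency - L) <= latencyTol) |
        vapply(tab$stim_time, function(s)
            any(abs(spontTimes - s - L / 1000) <= latencyTol / 1000),
            logical(1))
    blocked <- mean(!atLatency[isCollision])
    presentElsewhere <- any(atLatency[!isCollision])
    (blocked >= minBlockedFrac) && presentElsewhere
}

#' Classify a unit from the three antidromic criteria
#'
#' A unit is antidromically activated when it meets at least two of the
#' three criteria (indeterminate flags count as unmet). A unit that fails
#' the panel but shows time-locked responses — typically with long or
#' variable latency, as produced by a synaptic input from neighbouring
#' neurons — is classed as synaptically activated; a unit without responses
#' is unresponsive.
#'
#' @param constantLatency,followsHighFreq,collisionPass criterion flags
#'   (\code{TRUE}/\code{FALSE}/\code{NA}).
#' @param responses optional \linkS4class{StimResponseTable} used to decide
#'   responsiveness; alternatively pass \code{hasResponses}.
#' @param hasResponses logical, whether any time-locked response was seen.
#' @return an \linkS4class{AntidromicVerdict}.
#' @export
classifyAntidromic <- function(constantLatency, followsHighFreq,
                               collisionPass, responses = NULL,
                               hasResponses = NULL) {
    if (is.null(hasResponses)) {
        hasResponses <- if (is.null(responses)) {
            isTRUE(constantLatency) || isTRUE(followsHighFreq)
        } else any(responses@table$responded)
    }
    flags <- c(constantLatency, followsHighFreq, collisionPass)
    nMet <- sum(flags, na.rm = TRUE)
    cls <- if (nMet >= 2L) "antidromic" else if (hasResponses) "synaptic"
        else "unresponsive"
    new("AntidromicVerdict",
        constantLatency = as.logical(constantLatency),
        followsHighFreq = as.logical(followsHighFreq),
        collisionPass = as.logical(collisionPass),
        nCriteriaMet = as.integer(nMet), classification = cls)
}

#' Caudal responsiveness from a PSTH
#'
#' A unit counts as respondent to caudal stimulation when a single
#' post-stimulus bin overcomes the threshold mean + SD of the background
#' activity, i.e. the pre-stimulus bins of the same histogram.
#'
#' @param psth a \linkS4class{PSTH} whose window includes pre-stimulus
#'   bins.
#' @param k SD multiplier on the background, default 1.
#' @return logical flag.
#' @export
caudalResponsiveness <- function(psth, k = 1) {
    stopifnot(is(psth, "PSTH"))
    lower <- psth@breaks[-length(psth@breaks)]
    upper <- psth@breaks[-1]
    pre <- psth@counts[upper <= 0]
    post <- psth@counts[lower >= 0]
    if (length(pre) == 0)
        stop("PSTH has no pre-stimulus bins", call. = FALSE)
    if (length(post) == 0) return(FALSE)
    thr <- mean(pre) + k * stats::sd(pre)
    if (is.na(thr)) thr <- mean(pre)   # single pre bin
    any(post > thr)
}

#' Conduction velocity
#'
#' Axonal path length divided by response latency; mm/ms is numerically
#' identical to m/s.
#'
#' @param pathLength path length (mm), > 0.
#' @param latency response latency (ms), > 0.
#' @return velocity (m/s).
#' @examples
#' conductionVelocity(57.3, 3)   # 19.1
#' @export
conductionVelocity <- function(pathLength, latency) {
    if (any(pathLength <= 0) || any(latency <= 0))
        stop("path length and latency must be positive", call. = FALSE)
    pathLength / latency
}

#' Cohort summary of antidromic recordings
#'
#' Per-group totals over a per-animal table: number of animals, total and
#' mean antidromic units per animal, and the percentage of animals with at
#' least one caudally activated unit.
#'
#' @param cohort data.frame with columns \code{group}, \code{n_units} and
#'   \code{caudal_respondent} (logical), one row per animal;
#'   \code{n_insertions} is carried through when present.
#' @return data.frame, one row per group, with columns \code{n_animals},
#'   \code{total_units}, \code{mean_units}, \code{sd_units},
#'   \code{pct_respondent}; the \code{"total_units"} attribute holds the
#'   grand total. Empty groups yield zero counts and \code{NA} means, and
#'   are listed in the \code{"emptyGroups"} attribute.
#' @examples
#' coh <- data.frame(group = rep(c("SCI+rGO", "SCI"), c(11, 4)),
#'                   n_units = c(rep(4, 10), 5, rep(5, 4)),
#'                   caudal_respondent = c(rep(TRUE, 3), rep(FALSE, 12)))
#' cohortSummary(coh)
#' @export
cohortSummary <- function(cohort) {
    if (!is.data.frame(cohort) || nrow(cohort) == 0)
        stop("'cohort' must be a non-empty data.frame", call. = FALSE)
    need <- c("group", "n_units", "caudal_respondent")
    if (!all(need %in% names(cohort)))
        stop("missing columns: ",
             paste(setdiff(need, names(cohort)), collapse = ", "),
             call. = FALSE)
    if (any(cohort$n_units < 0)) stop("negative unit counts", call. = FALSE)
    g <- as.factor(cohort$group)
    out <- data.frame(
        group = levels(g),
        n_animals = as.integer(table(g)),
        total_units = as.numeric(tapply(cohort$n_units, g, sum,
                                        default = 0)),
        mean_units = as.numeric(tapply(cohort$n_units, g, mean)),
        sd_units = as.numeric(tapply(cohort$n_units, g, stats::sd)),
        pct_respondent = as.numeric(tapply(cohort$caudal_respondent, g,
                                           function(x) 100 * mean(x))))
    attr(out, "total_units") <- sum(cohort$n_units)
    attr(out, "emptyGroups") <- levels(g)[table(g) == 0]
    out
}
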