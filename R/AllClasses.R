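#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Extracellular recording with stimulation metadata
#'
#' Container for a single-electrode extracellular voltage trace together with
#' the stimulus train applied to the spinal cord. Times are seconds, the
#' signal is microvolts.
#'
#' @slot signal numeric vector of voltage samples (uV).
#' @slot rate sampling rate (Hz).
#' @slot stimTimes stimulus onset times (s), sorted.
#' @slot stimFreq per-stimulus train frequency (Hz), recycled to
#'   \code{length(stimTimes)}.
#' @slot stimSite \code{"rostral"} or \code{"caudal"} relative to the lesion.
#' @slot pathLength recording-to-stimulation path length (mm), \code{NA} if
#'   unknown; used for conduction-velocity estimates.
#'
#' @exportClass Recording
setClass("Recording",
    representation(signal = "numeric", rate = "numeric",
                   stimTimes = "numeric", stimFreq = "numeric",
                   stimSite = "character", pathLength = "numeric"),
    prototype(stimFreq = numeric(), stimSite = "rostral", pathLength = NA_real_))

setValidity("Recording", function(object) {
    msg <- character()
    if (length(object@rate) != 1L || object@rate <= 0)
        msg <- c(msg, "'rate' must be a single positive number")
    if (is.unsorted(object@stimTimes))
        msg <- c(msg, "'stimTimes' must be sorted")
    dur <- length(object@signal) / object@rate
    if (length(object@stimTimes) &&
        (min(object@stimTimes) < 0 || max(object@stimTimes) > dur))
        msg <- c(msg, "'stimTimes' must lie within the recording duration")
    if (length(object@stimFreq) &&
        length(object@stimFreq) != length(object@stimTimes))
        msg <- c(msg, "'stimFreq' must match 'stimTimes' in length")
    if (!object@stimSite %in% c("rostral", "caudal"))
        msg <- c(msg, "'stimSite' must be 'rostral' or 'caudal'")
    if (length(msg)) msg else TRUE
})

#' Detected spike train
#'
#' @slot times spike times (s), strictly increasing.
#' @slot amplitudes spike peak amplitudes (uV) on the detection polarity.
#' @slot threshold detection threshold used (uV).
#' @slot baselineWindow two-element window (s) the threshold was estimated on.
#' @slot refractory minimum inter-spike interval enforced (s).
#'
#' @exportClass SpikeTrain
setClass("SpikeTrain",
    representation(times = "numeric", amplitudes = "numeric",
                   threshold = "numeric", baselineWindow = "numeric",
                   refractory = "numeric"))

setValidity("SpikeTrain", function(object) {
    msg <- character()
    if (length(object@times) != length(object@amplitudes))
        msg <- c(msg, "'times' and 'amplitudes' must have equal length")
    if (length(object@times) > 1L) {
        if (any(diff(object@times) <= 0))
            msg <- c(msg, "spike times must be strictly increasing")
        else if (any(diff(object@times) < object@refractory - 1e-12))
            msg <- c(msg, "inter-spike intervals violate the refractory setting")
    }
    if (length(msg)) msg else TRUE
})

#' Per-stimulus response table
#'
#' One row per stimulus: whether a time-locked spike was found in the response
#' window, its latency (ms) and amplitude (uV), the stimulation frequency of
#' the trial, and (when known from a simulation truth table) whether the trial
#' was a collision trial.
#'
#' @slot table data.frame with columns \code{stim_time}, \code{responded},
#'   \code{latency}, \code{amplitude}, \code{stim_freq}, \code{collided}.
#' @slot window response window (ms post-stimulus) used for matching.
#'
#' @exportClass StimResponseTable
setClass("StimResponseTable",
    representation(table = "data.frame", window = "numeric"))

setValidity("StimResponseTable", function(object) {
    need <- c("stim_time", "responded", "latency", "amplitude",
              "stim_freq", "collided")
    msg <- character()
    if (!all(need %in% names(object@table)))
        msg <- c(msg, paste("missing columns:",
                            paste(setdiff(need, names(object@table)),
                                  collapse = ", ")))
    else {
        tab <- object@table
        if (any(tab$responded & is.na(tab$latency)) ||
            any(!tab$responded & !is.na(tab$latency)))
            msg <- c(msg, "'latency' must be present iff 'responded'")
        ok <- tab$responded & !is.na(tab$latency)
        if (any(ok) && (min(tab$latency[ok]) < object@window[1] - 1e-9 ||
                        max(tab$latency[ok]) > object@window[2] + 1e-9))
            msg <- c(msg, "latencies must lie within the response window")
    }
    if (length(msg)) msg else TRUE
})

#' Peristimulus time histogram
#'
#' @slot breaks bin edges (ms relative to stimulus onset); bins are half-open
#'   \code{[t, t + binWidth)}.
#' @slot counts spike count per bin, summed across stimuli.
#' @slot normalized counts as a percentage of the number of stimuli.
#' @slot nStimuli number of stimuli the histogram was built from.
#' @slot binWidth bin width (ms).
#'
#' @exportClass PSTH
setClass("PSTH",
    representation(breaks = "numeric", counts = "numeric",
                   normalized = "numeric", nStimuli = "numeric",
                   binWidth = "numeric"))

setValidity("PSTH", function(object) {
    msg <- character()
    if (length(object@counts) != length(object@breaks) - 1L)
        msg <- c(msg, "'counts' must have one element per bin")
    if (any(abs(object@normalized -
                object@counts / object@nStimuli * 100) > 1e-9))
        msg <- c(msg, "'normalized' must equal counts / nStimuli * 100")
    if (length(msg)) msg else TRUE
})

#' Antidromic classification verdict
#'
#' A unit is antidromically activated when it meets at least two of three
#' criteria: constant latency and amplitude, reliable following of
#' high-frequency stimulation, and a positive collision test. A responsive
#' unit that fails the panel is classed as synaptically activated; a unit
#' with no time-locked responses is unresponsive.
#'
#' @slot constantLatency logical flag (\code{NA} = indeterminate).
#' @slot followsHighFreq logical flag (\code{NA} = indeterminate).
#' @slot collisionPass logical flag (\code{NA} = indeterminate).
#' @slot nCriteriaMet number of criteria met (0-3, \code{NA}s count as unmet).
#' @slot classification \code{"antidromic"}, \code{"synaptic"} or
#'   \code{"unresponsive"}.
#'
#' @exportClass AntidromicVerdict
setClass("AntidromicVerdict",
    representation(constantLatency = "logical", followsHighFreq = "logical",
                   collisionPass = "logical", nCriteriaMet = "integer",
                   classification = "character"))

setValidity("AntidromicVerdict", function(object) {
    msg <- character()
    if (!object@classification %in% c("antidromic", "synaptic", "unresponsive"))
        msg <- c(msg, "invalid 'classification'")
    if (object@classification == "antidromic" && object@nCriteriaMet < 2L)
        msg <- c(msg, "'antidromic' requires at least two criteria met")
    if (length(msg)) msg else TRUE
})

#' K-means colour model of an RGB image
#'
#' @slot k number of colour clusters.
#' @slot centroids k x 3 matrix of cluster RGB centroids (0-255).
#' @slot labels H x W integer matrix assigning each pixel to its nearest
#'   centroid (ties broken towards the lowest cluster index).
#' @slot seed RNG seed the clustering was run under.
#'
#' @exportClass ColorClusterModel
setClass("ColorClusterModel",
    representation(k = "integer", centroids = "matrix", labels = "matrix",
                   seed = "numeric"))

setValidity("ColorClusterModel", function(object) {
    msg <- character()
    if (nrow(object@centroids) != object@k || ncol(object@centroids) != 3L)
        msg <- c(msg, "'centroids' must be a k x 3 matrix")
    if (object@k < 2L)
        msg <- c(msg, "'k' must be at least 2")
    rng <- range(object@labels)
    if (rng[1] < 1L || rng[2] > object@k)
        msg <- c(msg, "labels out of range")
    if (length(msg)) msg else TRUE
})

#' Per-pixel tissue class map
#'
#' Pixels are classed as background, collagen (blue trichrome tones),
#' tissue (red-purple tones) or scaffold (black tones) by applying a
#' centroid-to-class rule to a \linkS4class{ColorClusterModel}.
#'
#' @slot classes H x W integer matrix with levels given by
#'   \code{levels(classMap(x))}; see \code{\link{classifyClusters}}.
#' @slot classLevels character vector naming the integer codes.
#' @slot classRule audit table: one row per centroid with its RGB value, the
#'   class assigned, the rule that fired, and whether the fallback
#'   nearest-prototype rule had to be used (flagged for review).
#' @slot pixelSize image calibration (um/pixel).
#'
#' @exportClass PixelClassMap
setClass("PixelClassMap",
    representation(classes = "matrix", classLevels = "character",
                   classRule = "data.frame", pixelSize = "numeric"))

#' Area quantification of a classified trichrome image
#'
#' @slot areas named numeric, area per class (um^2).
#' @slot bluePurpleRatio collagen area / tissue area, background excluded.
#' @slot ratioDefined FALSE when the tissue area is zero.
#' @slot excludedBackground background area (um^2) excluded from the ratio.
#'
#' @exportClass AreaReport
setClass("AreaReport",
    representation(areas = "numeric", bluePurpleRatio = "numeric",
                   ratioDefined = "logical", excludedBackground = "numeric"))

#' Collagen compactness map
#'
#' For each collagen pixel, the blue stain intensity of the pixel plus the
#' summed intensities of its neighbours within a square window (non-collagen
#' intensities taken as zero). Non-collagen pixels carry 0.
#'
#' @slot intensity H x W blue-intensity matrix in [0, 1].
#' @slot mask H x W logical collagen mask.
#' @slot compactness H x W neighbourhood-summed intensity.
#' @slot radius neighbourhood radius (pixels); the window is (2r+1)^2.
#'
#' @exportClass CompactnessMap
setClass("CompactnessMap",
    representation(intensity = "matrix", mask = "matrix",
                   compactness = "matrix", radius = "integer"))

setValidity("CompactnessMap", function(object) {
    msg <- character()
    if (!identical(dim(object@intensity), dim(object@compactness)) ||
        !identical(dim(object@intensity), dim(object@mask)))
        msg <- c(msg, "slot dimensions differ")
    if (object@radius < 1L)
        msg <- c(msg, "'radius' must be >= 1")
    m <- object@mask
    if (any(object@compactness[m] < object@intensity[m] - 1e-12))
        msg <- c(msg, "compactness below own intensity on collagen pixels")
    if (any(object@compactness[!m] != 0))
        msg <- c(msg, "non-collagen pixels must carry zero compactness")
    if (length(msg)) msg else TRUE
})

#' Four-level compactness histogram
#'
#' Collagen area split into quarters of the per-image maximum compactness
#' (0-25, 25-50, 50-75 and 75-100 %).
#'
#' @slot levelAreas area (um^2) per level.
#' @slot levelFractions fraction of collagen area per level (sums to 1).
#' @slot maxCompactness the per-image normalizer.
#' @slot empty TRUE when the image held no collagen pixels.
#'
#' @exportClass CompactnessHistogram
setClass("CompactnessHistogram",
    representation(levelAreas = "numeric", levelFractions = "numeric",
                   maxCompactness = "numeric", empty = "logical"))

#' Distributional homogeneity index result
#'
#' @slot dhi the index; 0 for exactly uniform block coverage, larger for more
#'   spatially clustered (less homogeneous) colonization.
#' @slot macropixelSizes block edge lengths (pixels) of the dyadic ladder.
#' @slot perScale per-size heterogeneity (RMS block-coverage deviation over
#'   mean block coverage).
#' @slot globalCoverage overall foreground fraction.
#' @slot defined FALSE for an empty mask.
#'
#' @exportClass DHIResult
setClass("DHIResult",
    representation(dhi = "numeric", macropixelSizes = "numeric",
                   perScale = "numeric", globalCoverage = "numeric",
                   defined = "logical"))

#' Binary structure mask
#'
#' @slot mask H x W logical matrix.
#' @slot pixelSize calibration (um/pixel).
#' @slot axis rostro-caudal axis of the image: \code{"rows"} when the body
#'   axis runs along increasing row index, \code{"columns"} otherwise.
#'
#' @exportClass StructureMask
setClass("StructureMask",
    representation(mask = "matrix", pixelSize = "numeric", axis = "character"))

setValidity("StructureMask", function(object) {
    msg <- character()
    if (!is.logical(object@mask))
        msg <- c(msg, "'mask' must be logical")
    if (!object@axis %in% c("rows", "columns"))
        msg <- c(msg, "'axis' must be 'rows' or 'columns'")
    if (object@pixelSize <= 0)
        msg <- c(msg, "'pixelSize' must be positive")
    if (length(msg)) msg else TRUE
})

#' Morphometry of labelled structures
#'
#' @slot table one row per structure: \code{length}, \code{diameter}
#'   (vessels; \code{NA} for neurites), \code{extent} (rostro-caudal), all um.
#' @slot kind \code{"neurite"} or \code{"vessel"}.
#' @slot pixelSize calibration (um/pixel).
#'
#' @exportClass StructureStats
setClass("StructureStats",
    representation(table = "data.frame", kind = "character",
                   pixelSize = "numeric"))

#' Landmark scene for postural angles
#'
#' Eye, shoulder and hip positions in image coordinates (y increases
#' downwards) plus the ground direction, with the programmed ground-truth
#' angles when the scene was simulated.
#'
#' @slot eye,shoulder,hip 2-element numeric points (pixels).
#' @slot ground unit 2-vector giving the ground (horizon) direction.
#' @slot trueCtl programmed cervico-thoraco-lumbar angle (deg), NA if unknown.
#' @slot trueTrunk programmed trunk alignment angle (deg), NA if unknown.
#' @slot frame frame identifier.
#'
#' @exportClass LandmarkScene
setClass("LandmarkScene",
    representation(eye = "numeric", shoulder = "numeric", hip = "numeric",
                   ground = "numeric", trueCtl = "numeric",
                   trueTrunk = "numeric", frame = "character"),
    prototype(trueCtl = NA_real_, trueTrunk = NA_real_, frame = "1"))

setValidity("LandmarkScene", function(object) {
    msg <- character()
    pts <- list(object@eye, object@shoulder, object@hip)
    if (any(vapply(pts, length, 1L) != 2L) || length(object@ground) != 2L)
        msg <- c(msg, "points and ground must be 2-element numerics")
    else {
        if (isTRUE(all.equal(object@eye, object@shoulder)) ||
            isTRUE(all.equal(object@shoulder, object@hip)) ||
            isTRUE(all.equal(object@eye, object@hip)))
            msg <- c(msg, "landmark points must be pairwise distinct")
        if (sqrt(sum(object@ground^2)) < 1e-12)
            msg <- c(msg, "'ground' must be a non-zero vector")
    }
    if (length(msg)) msg else TRUE
})
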