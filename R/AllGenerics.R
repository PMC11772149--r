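#' @include AllClasses.R
NULL

#' Accessors for cordmetrics containers
#'
#' Small accessor family for the S4 containers; slot access from user code is
#' discouraged.
#'
#' @param object a cordmetrics S4 object.
#' @return the requested component.
#' @name accessors
#' @aliases samplingRate stimTimes spikeTimes amplitudes responseTable
#'   classMap dhi normalizedCounts
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("stimTimes", function(object) standardGeneric("stimTimes"))
#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(object) standardGeneric("spikeTimes"))
#' @rdname accessors
#' @export
setGeneric("amplitudes", function(object) standardGeneric("amplitudes"))
#' @rdname accessors
#' @export
setGeneric("responseTable", function(object) standardGeneric("responseTable"))
#' @rdname accessors
#' @export
setGeneric("classMap", function(object) standardGeneric("classMap"))
#' @rdname accessors
#' @export
setGeneric("dhi", function(object) standardGeneric("dhi"))
#' @rdname accessors
#' @export
setGeneric("normalizedCounts",
           function(object) standardGeneric("normalizedCounts"))

#' @rdname accessors
setMethod("samplingRate", "Recording", function(object) object@rate)
#' @rdname accessors
setMethod("stimTimes", "Recording", function(object) object@stimTimes)
#' @rdname accessors
setMethod("spikeTimes", "SpikeTrain", function(object) object@times)
#' @rdname accessors
setMethod("amplitudes", "SpikeTrain", function(object) object@amplitudes)
#' @rdname accessors
setMethod("responseTable", "StimResponseTable",
          function(object) object@table)
#' @rdname accessors
setMethod("classMap", "PixelClassMap", function(object) {
    m <- object@classes
    structure(m, levels = object@classLevels)
})
#' @rdname accessors
setMethod("dhi", "DHIResult", function(object) object@dhi)
#' @rdname accessors
setMethod("normalizedCounts", "PSTH", function(object) object@normalized)

#' @export
setMethod("show", "Recording", function(object) {
    cat(sprintf("Recording: %d samples at %g Hz (%.2f s), %d %s stimuli\n",
                length(object@signal), object@rate,
                length(object@signal) / object@rate,
                length(object@stimTimes), object@stimSite))
})

#' @export
setMethod("show", "SpikeTrain", function(object) {
    cat(sprintf("SpikeTrain: %d spikes, threshold %.2f uV, refractory %g ms\n",
                length(object@times), object@threshold,
                object@refractory * 1000))
})

#' @export
setMethod("show", "StimResponseTable", function(object) {
    tab <- object@table
    cat(sprintf(
        "StimResponseTable: %d stimuli, %d responded (%.1f%%), window [%g, %g] ms\n",
        nrow(tab), sum(tab$responded), 100 * mean(tab$responded),
        object@window[1], object@window[2]))
})

#' @export
setMethod("show", "PSTH", function(object) {
    cat(sprintf("PSTH: %d bins of %g ms over [%g, %g] ms, %d stimuli\n",
                length(object@counts), object@binWidth,
                min(object@breaks), max(object@breaks), object@nStimuli))
})

#' @export
setMethod("show", "AntidromicVerdict", function(object) {
    f <- function(x) if (is.na(x)) "indeterminate" else if (x) "pass" else "fail"
    cat(sprintf(paste0("AntidromicVerdict: %s (%d/3 criteria)\n",
                       "  constant latency/amplitude: %s\n",
                       "  high-frequency following:   %s\n",
                       "  collision test:             %s\n"),
                object@classification, object@nCriteriaMet,
                f(object@constantLatency), f(object@followsHighFreq),
                f(object@collisionPass)))
})

#' @export
setMethod("show", "ColorClusterModel", function(object) {
    cat(sprintf("ColorClusterModel: k = %d over %d x %d pixels (seed %g)\n",
                object@k, nrow(object@labels), ncol(object@labels),
                object@seed))
})

#' @export
setMethod("show", "PixelClassMap", function(object) {
    tab <- table(factor(object@classLevels[object@classes],
                        levels = object@classLevels))
    cat("PixelClassMap:\n")
    print(tab)
})

#' @export
setMethod("show", "AreaReport", function(object) {
    cat("AreaReport (um^2):\n")
    print(round(object@areas, 2))
    cat(sprintf("blue/purple ratio: %s\n",
                if (object@ratioDefined)
                    sprintf("%.3f", object@bluePurpleRatio) else "undefined"))
})

#' @export
setMethod("show", "CompactnessMap", function(object) {
    cat(sprintf(
        "CompactnessMap: %d x %d, radius %d, %d collagen pixels, max %.3f\n",
        nrow(object@compactness), ncol(object@compactness), object@radius,
        sum(object@mask), max(object@compactness)))
})

#' @export
setMethod("show", "DHIResult", function(object) {
    if (!object@defined) {
        cat("DHIResult: undefined (empty mask)\n")
    } else {
        cat(sprintf("DHI = %.2f (coverage %.3f; scales %s px)\n",
                    object@dhi, object@globalCoverage,
                    paste(object@macropixelSizes, collapse = ", ")))
    }
})

#' @export
setMethod("show", "StructureStats", function(object) {
    cat(sprintf("StructureStats: %d %ss, total length %.1f um\n",
                nrow(object@table), object@kind, sum(object@table$length)))
})

#' @export
setMethod("show", "LandmarkScene", function(object) {
    cat(sprintf(
        "LandmarkScene [%s]: eye (%.1f, %.1f), shoulder (%.1f, %.1f), hip (%.1f, %.1f)\n",
        object@frame, object@eye[1], object@eye[2], object@shoulder[1],
        object@shoulder[2], object@hip[1], object@hip[2]))
})

#' @export
setMethod("as.data.frame", "StimResponseTable",
          function(x, ...) x@table)

#' @export
setMethod("as.data.frame", "StructureStats", function(x, ...) x@table)
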