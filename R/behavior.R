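#' Cervico-thoraco-lumbar angle
#'
#' Interior angle at the shoulder between the shoulder-to-eye and
#' shoulder-to-hip segments, in degrees. This angle indexes upper-body
#' posture: small when the snout points to the ground, approaching 180
#' degrees at full extension with eye, shoulder and hip collinear.
#'
#' @param eye,shoulder,hip 2-element points (pixels, y down).
#' @return angle in degrees, (0, 180].
#' @examples
#' ctlAngle(c(0, 1), c(0, 0), c(1, 0))   # 90
#' @export
ctlAngle <- function(eye, shoulder, hip) {
    u <- eye - shoulder; v <- hip - shoulder
    if (sqrt(sum(u^2)) < 1e-12 || sqrt(sum(v^2)) < 1e-12)
        stop("coincident landmark points", call. = FALSE)
    .vecAngle(u, v)
}

#' Trunk alignment angle
#'
#' Absolute angle between the shoulder-hip line and the ground direction,
#' in degrees [0, 90]. Reported unsigned: the measure is an alignment
#' magnitude (0 = trunk parallel to the ground).
#'
#' @param shoulder,hip 2-element points (pixels).
#' @param ground 2-element ground (horizon) direction; supplied per scene so
#'   camera tilt can be compensated.
#' @return angle in degrees, [0, 90].
#' @examples
#' trunkAngle(c(0, 1), c(1, 0), c(1, 0))   # 45
#' @export
trunkAngle <- function(shoulder, hip, ground = c(1, 0)) {
    d <- hip - shoulder
    if (sqrt(sum(d^2)) < 1e-12)
        stop("coincident shoulder and hip", call. = FALSE)
    if (sqrt(sum(ground^2)) < 1e-12)
        stop("'ground' must be a non-zero vector", call. = FALSE)
    a <- .vecAngle(d, ground)
    min(a, 180 - a)
}

#' Angles of a landmark scene
#'
#' @param scene a \linkS4class{LandmarkScene}.
#' @return named numeric: \code{ctl}, \code{trunk} (degrees).
#' @export
sceneAngles <- function(scene) {
    stopifnot(is(scene, "LandmarkScene"))
    c(ctl = ctlAngle(scene@eye, scene@shoulder, scene@hip),
      trunk = trunkAngle(scene@shoulder, scene@hip, scene@ground))
}

#' Per-animal range of movement
#'
#' Extremes and range of the two postural angles over a selection of frames
#' (at least 3 per animal).
#'
#' @param measures data.frame with numeric columns \code{ctl} and
#'   \code{trunk}, one row per frame.
#' @return data.frame with rows \code{ctl} and \code{trunk} and columns
#'   \code{min}, \code{max}, \code{range} (degrees).
#' @export
angleRange <- function(measures) {
    if (!is.data.frame(measures) ||
        !all(c("ctl", "trunk") %in% names(measures)))
        stop("'measures' needs columns 'ctl' and 'trunk'", call. = FALSE)
    if (nrow(measures) < 3)
        stop("at least 3 frames per animal are required", call. = FALSE)
    f <- function(x) c(min = min(x), max = max(x), range = diff(range(x)))
    as.data.frame(rbind(ctl = f(measures$ctl), trunk = f(measures$trunk)))
}

#' Prevalence of a categorical finding per group
#'
#' Percentage of flagged animals per experimental group, plus the 2 x k
#' contingency table for export to standard chi-squared testing.
#'
#' @param flags logical vector, one element per animal.
#' @param group group labels (character or factor) parallel to \code{flags}.
#' @return list with \code{percent} (named numeric, per group) and
#'   \code{table} (flagged/unflagged x group contingency table). Groups with
#'   no animals get \code{NA} percent and are named in the
#'   \code{"emptyGroups"} attribute.
#' @examples
#' prevalence(c(TRUE, TRUE, TRUE, TRUE, FALSE),
#'            rep("SCI", 5))$percent      # 80
#' @export
prevalence <- function(flags, group) {
    if (length(flags) != length(group))
        stop("'flags' and 'group' lengths differ", call. = FALSE)
    if (length(flags) == 0)
        stop("empty input", call. = FALSE)
    group <- as.factor(group)
    pct <- tapply(flags, group, function(x) 100 * mean(x))
    pct <- stats::setNames(as.numeric(pct), levels(group))
    tab <- table(flagged = factor(flags, levels = c(TRUE, FALSE)), group)
    out <- list(percent = pct, table = tab)
    empty <- levels(group)[tabulate(group, nbins = nlevels(group)) == 0]
    attr(out, "emptyGroups") <- empty
    out
}
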