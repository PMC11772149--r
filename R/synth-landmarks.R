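#' Simulate a landmark scene with programmed postural angles
#'
#' Places eye, shoulder and hip points (image coordinates, y down) and a
#' ground direction such that the cervico-thoraco-lumbar angle (interior
#' angle at the shoulder between shoulder-eye and shoulder-hip) and the
#' trunk alignment angle (absolute angle between the shoulder-hip line and
#' the ground) equal the requested values. Scene position, orientation and
#' segment lengths are randomized; the programmed angles are recoverable to
#' 1e-6 degrees.
#'
#' @param ctlAngle requested cervico-thoraco-lumbar angle, degrees in
#'   (0, 180].
#' @param trunkAngle requested trunk alignment angle, degrees in [0, 90].
#' @param scale approximate shoulder-hip distance (pixels).
#' @param seed RNG seed.
#' @param frame frame identifier.
#' @return a \linkS4class{LandmarkScene}.
#' @examples
#' sc <- genLandmarkScene(137, 30, seed = 4)
#' ctlAngle(sc@eye, sc@shoulder, sc@hip)
#' @export
genLandmarkScene <- function(ctlAngle, trunkAngle, scale = 100, seed = 1,
                             frame = "1") {
    if (!is.numeric(ctlAngle) || ctlAngle <= 0 || ctlAngle > 180)
        stop("'ctlAngle' must be in (0, 180] degrees", call. = FALSE)
    if (!is.numeric(trunkAngle) || trunkAngle < 0 || trunkAngle > 90)
        stop("'trunkAngle' must be in [0, 90] degrees", call. = FALSE)
    withSeed(seed, {
        g <- .rot2(c(1, 0), stats::runif(1, 0, 360))      # ground direction
        hip <- stats::runif(2, 100, 400)
        sgnT <- sample(c(-1, 1), 1)
        l1 <- scale * stats::runif(1, 0.9, 1.1)
        shoulder <- hip + l1 * .rot2(g, sgnT * trunkAngle)
        v <- (hip - shoulder) / sqrt(sum((hip - shoulder)^2))
        sgnC <- sample(c(-1, 1), 1)
        l2 <- 0.6 * scale * stats::runif(1, 0.9, 1.1)
        eye <- shoulder + l2 * .rot2(v, sgnC * ctlAngle)
        sc <- new("LandmarkScene", eye = eye, shoulder = shoulder, hip = hip,
                  ground = g, trueCtl = ctlAngle, trueTrunk = trunkAngle,
                  frame = as.character(frame))
        stopifnot(abs(ctlAngle(eye, shoulder, hip) - ctlAngle) < 1e-6,
                  abs(trunkAngle(shoulder, hip, g) - trunkAngle) < 1e-6)
        sc
    })
}
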