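#' Collagen compactness map
#'
#' For every collagen pixel, accumulates the blue-stain intensities of the
#' pixels in its square neighbourhood ((2r+1)^2 window, the pixel's own
#' value included) onto its own value; intensities of non-collagen pixels
#' count as zero. Border pixels use the in-image part of their
#' neighbourhood. Dense collagen accumulations therefore map to high summed
#' intensities.
#'
#' @param intensity H x W intensity matrix in [0, 1] (zero outside
#'   collagen), e.g. from \code{\link{blueIntensity}}; may also be the list
#'   that function returns.
#' @param mask logical collagen mask; taken from \code{intensity$mask} when
#'   a \code{blueIntensity} result is supplied.
#' @param radius neighbourhood radius in pixels (>= 1); the default 1 gives
#'   the 8-neighbourhood plus the centre.
#' @return a \linkS4class{CompactnessMap}.
#' @examples
#' bi <- list(intensity = matrix(1, 3, 3), mask = matrix(TRUE, 3, 3))
#' collagenCompactness(bi)@compactness[2, 2]   # 9
#' @export
collagenCompactness <- function(intensity, mask = NULL, radius = 1) {
    if (is.list(intensity)) {
        if (is.null(mask)) mask <- intensity$mask
        intensity <- intensity$intensity
    }
    if (is.null(mask)) mask <- intensity > 0
    if (!is.matrix(intensity) || !identical(dim(intensity), dim(mask)))
        stop("'intensity' and 'mask' must be matrices of equal size",
             call. = FALSE)
    if (!is.numeric(radius) || length(radius) != 1L || radius < 1)
        stop("'radius' must be a positive integer", call. = FALSE)
    r <- as.integer(radius)
    vals <- intensity
    vals[!mask] <- 0               # non-blue intensities count as zero
    acc <- matrix(0, nrow(vals), ncol(vals))
    for (dx in -r:r)               # column-major accumulation order
        for (dy in -r:r)
            acc <- acc + .shiftMat(vals, dy, dx)
    acc[!mask] <- 0
    new("CompactnessMap", intensity = vals, mask = mask, compactness = acc,
        radius = r)
}

#' Bin a compactness map into four relative levels
#'
#' Collagen pixels are split into four compactness levels at quarters of the
#' per-image maximum summed intensity (0-25, 25-50, 50-75 and 75-100 %),
#' reported as areas and as fractions of the collagen area.
#'
#' @param cmap a \linkS4class{CompactnessMap}.
#' @param pixelSize calibration (um/pixel).
#' @return a \linkS4class{CompactnessHistogram}; when the map holds no
#'   collagen pixels the result carries the \code{empty} flag and zero
#'   areas.
#' @export
binCompactness <- function(cmap, pixelSize = 0.65) {
    stopifnot(is(cmap, "CompactnessMap"))
    vals <- cmap@compactness[cmap@mask]
    lv <- c("0-25%", "25-50%", "50-75%", "75-100%")
    if (length(vals) == 0)
        return(new("CompactnessHistogram",
                   levelAreas = stats::setNames(numeric(4), lv),
                   levelFractions = stats::setNames(numeric(4), lv),
                   maxCompactness = NA_real_, empty = TRUE))
    mx <- max(vals)
    lev <- if (mx == 0) rep(1L, length(vals)) else
        pmin(pmax(ceiling(vals / mx * 4), 1L), 4L)
    counts <- tabulate(lev, 4L)
    new("CompactnessHistogram",
        levelAreas = stats::setNames(counts * pixelSize^2, lv),
        levelFractions = stats::setNames(counts / length(vals), lv),
        maxCompactness = mx, empty = FALSE)
}

#' Positively stained area fraction
#'
#' Percentage of pixels at or above an intensity threshold, the standard
#' quantification for an immunofluorescence marker channel after the
#' positive-labelling threshold has been defined.
#'
#' @param channel single-channel intensity matrix.
#' @param threshold positive-labelling threshold; must lie within
#'   \code{range}.
#' @param range representable intensity range, default \code{c(0, 255)}.
#' @return percentage in [0, 100].
#' @export
positiveAreaFraction <- function(channel, threshold, range = c(0, 255)) {
    if (!is.matrix(channel))
        stop("'channel' must be a single-channel matrix", call. = FALSE)
    if (threshold < range[1] || threshold > range[2])
        stop("'threshold' outside the intensity range", call. = FALSE)
    100 * mean(channel >= threshold)
}

## Mean of s x s blocks (complete blocks only).
.blockMeans <- function(m, s) {
    nby <- nrow(m) %/% s; nbx <- ncol(m) %/% s
    m <- m[seq_len(nby * s), seq_len(nbx * s), drop = FALSE]
    rowGrp <- rep(seq_len(nby), each = s)
    colGrp <- rep(seq_len(nbx), each = s)
    t(rowsum(t(rowsum(m, rowGrp)), colGrp)) / s^2
}

#' Distributional homogeneity index
#'
#' Measures how evenly a structure mask (or a coverage map in [0, 1])
#' covers the image. The image is tiled with square macropixels at a dyadic
#' ladder of sizes; at each size the heterogeneity is the RMS deviation of
#' block coverage around the mean block coverage, divided by that mean
#' (a coefficient of variation). The index is 100 times the mean
#' heterogeneity across sizes: 0 for exactly uniform block coverage, larger
#' when structures concentrate in clusters or at the borders.
#'
#' @param mask logical/0-1 matrix, or a numeric coverage map in [0, 1], or
#'   a \linkS4class{StructureMask}.
#' @param macropixelSizes block edge lengths (pixels); default a dyadic
#'   ladder giving between 4 and 16 blocks along the shorter image side.
#' @return a \linkS4class{DHIResult}; an empty mask gives an undefined
#'   (flagged) result.
#' @export
computeDHI <- function(mask, macropixelSizes = NULL) {
    if (is(mask, "StructureMask")) mask <- mask@mask
    m <- mask * 1
    if (!is.matrix(m)) stop("'mask' must be a matrix", call. = FALSE)
    mn <- min(dim(m))
    if (is.null(macropixelSizes)) {
        p <- 2^(1:30)
        macropixelSizes <- p[p >= mn / 16 & p <= mn / 4 & p >= 2]
        if (!length(macropixelSizes))
            macropixelSizes <- max(2, 2^floor(log2(mn / 4)))
    }
    if (any(macropixelSizes < 2) || any(macropixelSizes > mn))
        stop("'macropixelSizes' must be >= 2 px and fit in the image",
             call. = FALSE)
    cov <- mean(m)
    if (sum(m) == 0)
        return(new("DHIResult", dhi = NA_real_,
                   macropixelSizes = macropixelSizes,
                   perScale = rep(NA_real_, length(macropixelSizes)),
                   globalCoverage = 0, defined = FALSE))
    het <- vapply(macropixelSizes, function(s) {
        b <- .blockMeans(m, s)
        g <- mean(b)
        sqrt(mean((b - g)^2)) / g
    }, numeric(1))
    new("DHIResult", dhi = 100 * mean(het),
        macropixelSizes = macropixelSizes, perScale = het,
        globalCoverage = cov, defined = TRUE)
}
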