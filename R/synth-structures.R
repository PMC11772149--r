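## Disc of integer offsets with Euclidean radius <= r (r = 0 gives the centre).
.discOffsets <- function(r) {
    g <- expand.grid(dy = -r:r, dx = -r:r)
    g[g$dy^2 + g$dx^2 <= r^2 + 1e-9, , drop = FALSE]
}

## Smooth curvilinear pixel chain: unit (1 px) steps with Gaussian heading
## noise, rasterized by rounding. Returns the chain (n x 2, row/col) and
## the continuous path length in pixels (number of unit steps, plus 1 for
## the first pixel — so a straight horizontal chain of 100 pixels has
## length 100).
.genPath <- function(y0, x0, thetaDeg, targetLenPx, h, w, curvSD = 3) {
    th <- .radians(thetaDeg)
    y <- y0; x <- x0
    chain <- matrix(c(round(y0), round(x0)), 1, 2)
    len <- 1
    while (len < targetLenPx) {
        th <- th + .radians(stats::rnorm(1, 0, curvSD))
        y <- y + sin(th); x <- x + cos(th)
        py <- round(y); px <- round(x)
        if (py < 1 || py > h || px < 1 || px > w) break
        len <- len + 1
        last <- chain[nrow(chain), ]
        if (py == last[1] && px == last[2]) next
        if (max(abs(c(py, px) - last)) > 1) {  # rounding skipped a pixel
            my <- round((py + last[1]) / 2); mx <- round((px + last[2]) / 2)
            if (my != last[1] || mx != last[2])
                chain <- rbind(chain, c(my, mx))
        }
        chain <- rbind(chain, c(py, px))
    }
    list(chain = chain, lengthPx = len)
}

#' Simulate a binary mask of neurites or blood vessels with known morphometry
#'
#' Draws \code{nStructures} disjoint curvilinear structures: 1-pixel-wide
#' paths for neurites, or paths dilated by a disc for vessels (giving an odd
#' pixel width \code{2r + 1}). Structures are placed uniformly or
#' concentrated at the image border, and a ground-truth table records each
#' structure's realized length, requested and drawn diameter, and
#' rostro-caudal extent. Masks are hard binary (no anti-aliasing) so lengths
#' and diameters are exactly countable.
#'
#' @param width,height mask size (pixels).
#' @param nStructures number of structures to place.
#' @param kind \code{"neurite"} or \code{"vessel"}.
#' @param lengthRange structure length range (um).
#' @param diameterRange vessel diameter range (um); ignored for neurites.
#' @param orientationBias mean path heading (degrees, 0 = along columns);
#'   \code{NULL} for isotropic headings.
#' @param orientationSD heading SD (degrees) around the bias.
#' @param curvSD per-pixel heading noise (degrees) controlling tortuosity.
#' @param placement \code{"uniform"} or \code{"border"}.
#' @param pixelSize calibration (um/pixel).
#' @param axis rostro-caudal axis (\code{"rows"} or \code{"columns"}).
#' @param seed RNG seed.
#' @param maxTries placement attempts per structure before a capacity error.
#'
#' @return list with \code{mask} (a \linkS4class{StructureMask}),
#'   \code{truth} (data.frame: \code{length}, \code{diameter} — the
#'   realized drawn diameter, um —, \code{diameter_requested},
#'   \code{diameter_px}, \code{extent}), and \code{params}. The requested
#'   diameter is quantized to the nearest odd pixel width when drawing;
#'   \code{diameter} records the realized value, which equals the request
#'   whenever the requested width is an odd number of pixels.
#' @examples
#' sim <- genStructureMask(128, 128, nStructures = 3, kind = "neurite",
#'                         lengthRange = c(20, 30), seed = 2)
#' sim$truth
#' @export
genStructureMask <- function(width, height, nStructures,
                             kind = c("neurite", "vessel"),
                             lengthRange = c(30, 60),
                             diameterRange = c(8, 16),
                             orientationBias = NULL, orientationSD = 20,
                             curvSD = 3,
                             placement = c("uniform", "border"),
                             pixelSize = 0.5, axis = "rows", seed = 1,
                             maxTries = 200) {
    kind <- match.arg(kind); placement <- match.arg(placement)
    .checkScalar(nStructures, "nStructures", 1)
    if (any(lengthRange <= 0) || lengthRange[1] > lengthRange[2])
        stop("invalid 'lengthRange'", call. = FALSE)
    if (min(lengthRange) / pixelSize < 2)
        stop("structures must span at least 2 pixels", call. = FALSE)
    h <- as.integer(height); w <- as.integer(width)
    mask <- matrix(FALSE, h, w)
    occupied <- matrix(FALSE, h, w)
    band <- max(3L, round(0.12 * min(h, w)))
    truth <- vector("list", nStructures)

    withSeed(seed, {
        for (i in seq_len(nStructures)) {
            placed <- FALSE
            for (try in seq_len(maxTries)) {
                lenUm <- stats::runif(1, lengthRange[1], lengthRange[2])
                lenPx <- lenUm / pixelSize
                dUm <- if (kind == "vessel")
                    stats::runif(1, diameterRange[1], diameterRange[2]) else
                    NA_real_
                r <- if (kind == "vessel")
                    max(1L, round((dUm / pixelSize - 1) / 2)) else 0L
                if (placement == "uniform") {
                    y0 <- stats::runif(1, r + 2, h - r - 1)
                    x0 <- stats::runif(1, r + 2, w - r - 1)
                    th <- if (is.null(orientationBias))
                        stats::runif(1, 0, 360) else
                        stats::rnorm(1, orientationBias, orientationSD)
                } else {
                    side <- sample.int(4, 1)
                    u <- stats::runif(1, r + 2, band)
                    v <- stats::runif(1, 2, c(w, w, h, h)[side] - 1)
                    y0 <- switch(side, u, h - u, v, v)
                    x0 <- switch(side, v, v, u, w - u)
                    ## run roughly along the nearest edge
                    th <- switch(side, 0, 0, 90, 90) +
                        stats::rnorm(1, 0, 10) + sample(c(0, 180), 1)
                }
                p <- .genPath(y0, x0, th, lenPx, h, w, curvSD)
                if (p$lengthPx < 0.9 * lenPx) next   # clipped at border
                off <- .discOffsets(r)
                draw <- unique(cbind(rep(p$chain[, 1], each = nrow(off)) +
                                     off$dy,
                                     rep(p$chain[, 2], each = nrow(off)) +
                                     off$dx))
                keep <- draw[, 1] >= 1 & draw[, 1] <= h &
                        draw[, 2] >= 1 & draw[, 2] <= w
                if (!all(keep)) next
                guard <- .discOffsets(r + 2L)
                zone <- unique(cbind(rep(p$chain[, 1], each = nrow(guard)) +
                                     guard$dy,
                                     rep(p$chain[, 2], each = nrow(guard)) +
                                     guard$dx))
                zone[, 1] <- pmin(pmax(zone[, 1], 1L), h)
                zone[, 2] <- pmin(pmax(zone[, 2], 1L), w)
                if (any(occupied[zone])) next
                mask[draw] <- TRUE
                occupied[draw] <- TRUE
                ax <- if (axis == "rows") draw[, 1] else draw[, 2]
                truth[[i]] <- data.frame(
                    length = p$lengthPx * pixelSize,
                    diameter = if (kind == "vessel")
                        (2 * r + 1) * pixelSize else NA_real_,
                    diameter_requested = dUm,
                    diameter_px = 2 * r + 1,
                    extent = (max(ax) - min(ax) + 1) * pixelSize,
                    seed_row = p$chain[1, 1], seed_col = p$chain[1, 2])
                placed <- TRUE
                break
            }
            if (!placed)
                stop(sprintf(
                    "could not place %d disjoint structures (capacity)",
                    nStructures), call. = FALSE)
        }
    })
    list(mask = new("StructureMask", mask = mask, pixelSize = pixelSize,
                    axis = axis),
         truth = do.call(rbind, truth),
         params = list(width = width, height = height,
                       nStructures = nStructures, kind = kind,
                       lengthRange = lengthRange,
                       diameterRange = diameterRange, placement = placement,
                       pixelSize = pixelSize, seed = seed))
}
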