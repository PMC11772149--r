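#' Default trichrome palette
#'
#' Representative RGB tones for the four pixel classes of a Masson's
#' trichrome section: near-white substrate/background, blue collagen,
#' red-purple (hematoxylin-stained) neural tissue, and near-black scaffold
#' material.
#'
#' @return a 4 x 3 matrix with rownames
#'   \code{background, collagen, tissue, scaffold}.
#' @export
trichromePalette <- function() {
    rbind(background = c(245, 245, 245),
          collagen   = c(70, 90, 200),
          tissue     = c(160, 70, 140),
          scaffold   = c(30, 30, 30))
}

#' Simulate a Masson's trichrome section with known pixel classes
#'
#' Generates an RGB image whose per-pixel true class (background, collagen,
#' tissue, scaffold) is returned alongside. Class area fractions are realized
#' exactly (up to integer rounding); the spatial layout of the collagen
#' class is controllable to emulate uniformly spread, clustered, or
#' border-concentrated collagen deposition.
#'
#' @param width,height image size in pixels.
#' @param pixelSize calibration (um/pixel).
#' @param fractions named or positional numeric of length 4 giving the
#'   requested area fractions for background, collagen, tissue and scaffold;
#'   must sum to 1.
#' @param collagenLayout \code{"uniform"}, \code{"clustered"} or
#'   \code{"border"}.
#' @param clusterCount number of collagen clusters for the clustered layout.
#' @param palette 4 x 3 RGB matrix, one row per class.
#' @param colorNoiseSD per-pixel Gaussian RGB noise SD (0-255 scale).
#' @param seed RNG seed; identical parameters and seed give bit-identical
#'   output.
#'
#' @return a list with \code{image} (H x W x 3 integer array, 0-255),
#'   \code{truth} (H x W integer matrix of true classes, levels in
#'   \code{attr(truth, "levels")}), \code{pixelSize} and \code{params}.
#' @examples
#' sim <- genTrichromeImage(64, 64, fractions = c(0.4, 0.3, 0.25, 0.05),
#'                          seed = 1)
#' table(sim$truth) / length(sim$truth)
#' @export
genTrichromeImage <- function(width, height, pixelSize = 0.65,
                              fractions = c(background = 0.4, collagen = 0.3,
                                            tissue = 0.25, scaffold = 0.05),
                              collagenLayout = c("uniform", "clustered",
                                                 "border"),
                              clusterCount = 5, palette = trichromePalette(),
                              colorNoiseSD = 8, seed = 1) {
    collagenLayout <- match.arg(collagenLayout)
    .checkScalar(width, "width", 1); .checkScalar(height, "height", 1)
    if (length(fractions) != 4L || any(fractions < 0) || any(fractions > 1))
        stop("'fractions' must be four values in [0, 1]", call. = FALSE)
    if (abs(sum(fractions) - 1) > 1e-9)
        stop("'fractions' must sum to 1", call. = FALSE)
    classes <- c("background", "collagen", "tissue", "scaffold")
    n <- as.integer(width) * as.integer(height)

    ## exact pixel budget per class; the largest class absorbs the rounding
    counts <- round(fractions * n)
    counts[which.max(counts)] <- counts[which.max(counts)] + (n - sum(counts))

    withSeed(seed, {
        truth <- integer(n)
        idxAll <- seq_len(n)
        ## place collagen first according to the requested layout
        nc <- counts[2]
        colIdx <- if (nc == 0) integer() else switch(collagenLayout,
            uniform = sample(idxAll, nc),
            clustered = .sampleClustered(height, width, nc, clusterCount),
            border = .sampleBorder(height, width, nc))
        truth[colIdx] <- 2L
        rest <- sample(setdiff(idxAll, colIdx))
        truth[rest] <- rep.int(c(1L, 3L, 4L), counts[c(1, 3, 4)])
        truth <- matrix(truth, nrow = height, ncol = width)

        img <- array(0, dim = c(height, width, 3))
        for (ch in 1:3)
            img[, , ch] <- matrix(palette[truth, ch], height, width)
        if (colorNoiseSD > 0)
            img <- img + array(stats::rnorm(3 * n, 0, colorNoiseSD),
                               dim = dim(img))
        img <- round(pmin(pmax(img, 0), 255))
        storage.mode(img) <- "integer"
        attr(truth, "levels") <- classes
        list(image = img, truth = truth, pixelSize = pixelSize,
             params = list(width = width, height = height,
                           fractions = stats::setNames(fractions, classes),
                           collagenLayout = collagenLayout,
                           clusterCount = clusterCount,
                           colorNoiseSD = colorNoiseSD, seed = seed))
    })
}

## Sample `nc` distinct pixel indices concentrated in `k` Gaussian blobs.
.sampleClustered <- function(h, w, nc, k) {
    cx <- stats::runif(k, 0.15 * w, 0.85 * w)
    cy <- stats::runif(k, 0.15 * h, 0.85 * h)
    sd <- sqrt(nc / k) * 0.7 + 2
    got <- integer()
    while (length(got) < nc) {
        m <- 2L * (nc - length(got)) + 50L
        j <- sample.int(k, m, replace = TRUE)
        x <- pmin(pmax(round(stats::rnorm(m, cx[j], sd)), 1), w)
        y <- pmin(pmax(round(stats::rnorm(m, cy[j], sd)), 1), h)
        got <- unique(c(got, (x - 1L) * h + y))
    }
    got[seq_len(nc)]
}

## Sample `nc` distinct indices from the thinnest border band that holds them.
.sampleBorder <- function(h, w, nc) {
    d <- pmin(outer(seq_len(h), rep(1, w)), outer(rep(1, h), seq_len(w)),
              outer(h - seq_len(h) + 1, rep(1, w)),
              outer(rep(1, h), w - seq_len(w) + 1))
    band <- 1L
    while (sum(d <= band) < nc && band < max(h, w)) band <- band + 1L
    sample(which(d <= band), nc)
}
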