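#' K-means colour clustering of a trichrome image
#'
#' Clusters pixel colours in raw RGB space into \code{k} representative
#' colours (default 16), then assigns every pixel to its nearest centroid
#' (Euclidean RGB distance, ties broken towards the lowest cluster index).
#' When the image contains exactly \code{k} distinct colours the centroids
#' are those colours and the labelling is exact.
#'
#' @param image H x W x 3 RGB array (0-255) or a list from
#'   \code{\link{genTrichromeImage}}.
#' @param k number of colour clusters, >= 2 and at most the number of
#'   distinct colours in the image.
#' @param seed RNG seed for the k-means initialization.
#' @param nstart,iterMax k-means control parameters.
#' @return a \linkS4class{ColorClusterModel}.
#' @export
clusterColors <- function(image, k = 16, seed = 1, nstart = 5,
                          iterMax = 100) {
    if (is.list(image)) image <- image$image
    stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
    .checkScalar(k, "k", 2)
    h <- dim(image)[1]; w <- dim(image)[2]
    pix <- cbind(as.numeric(image[, , 1]), as.numeric(image[, , 2]),
                 as.numeric(image[, , 3]))
    distinct <- unique(pix)
    if (k > nrow(distinct))
        stop(sprintf("k = %d exceeds the %d distinct colours in the image",
                     k, nrow(distinct)), call. = FALSE)
    centroids <- if (k == nrow(distinct)) {
        distinct[order(distinct[, 1], distinct[, 2], distinct[, 3]), ,
                 drop = FALSE]
    } else {
        ## empty clusters are harmless: labels are reassigned to nearest
        ## centroids below, and unused centroids simply go unreferenced
        withSeed(seed, suppressWarnings(
            stats::kmeans(pix, centers = k, nstart = nstart,
                          iter.max = iterMax,
                          algorithm = "Lloyd")$centers))
    }
    labels <- .nearestCentroid(pix, centroids)
    new("ColorClusterModel", k = as.integer(k),
        centroids = unname(centroids),
        labels = matrix(labels, h, w), seed = seed)
}

## Row-wise nearest centroid, ties to the lowest index.
.nearestCentroid <- function(pix, centroids) {
    d2 <- outer(rowSums(pix^2), rep(1, nrow(centroids))) -
        2 * pix %*% t(centroids) +
        outer(rep(1, nrow(pix)), rowSums(centroids^2))
    max.col(-d2, ties.method = "first")
}

## Class prototypes used by the fallback nearest-prototype rule.
.classPrototypes <- function(scaffoldPresent) {
    p <- rbind(background = c(255, 255, 255),
               collagen   = c(60, 90, 200),
               tissue     = c(150, 60, 120),
               scaffold   = c(20, 20, 20))
    if (!scaffoldPresent) p <- p[rownames(p) != "scaffold", , drop = FALSE]
    p
}

#' Assign tissue classes to colour clusters
#'
#' Maps each centroid of a \linkS4class{ColorClusterModel} to one of
#' background, collagen, tissue or scaffold, and propagates the assignment
#' to all pixels. The rule set follows the trichrome colour families:
#' near-white centroids are background, near-black ones scaffold (when a
#' scaffold is present in the preparation), blue-dominant ones collagen, and
#' red-purple ones (red and blue both exceeding green) preserved tissue.
#' Centroids matching no family are assigned to the nearest class prototype
#' and flagged for review in the audit table.
#'
#' @param model a \linkS4class{ColorClusterModel}.
#' @param scaffoldPresent whether black tones may be scaffold material; when
#'   \code{FALSE} dark centroids fall through to the nearest-prototype rule.
#' @param delta blue/purple dominance margin (0-255 scale).
#' @param brightMin minimum channel value for the background rule.
#' @param darkMax maximum channel value for the scaffold rule.
#' @param pixelSize calibration (um/pixel) carried to area quantification.
#' @param rule optional explicit character vector (length k) of classes,
#'   overriding the automatic rules.
#' @return a \linkS4class{PixelClassMap}; its \code{classRule} slot is the
#'   centroid-to-class audit table.
#' @export
classifyClusters <- function(model, scaffoldPresent = TRUE, delta = 20,
                             brightMin = 220, darkMax = 60, pixelSize = 0.65,
                             rule = NULL) {
    stopifnot(is(model, "ColorClusterModel"))
    levs <- c("background", "collagen", "tissue", "scaffold")
    cen <- model@centroids
    k <- nrow(cen)
    if (!is.null(rule)) {
        if (length(rule) != k || !all(rule %in% levs))
            stop("'rule' must assign every centroid a valid class",
                 call. = FALSE)
        cls <- rule
        why <- rep("explicit", k); flag <- rep(FALSE, k)
    } else {
        cls <- character(k); why <- character(k); flag <- logical(k)
        proto <- .classPrototypes(scaffoldPresent)
        for (i in seq_len(k)) {
            rgb <- cen[i, ]
            if (min(rgb) >= brightMin) {
                cls[i] <- "background"; why[i] <- "bright"
            } else if (scaffoldPresent && max(rgb) <= darkMax) {
                cls[i] <- "scaffold"; why[i] <- "dark"
            } else if (rgb[3] == max(rgb) && rgb[3] - rgb[1] >= delta) {
                cls[i] <- "collagen"; why[i] <- "blue-dominant"
            } else if (rgb[1] - rgb[2] >= delta && rgb[3] - rgb[2] >= delta) {
                cls[i] <- "tissue"; why[i] <- "red-purple"
            } else {
                j <- .nearestCentroid(matrix(rgb, 1), proto)
                cls[i] <- rownames(proto)[j]
                why[i] <- "nearest-prototype"; flag[i] <- TRUE
            }
        }
    }
    audit <- data.frame(R = cen[, 1], G = cen[, 2], B = cen[, 3],
                        class = cls, rule = why, flagged = flag)
    codes <- match(cls, levs)
    new("PixelClassMap",
        classes = matrix(codes[model@labels], nrow(model@labels),
                         ncol(model@labels)),
        classLevels = levs, classRule = audit, pixelSize = pixelSize)
}

#' Quantify class areas and the blue/purple ratio
#'
#' Converts per-class pixel counts to areas (um^2) and reports the
#' collagen-to-tissue ("blue/purple") area ratio with the background
#' excluded. The ratio is flagged undefined when no tissue pixels exist.
#'
#' @param classmap a \linkS4class{PixelClassMap}.
#' @param pixelSize calibration (um/pixel); defaults to the one stored in
#'   the class map.
#' @return an \linkS4class{AreaReport}.
#' @export
quantifyAreas <- function(classmap, pixelSize = NULL) {
    stopifnot(is(classmap, "PixelClassMap"))
    if (is.null(pixelSize)) pixelSize <- classmap@pixelSize
    levs <- classmap@classLevels
    counts <- tabulate(classmap@classes, nbins = length(levs))
    areas <- stats::setNames(counts * pixelSize^2, levs)
    tissue <- areas[["tissue"]]
    defined <- tissue > 0
    new("AreaReport", areas = areas,
        bluePurpleRatio = if (defined) areas[["collagen"]] / tissue else
            NA_real_,
        ratioDefined = defined,
        excludedBackground = areas[["background"]])
}

#' Blue stain intensity of collagen pixels
#'
#' The intensity of blue staining is the inverse of the grey-scale value of
#' each collagen pixel, scaled to [0, 1] (grey 255 = white = intensity 0,
#' grey 0 = black = intensity 1). Non-collagen pixels carry 0. Grey-scale
#' conversion uses the luminance weighting 0.299 R + 0.587 G + 0.114 B.
#'
#' @param image H x W x 3 RGB array (0-255).
#' @param classmap a \linkS4class{PixelClassMap} aligned with the image.
#' @return list with \code{intensity} (H x W matrix in [0, 1]) and
#'   \code{mask} (logical collagen mask).
#' @export
blueIntensity <- function(image, classmap) {
    if (is.list(image)) image <- image$image
    stopifnot(is(classmap, "PixelClassMap"))
    if (!identical(dim(image)[1:2], dim(classmap@classes)))
        stop("image and class map dimensions differ", call. = FALSE)
    gray <- matrix(.luminance(image[, , 1], image[, , 2], image[, , 3]),
                   dim(image)[1], dim(image)[2])
    mask <- classmap@classes ==
        match("collagen", classmap@classLevels)
    intensity <- matrix(0, nrow(gray), ncol(gray))
    intensity[mask] <- (255 - gray[mask]) / 255
    list(intensity = intensity, mask = mask)
}
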