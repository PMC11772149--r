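## 8-connected component labelling: EBImage::bwlabel (4-connected) followed
## by union-find merging of diagonally adjacent label pairs.
.label8 <- function(mask) {
    lab <- EBImage::imageData(EBImage::bwlabel(mask * 1))
    nl <- max(lab)
    if (nl <= 1) return(lab)
    parent <- seq_len(nl)
    find <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    for (d in list(c(1, 1), c(1, -1))) {
        b <- .shiftMat(lab, d[1], d[2])
        sel <- lab > 0 & b > 0 & lab != b
        if (any(sel)) {
            prs <- unique(cbind(lab[sel], b[sel]))
            for (r in seq_len(nrow(prs))) {
                ra <- find(prs[r, 1]); rb <- find(prs[r, 2])
                if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
            }
        }
    }
    root <- vapply(seq_len(nl), find, numeric(1))
    newId <- match(root, sort(unique(root)))
    out <- lab
    out[lab > 0] <- newId[lab[lab > 0]]
    out
}

## Zhang-Suen thinning to a 1-pixel skeleton. Vectorized over neighbour
## shifts; terminates when an iteration removes nothing.
.thin <- function(mask) {
    m <- mask * 1
    repeat {
        changed <- FALSE
        for (step in 1:2) {
            p2 <- .shiftMat(m, 1, 0);  p3 <- .shiftMat(m, 1, -1)
            p4 <- .shiftMat(m, 0, -1); p5 <- .shiftMat(m, -1, -1)
            p6 <- .shiftMat(m, -1, 0); p7 <- .shiftMat(m, -1, 1)
            p8 <- .shiftMat(m, 0, 1);  p9 <- .shiftMat(m, 1, 1)
            bp <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
            ap <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) +
                  (p4 == 0 & p5 == 1) + (p5 == 0 & p6 == 1) +
                  (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
                  (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
            cond <- m == 1 & bp >= 2 & bp <= 6 & ap == 1
            if (step == 1)
                cond <- cond & (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
            else
                cond <- cond & (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
            if (any(cond)) {
                m[cond] <- 0
                changed <- TRUE
            }
        }
        if (!changed) break
    }
    m == 1
}

## Ordered backbone of a skeleton: the longest shortest path (weighted
## graph diameter) over the 8-adjacency graph with weights 1 / sqrt(2).
## Choosing the diameter path ignores short side spurs left by thinning.
## Returns the ordered pixel coordinates and the geometric path length: the
## Euclidean length of the polyline through every 4th backbone pixel (which
## removes the staircase digitization bias of per-step chain codes), plus 1
## for the pixel-count convention.
.skeletonPath <- function(skel) {
    idx <- which(skel, arr.ind = TRUE)
    n <- nrow(idx)
    if (n <= 1) return(list(path = idx, lengthPx = n))
    stride <- max(idx[, 1]) + 1
    key <- idx[, 1] + (idx[, 2] - 1) * stride
    lookup <- stats::setNames(seq_len(n), key)
    edges <- NULL; wts <- NULL
    for (d in list(c(0, 1, 1), c(1, 0, 1), c(1, 1, sqrt(2)),
                   c(-1, 1, sqrt(2)))) {
        nb <- (idx[, 1] + d[1]) + (idx[, 2] + d[2] - 1) * stride
        j <- lookup[as.character(nb)]
        ok <- !is.na(j)
        if (any(ok)) {
            edges <- rbind(edges, cbind(which(ok), j[ok]))
            wts <- c(wts, rep(d[3], sum(ok)))
        }
    }
    if (is.null(edges))   # isolated pixels only
        return(list(path = idx[1, , drop = FALSE], lengthPx = 1))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    if (igraph::vcount(g) < n)
        g <- igraph::add_vertices(g, n - igraph::vcount(g))
    igraph::E(g)$weight <- wts
    deg <- igraph::degree(g)
    ends <- which(deg <= 1)
    if (length(ends) < 2) ends <- seq_len(n)   # loop-like skeleton
    dm <- igraph::distances(g, v = ends, to = ends)
    dm[!is.finite(dm)] <- 0
    far <- which(dm == max(dm), arr.ind = TRUE)[1, ]
    vp <- igraph::shortest_paths(g, from = ends[far[1]],
                                 to = ends[far[2]])$vpath[[1]]
    path <- idx[as.integer(vp), , drop = FALSE]
    m <- nrow(path)
    samp <- unique(c(seq(1, m, by = 4), m))
    pts <- path[samp, , drop = FALSE]
    len <- sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                             pts[-nrow(pts), , drop = FALSE])^2)))
    list(path = path, lengthPx = len + 1)
}

## Geodesic length of a component: longest shortest path between component
## pixels (double-sweep approximation), polyline-resampled like the
## skeleton backbone. For a tube this runs from end-cap tip to end-cap tip,
## so the tube length is this value minus (width - 1).
.componentGeodesicLength <- function(comp) {
    idx <- which(comp, arr.ind = TRUE)
    n <- nrow(idx)
    if (n <= 1) return(n)
    stride <- max(idx[, 1]) + 1
    key <- idx[, 1] + (idx[, 2] - 1) * stride
    lookup <- stats::setNames(seq_len(n), key)
    edges <- NULL; wts <- NULL
    for (d in list(c(0, 1, 1), c(1, 0, 1), c(1, 1, sqrt(2)),
                   c(-1, 1, sqrt(2)))) {
        nb <- (idx[, 1] + d[1]) + (idx[, 2] + d[2] - 1) * stride
        j <- lookup[as.character(nb)]
        ok <- !is.na(j)
        if (any(ok)) {
            edges <- rbind(edges, cbind(which(ok), j[ok]))
            wts <- c(wts, rep(d[3], sum(ok)))
        }
    }
    if (is.null(edges)) return(1)
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    if (igraph::vcount(g) < n)
        g <- igraph::add_vertices(g, n - igraph::vcount(g))
    igraph::E(g)$weight <- wts
    sweep1 <- igraph::distances(g, v = 1)
    u <- which.max(sweep1)
    vp <- igraph::shortest_paths(g, from = u,
                                 to = which.max(igraph::distances(
                                     g, v = u)))$vpath[[1]]
    path <- idx[as.integer(vp), , drop = FALSE]
    m <- nrow(path)
    samp <- unique(c(seq(1, m, by = 4), m))
    pts <- path[samp, , drop = FALSE]
    sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                      pts[-nrow(pts), , drop = FALSE])^2))) + 1
}

## Caliper width: at interior backbone pixels, march perpendicular rays in
## half-pixel steps until they leave the component; the local width is the
## two reaches plus the centre pixel. Robust to tube orientation, unlike a
## distance-transform reading on a jagged rasterized boundary.
.caliperWidth <- function(comp, path) {
    m <- nrow(path)
    if (m < 9) return(NA_real_)
    h <- nrow(comp); w <- ncol(comp)
    inside <- function(y, x) {
        py <- floor(y + 0.5); px <- floor(x + 0.5)
        py >= 1 && py <= h && px >= 1 && px <= w && comp[py, px]
    }
    widths <- vapply(seq(5, m - 4, by = 3), function(i) {
        dirv <- path[i + 4, ] - path[i - 4, ]
        nv <- sqrt(sum(dirv^2))
        if (nv < 1e-9) return(NA_real_)
        perp <- c(-dirv[2], dirv[1]) / nv
        reach <- function(sg) {
            t <- 0
            while (t < max(h, w) &&
                   inside(path[i, 1] + sg * (t + 0.5) * perp[1],
                          path[i, 2] + sg * (t + 0.5) * perp[2]))
                t <- t + 0.5
            t
        }
        ## the half-pixel probe step overshoots by ~0.25 px per side
        reach(1) + reach(-1) + 0.5
    }, numeric(1))
    stats::median(widths, na.rm = TRUE)
}

#' Threshold a marker channel into a structure mask
#'
#' Binarizes a single-channel image at the positive-labelling threshold and
#' removes connected components (8-connected) smaller than \code{minSize}
#' pixels, which suppresses staining noise.
#'
#' @param channel single-channel intensity matrix, or an already-binary
#'   matrix / \linkS4class{StructureMask}.
#' @param threshold positive-labelling threshold.
#' @param minSize minimum component size (pixels) to keep.
#' @param pixelSize calibration (um/pixel).
#' @param axis rostro-caudal axis, \code{"rows"} or \code{"columns"}.
#' @return a \linkS4class{StructureMask}.
#' @export
segmentMask <- function(channel, threshold = 0.5, minSize = 10,
                        pixelSize = 0.5, axis = "rows") {
    if (is(channel, "StructureMask")) {
        mask <- channel@mask
        pixelSize <- channel@pixelSize
        axis <- channel@axis
    } else {
        stopifnot(is.matrix(channel))
        mask <- channel >= threshold
    }
    if (minSize > 1 && any(mask)) {
        lab <- .label8(mask)
        sizes <- tabulate(lab[lab > 0])
        drop <- which(sizes < minSize)
        if (length(drop)) mask[lab %in% drop] <- FALSE
    }
    new("StructureMask", mask = mask, pixelSize = pixelSize, axis = axis)
}

#' Measure structures in a binary mask
#'
#' Counts 8-connected structures and measures each one: length as the
#' geometric length of the skeleton backbone (the longest path through the
#' thinned structure, polyline-resampled to remove staircase digitization
#' bias), vessel diameter as the median caliper width measured
#' perpendicular to the backbone, and the bounding extent along the
#' declared rostro-caudal axis. All outputs in um.
#'
#' @param mask a \linkS4class{StructureMask} (or logical matrix).
#' @param kind \code{"neurite"} or \code{"vessel"}; diameters are reported
#'   for vessels only.
#' @param pixelSize,axis used when \code{mask} is a plain matrix.
#' @return a \linkS4class{StructureStats}; an empty mask gives zero
#'   structures.
#' @examples
#' m <- matrix(FALSE, 20, 120); m[10, 11:110] <- TRUE
#' s <- measureStructures(new("StructureMask", mask = m, pixelSize = 1,
#'                            axis = "columns"), kind = "neurite")
#' as.data.frame(s)   # length 100, extent 100
#' @export
measureStructures <- function(mask, kind = c("neurite", "vessel"),
                              pixelSize = 0.5, axis = "rows") {
    kind <- match.arg(kind)
    if (is(mask, "StructureMask")) {
        px <- mask@pixelSize; ax <- mask@axis; m <- mask@mask
    } else {
        px <- pixelSize; ax <- axis; m <- mask
    }
    empty <- data.frame(length = numeric(), diameter = numeric(),
                        extent = numeric())
    if (!any(m))
        return(new("StructureStats", table = empty, kind = kind,
                   pixelSize = px))
    lab <- .label8(m)
    skel <- .thin(m)
    dist <- EBImage::imageData(EBImage::distmap(m * 1))
    rows <- lapply(seq_len(max(lab)), function(i) {
        comp <- lab == i
        sk <- skel & comp
        if (!any(sk)) sk <- comp & dist == max(dist[comp])  # degenerate blob
        bb <- .skeletonPath(sk)
        diamPx <- .caliperWidth(comp, bb$path)
        if (is.na(diamPx)) diamPx <- 2 * stats::median(dist[sk]) - 1
        ## thin structures: skeleton backbone geodesic. Thick tubes: the
        ## skeleton is end-eroded by thinning, so use the tip-to-tip
        ## geodesic of the component itself minus the width
        lenPx <- bb$lengthPx
        if (diamPx > 2)
            lenPx <- max(lenPx,
                         .componentGeodesicLength(comp) -
                             max(1, round(diamPx)))
        idx <- which(comp, arr.ind = TRUE)
        axv <- if (ax == "rows") idx[, 1] else idx[, 2]
        data.frame(length = lenPx * px,
                   diameter = if (kind == "vessel") diamPx * px else
                       NA_real_,
                   extent = (max(axv) - min(axv) + 1) * px)
    })
    new("StructureStats", table = do.call(rbind, rows), kind = kind,
        pixelSize = px)
}

#' Totals of a structure measurement
#'
#' @param stats a \linkS4class{StructureStats}.
#' @return named numeric: \code{n}, \code{total_length} (um),
#'   \code{mean_diameter} (um, vessels).
#' @export
structureTotals <- function(stats) {
    stopifnot(is(stats, "StructureStats"))
    tab <- stats@table
    c(n = nrow(tab), total_length = sum(tab$length),
      mean_diameter = if (all(is.na(tab$diameter))) NA_real_ else
          mean(tab$diameter, na.rm = TRUE))
}
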