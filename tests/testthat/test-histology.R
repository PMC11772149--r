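flatImage <- function(h, w, cols) {
    ## image tiled with the given list of RGB colours, in equal runs
    n <- h * w
    idx <- rep(seq_along(cols), length.out = n)
    img <- array(0L, c(h, w, 3))
    for (ch in 1:3)
        img[, , ch] <- matrix(vapply(idx, function(i) cols[[i]][ch], 0),
                              h, w)
    img
}

test_that("two flat colours are recovered exactly with k = 2", {
    img <- flatImage(20, 20, list(c(10, 20, 30), c(200, 100, 50)))
    m <- clusterColors(img, k = 2, seed = 1)
    cen <- m@centroids[order(m@centroids[, 1]), ]
    expect_equal(unname(cen), rbind(c(10, 20, 30), c(200, 100, 50)))
    ## every pixel labelled with its own colour
    lab <- m@labels
    expect_equal(length(unique(lab[img[, , 1] == 10])), 1L)
    expect_equal(length(unique(lab[img[, , 1] == 200])), 1L)
})

test_that("a 16-colour palette image yields the 16 palette centroids", {
    cols <- lapply(0:15, function(i) c(i * 16, (15 - i) * 16, i * 10 + 5))
    img <- flatImage(32, 32, cols)
    m <- clusterColors(img, k = 16, seed = 1)
    expect_equal(m@k, 16L)
    got <- m@centroids[order(m@centroids[, 1]), ]
    want <- do.call(rbind, cols)[order(sapply(cols, `[`, 1)), ]
    expect_equal(unname(got), unname(want))
    ## nearest-centroid invariant holds for every pixel
    pix <- cbind(as.numeric(img[, , 1]), as.numeric(img[, , 2]),
                 as.numeric(img[, , 3]))
    expect_equal(as.integer(m@labels),
                 cordmetrics:::.nearestCentroid(pix, m@centroids))
})

test_that("k larger than the distinct-colour count is rejected", {
    img <- flatImage(8, 8, list(c(0, 0, 0), c(255, 255, 255)))
    expect_error(clusterColors(img, k = 3), "distinct colours")
})

test_that("clustering is deterministic under a fixed seed", {
    g <- genTrichromeImage(64, 64, seed = 9)
    m1 <- clusterColors(g$image, k = 8, seed = 4)
    m2 <- clusterColors(g$image, k = 8, seed = 4)
    expect_identical(m1@labels, m2@labels)
    expect_identical(m1@centroids, m2@centroids)
})

test_that("centroid classes follow the trichrome colour families", {
    mkModel <- function(cen) new("ColorClusterModel", k = nrow(cen),
                                 centroids = cen,
                                 labels = matrix(seq_len(nrow(cen)), 1),
                                 seed = 1)
    cen <- rbind(c(0, 0, 255), c(255, 255, 255), c(40, 40, 40),
                 c(160, 70, 140))
    cm <- classifyClusters(mkModel(cen), scaffoldPresent = TRUE)
    expect_equal(cm@classRule$class,
                 c("collagen", "background", "scaffold", "tissue"))
    expect_false(any(cm@classRule$flagged))
    ## without a scaffold in the preparation, near-black falls through to
    ## the nearest prototype (dark tissue) and is flagged for review
    cm2 <- classifyClusters(mkModel(cen), scaffoldPresent = FALSE)
    expect_equal(cm2@classRule$class[3], "tissue")
    expect_true(cm2@classRule$flagged[3])
})

test_that("areas and the blue/purple ratio follow pixel counts", {
    classes <- matrix(1L, 100, 100)
    classes[1:40, ] <- 2L          # 4000 collagen px
    classes[41:60, ] <- 3L         # 2000 tissue px
    cm <- new("PixelClassMap", classes = classes,
              classLevels = c("background", "collagen", "tissue",
                              "scaffold"),
              classRule = data.frame(), pixelSize = 1)
    ar <- quantifyAreas(cm, pixelSize = 1)
    expect_equal(ar@bluePurpleRatio, 2)
    expect_equal(sum(ar@areas), 100 * 100)
    ## all background: areas zero except background, ratio undefined
    cm2 <- new("PixelClassMap", classes = matrix(1L, 10, 10),
               classLevels = cm@classLevels, classRule = data.frame(),
               pixelSize = 1)
    ar2 <- quantifyAreas(cm2)
    expect_false(ar2@ratioDefined)
    expect_true(is.na(ar2@bluePurpleRatio))
})

test_that("blue intensity is the normalized luminance complement", {
    img <- array(0L, c(1, 3, 3))
    img[1, 1, ] <- c(255, 255, 255)   # white collagen -> 0
    img[1, 2, ] <- c(0, 0, 0)         # black -> 1
    img[1, 3, ] <- c(100, 150, 200)
    cm <- new("PixelClassMap", classes = matrix(2L, 1, 3),
              classLevels = c("background", "collagen", "tissue",
                              "scaffold"),
              classRule = data.frame(), pixelSize = 1)
    bi <- blueIntensity(img, cm)
    lum <- 0.299 * 100 + 0.587 * 150 + 0.114 * 200
    expect_equal(as.numeric(bi$intensity),
                 c(0, 1, (255 - lum) / 255))
    ## non-collagen pixels carry zero
    cm@classes[1, 2] <- 3L
    expect_equal(blueIntensity(img, cm)$intensity[1, 2], 0)
    expect_error(blueIntensity(array(0, c(2, 2, 3)), cm), "dimensions")
})

test_that("class areas are recovered from synthetic sections within 2%", {
    fr <- c(0.35, 0.3, 0.3, 0.05)
    g <- genTrichromeImage(256, 256, pixelSize = 1, fractions = fr,
                           collagenLayout = "clustered", seed = 21)
    m <- clusterColors(g$image, k = 16, seed = 1)
    cm <- classifyClusters(m, pixelSize = 1)
    ar <- quantifyAreas(cm)
    tot <- 256 * 256
    expect_true(all(abs(ar@areas / tot - fr) < 0.02))
    expect_lt(abs(ar@bluePurpleRatio - fr[2] / fr[3]) / (fr[2] / fr[3]),
              0.05)
})
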