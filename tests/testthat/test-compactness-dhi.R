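test_that("compactness handles the isolated-pixel and full-block limits", {
    ## single isolated collagen pixel of intensity 1, radius 1
    int <- matrix(0, 5, 5); int[3, 3] <- 1
    cmap <- collagenCompactness(int, int > 0, radius = 1)
    expect_equal(cmap@compactness[3, 3], 1)
    ## 3x3 all-collagen block of intensity 1: centre accumulates all nine
    int2 <- matrix(1, 3, 3)
    cmap2 <- collagenCompactness(int2, matrix(TRUE, 3, 3), radius = 1)
    expect_equal(cmap2@compactness[2, 2], 9)
    expect_equal(cmap2@compactness[1, 1], 4)   # border truncation
    expect_error(collagenCompactness(int2, matrix(TRUE, 3, 3), radius = 0),
                 "radius")
})

test_that("compactness equals the exhaustive oracle bit for bit", {
    set.seed(101)
    for (i in 1:8) {
        h <- sample(8:64, 1); w <- sample(8:64, 1)
        r <- sample(1:3, 1)
        mask <- matrix(runif(h * w) < 0.4, h, w)
        int <- matrix(runif(h * w), h, w) * mask
        cmap <- collagenCompactness(int, mask, radius = r)
        expect_identical(cmap@compactness, bruteCompactness(int, mask, r))
    }
})

test_that("adding adjacent collagen never decreases compactness", {
    set.seed(77)
    mask <- matrix(runif(400) < 0.3, 20, 20)
    int <- matrix(runif(400), 20, 20) * mask
    base <- collagenCompactness(int, mask, radius = 1)
    ## grow the mask by one neighbouring pixel of positive intensity
    cand <- which(!mask)[1]
    mask2 <- mask; mask2[cand] <- TRUE
    int2 <- int; int2[cand] <- 0.5
    grown <- collagenCompactness(int2, mask2, radius = 1)
    expect_true(all(grown@compactness[mask] >= base@compactness[mask]))
})

test_that("compactness bins split areas at quarters of the maximum", {
    ## uniform compactness everywhere sits in the top (75-100%) level
    const <- new("CompactnessMap", intensity = matrix(0.5, 6, 6),
                 mask = matrix(TRUE, 6, 6),
                 compactness = matrix(4.5, 6, 6), radius = 1L)
    h <- binCompactness(const, 1)
    expect_equal(unname(h@levelFractions), c(0, 0, 0, 1))
    ## two-level map {c, c/10}: split across bottom and top bins
    cmap <- new("CompactnessMap",
                intensity = matrix(0.1, 2, 5), mask = matrix(TRUE, 2, 5),
                compactness = rbind(rep(2, 5), rep(0.2, 5)), radius = 1L)
    h2 <- binCompactness(cmap, 1)
    expect_equal(unname(h2@levelFractions), c(0.5, 0, 0, 0.5))
    ## fractions always sum to 1 on random maps
    set.seed(5)
    for (i in 1:5) {
        mask <- matrix(runif(64) < 0.5, 8, 8)
        if (!any(mask)) next
        int <- matrix(runif(64), 8, 8) * mask
        hh <- binCompactness(collagenCompactness(int, mask), 1)
        expect_equal(sum(hh@levelFractions), 1)
    }
    ## no collagen: flagged empty
    he <- binCompactness(collagenCompactness(matrix(0, 4, 4),
                                             matrix(FALSE, 4, 4)), 1)
    expect_true(he@empty)
})

test_that("positive area fraction counts thresholded pixels", {
    m <- matrix(200, 10, 10)
    expect_equal(positiveAreaFraction(m, 100), 100)
    expect_equal(positiveAreaFraction(m, 201), 0)
    m2 <- matrix(0, 10, 10); m2[1:37] <- 255
    expect_equal(positiveAreaFraction(m2, 128), 37)
    expect_error(positiveAreaFraction(m, 300), "range")
})

test_that("DHI is zero for uniform coverage and ranks layouts correctly", {
    ## exactly uniform block coverage at all dyadic scales
    u <- matrix(0, 64, 64); u[seq(1, 64, 4), seq(1, 64, 4)] <- 1
    expect_equal(dhi(computeDHI(u, c(4, 8, 16))), 0)
    ## same global coverage, one corner vs scattered
    n <- 64
    corner <- matrix(0, n, n); corner[1:16, 1:16] <- 1
    scattered <- matrix(0, n, n); scattered[seq(1, n, 4), seq(1, n, 4)] <- 1
    expect_equal(mean(corner), mean(scattered))
    expect_gt(dhi(computeDHI(corner)), dhi(computeDHI(scattered)))
    ## empty mask: undefined, flagged
    e <- computeDHI(matrix(0, 32, 32))
    expect_false(e@defined)
    expect_true(is.na(dhi(e)))
})

test_that("DHI is invariant to permuting block positions at one scale", {
    set.seed(12)
    s <- 8; nb <- 4
    blocks <- lapply(1:(nb * nb), function(i) matrix(runif(s * s) < 0.3,
                                                     s, s))
    build <- function(ord) {
        m <- matrix(0, nb * s, nb * s)
        k <- 1
        for (i in 1:nb) for (j in 1:nb) {
            m[((i - 1) * s + 1):(i * s), ((j - 1) * s + 1):(j * s)] <-
                blocks[[ord[k]]]
            k <- k + 1
        }
        m
    }
    d1 <- dhi(computeDHI(build(1:16), s))
    d2 <- dhi(computeDHI(build(sample(16)), s))
    expect_equal(d1, d2)
})
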