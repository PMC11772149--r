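test_that("segmentation thresholds and removes specks", {
    ## already-binary mask passes through unchanged
    g <- genStructureMask(64, 64, 2, "neurite", lengthRange = c(10, 15),
                          seed = 2)
    sm <- segmentMask(g$mask)
    expect_identical(sm@mask, g$mask@mask)
    ## a 3-px speck below min_size disappears
    ch <- matrix(0, 32, 32)
    ch[5, 5:7] <- 1
    ch[20, 5:25] <- 1
    sm2 <- segmentMask(ch, threshold = 0.5, minSize = 10)
    expect_false(any(sm2@mask[5, ]))
    expect_true(all(sm2@mask[20, 5:25]))
    ## graded image with known positive fraction
    ch3 <- matrix(0, 50, 50); ch3[1:925] <- 1   # 37%
    sm3 <- segmentMask(ch3, threshold = 0.5, minSize = 1)
    expect_equal(mean(sm3@mask), 0.37)
})

test_that("axis-aligned and diagonal structures measure exactly", {
    s <- measureStructures(straightMask(20, 160, 10, 21:120), "neurite")
    tab <- as.data.frame(s)
    expect_equal(nrow(tab), 1)
    expect_equal(tab$length, 100)
    expect_equal(tab$extent, 100)
    ## 45-degree segment spanning 100 px: extent 100, length ~ 141
    m <- matrix(FALSE, 160, 160); m[cbind(21:120, 21:120)] <- TRUE
    d <- as.data.frame(measureStructures(
        new("StructureMask", mask = m, pixelSize = 1, axis = "columns"),
        "neurite"))
    expect_equal(d$extent, 100)
    expect_lt(abs(d$length - 141) / 141, 0.05)
    ## empty mask: zero structures
    e <- measureStructures(straightMask(10, 10, integer(), integer()),
                           "neurite")
    expect_equal(nrow(as.data.frame(e)), 0)
})

test_that("vessel diameters come from the caliper width", {
    s <- as.data.frame(measureStructures(
        straightMask(60, 160, 20:30, 21:120), "vessel"))
    expect_equal(s$diameter, 11)
})

test_that("generator truth is recovered within stated tolerances", {
    for (seed in 1:4) {
        g <- genStructureMask(256, 256, 5, "neurite",
                              lengthRange = c(30, 60), pixelSize = 0.5,
                              seed = seed)
        st <- as.data.frame(measureStructures(g$mask, "neurite"))
        expect_equal(nrow(st), 5)   # counts exact for disjoint structures
        lab <- cordmetrics:::.label8(g$mask@mask)
        id <- lab[cbind(g$truth$seed_row, g$truth$seed_col)]
        relErr <- (st$length[id] - g$truth$length) / g$truth$length
        expect_true(all(abs(relErr) < 0.05))
    }
    g <- genStructureMask(256, 256, 4, "vessel", lengthRange = c(60, 120),
                          diameterRange = c(8, 16), pixelSize = 1,
                          curvSD = 1, seed = 7)
    st <- as.data.frame(measureStructures(g$mask, "vessel"))
    lab <- cordmetrics:::.label8(g$mask@mask)
    id <- lab[cbind(g$truth$seed_row, g$truth$seed_col)]
    expect_true(all(abs(st$diameter[id] - g$truth$diameter) /
                    g$truth$diameter < 0.10))
    expect_true(all(abs(st$length[id] - g$truth$length) /
                    g$truth$length < 0.05))
})

test_that("total length is additive over unions of disjoint structures", {
    a <- straightMask(40, 200, 10, 21:120)
    b <- straightMask(40, 200, 30, 41:100)
    u <- a
    u@mask <- a@mask | b@mask
    tu <- structureTotals(measureStructures(u, "neurite"))
    ta <- structureTotals(measureStructures(a, "neurite"))
    tb <- structureTotals(measureStructures(b, "neurite"))
    expect_equal(tu[["n"]], 2)
    expect_equal(tu[["total_length"]],
                 ta[["total_length"]] + tb[["total_length"]])
})

test_that("8-connected labelling joins diagonal touches", {
    m <- matrix(FALSE, 6, 6)
    m[cbind(1:4, 1:4)] <- TRUE       # diagonal chain: one component
    m[6, 6] <- TRUE                  # isolated pixel: second component
    lab <- cordmetrics:::.label8(m)
    expect_equal(max(lab), 2)
    expect_equal(length(unique(lab[cbind(1:4, 1:4)])), 1)
})
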