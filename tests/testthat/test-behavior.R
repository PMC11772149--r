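test_that("postural angles follow their closed forms", {
    expect_equal(ctlAngle(c(0, 2), c(0, 0), c(3, 0)), 90)
    expect_equal(ctlAngle(c(-2, 0), c(0, 0), c(5, 0)), 180)  # collinear
    expect_error(ctlAngle(c(0, 0), c(0, 0), c(1, 0)), "coincident")
    expect_equal(trunkAngle(c(0, 1), c(1, 1)), 0)            # horizontal
    expect_equal(trunkAngle(c(0, 1), c(1, 0)), 45)           # unit slope
    expect_equal(trunkAngle(c(0, 0), c(0, 2)), 90)
    expect_error(trunkAngle(c(0, 1), c(1, 0), c(0, 0)), "non-zero")
})

test_that("generated scenes round-trip their programmed angles", {
    for (i in 1:25) {
        ctl <- runif(1, 5, 180)
        trk <- runif(1, 0, 90)
        sc <- genLandmarkScene(ctl, trk, seed = i)
        a <- sceneAngles(sc)
        expect_lt(abs(a[["ctl"]] - ctl), 1e-6)
        expect_lt(abs(a[["trunk"]] - trk), 1e-6)
    }
    expect_error(genLandmarkScene(0, 10), "ctlAngle")
    expect_error(genLandmarkScene(90, 95), "trunkAngle")
    ## straight-angle scene is collinear
    sc <- genLandmarkScene(180, 20, seed = 3)
    v1 <- sc@eye - sc@shoulder; v2 <- sc@hip - sc@shoulder
    expect_lt(abs(v1[1] * v2[2] - v1[2] * v2[1]) /
              sqrt(sum(v1^2) * sum(v2^2)), 1e-9)
    ## zero trunk angle: shoulder-hip parallel to the ground
    sc0 <- genLandmarkScene(120, 0, seed = 4)
    d <- sc0@hip - sc0@shoulder
    expect_lt(abs(d[1] * sc0@ground[2] - d[2] * sc0@ground[1]) /
              sqrt(sum(d^2)), 1e-9)
})

test_that("angles are invariant under rigid motion and scaling", {
    set.seed(44)
    for (i in 1:20) {
        sc <- genLandmarkScene(runif(1, 10, 175), runif(1, 0, 90),
                               seed = i + 100)
        a0 <- sceneAngles(sc)
        th <- runif(1, 0, 360); shift <- runif(2, -50, 50)
        k <- runif(1, 0.2, 5)
        rot <- function(v) cordmetrics:::.rot2(v, th)
        sc2 <- new("LandmarkScene",
                   eye = k * rot(sc@eye) + shift,
                   shoulder = k * rot(sc@shoulder) + shift,
                   hip = k * rot(sc@hip) + shift,
                   ground = rot(sc@ground), frame = "t")
        expect_equal(sceneAngles(sc2), a0, tolerance = 1e-9)
    }
})

test_that("angle ranges need three frames and scan extremes", {
    m <- data.frame(ctl = c(90, 120, 150), trunk = c(10, 10, 10))
    r <- angleRange(m)
    expect_equal(r["ctl", "range"], 60)
    expect_equal(r["trunk", "range"], 0)
    expect_error(angleRange(m[1:2, ]), "at least 3")
    set.seed(1)
    m2 <- data.frame(ctl = runif(10, 0, 180), trunk = runif(10, 0, 90))
    r2 <- angleRange(m2)
    expect_equal(r2["ctl", "range"], max(m2$ctl) - min(m2$ctl))
})

test_that("prevalence reports per-group percentages and tables", {
    p <- prevalence(c(TRUE, TRUE, TRUE, TRUE, FALSE), rep("SCI", 5))
    expect_equal(unname(p$percent), 80)
    p2 <- prevalence(c(rep(FALSE, 4), rep(TRUE, 3)),
                     rep(c("A", "B"), c(4, 3)))
    expect_equal(unname(p2$percent), c(0, 100))
    expect_equal(as.numeric(p2$table["TRUE", ]), c(0, 3))
    p3 <- prevalence(c(TRUE, FALSE),
                     factor(c("A", "A"), levels = c("A", "B")))
    expect_equal(attr(p3, "emptyGroups"), "B")
    expect_true(is.na(p3$percent[["B"]]))
})
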