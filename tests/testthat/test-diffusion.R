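test_that("mask splitting cuts at crossings and conserves detections", {
    # track fully inside a permissive mask
    mask <- matrix(TRUE, 10, 10)
    d <- data.frame(track_id = 1, frame = 1:5,
                    x_nm = seq(100, 500, 100), y_nm = 500, z_nm = NA)
    ts <- TrackSet(d, dt = 0.01)
    sp <- splitTracksByMask(ts, mask, pixelSize = 100)
    expect_equal(length(sp$inside), 1L)
    expect_equal(length(sp$outside), 0L)

    # single crossing: one in-fragment, one out-fragment
    mask2 <- matrix(FALSE, 10, 10); mask2[1:6, ] <- TRUE
    sp2 <- splitTracksByMask(ts, mask2, pixelSize = 100)
    expect_equal(length(sp2$inside), 1L)
    expect_equal(length(sp2$outside), 0L)
    d2 <- d; d2$x_nm <- seq(100, 900, 200)
    sp3 <- splitTracksByMask(TrackSet(d2, dt = 0.01), mask2,
                             pixelSize = 100)
    expect_equal(length(sp3$inside) + length(sp3$outside), 2L)
    tot <- nrow(trackData(sp3$inside)) + nrow(trackData(sp3$outside))
    expect_equal(tot, 5L)
})

test_that("splitting with a full-field mask is the identity on D estimates", {
    ts <- genBrownianTracks(0.5, 0.01, nTracks = 20, nFrames = 15, dim = 2,
                            fieldNm = 5000, seed = 1)
    mask <- matrix(TRUE, 200, 200)   # covers the field at 100 nm/px... or not
    sp <- splitTracksByMask(ts, mask, pixelSize = 100,
                            origin = c(-10000, -10000))
    dIn <- estimateD(sp$inside, r2Min = 0)
    dAll <- estimateD(ts, r2Min = 0)
    expect_equal(sort(dIn$D), sort(dAll$D))
    expect_equal(length(sp$outside), 0L)
})

test_that("MSD fits recover D within 10% and floor immobile tracks near zero", {
    ts <- genBrownianTracks(1, 0.01, nTracks = 100, nFrames = 30, seed = 2)
    est <- estimateD(ts, r2Min = 0)
    expect_equal(nrow(est), 100L)
    expect_equal(mean(est$D), 1, tolerance = 0.1)

    still <- genBrownianTracks(0, 0.01, nTracks = 20, nFrames = 30,
                               locNoiseSd = 20, seed = 3)
    estS <- estimateD(still, r2Min = 0)
    # static-noise floor: D on the scale of sigma^2/dt, far below 0.1 um^2/s
    expect_lt(mean(estS$D), 0.05)
})

test_that("tracks shorter than minFrames or failing the R2 gate are excluded", {
    short <- genBrownianTracks(1, 0.01, nTracks = 5, nFrames = 5, seed = 4)
    expect_equal(nrow(estimateD(short, minFrames = 8)), 0L)
    noisy <- genBrownianTracks(0, 0.01, nTracks = 30, nFrames = 10,
                               locNoiseSd = 30, seed = 5)
    est <- estimateD(noisy, r2Min = 0.8)
    expect_true(any(!est$accepted))
})

test_that("mixture decomposition recovers labelled weights within 10 points", {
    pops <- data.frame(D = c(1.4, 0.017), fraction = c(0.36, 0.64))
    mx <- genMixtureTracks(pops, dt = 0.01, nTracks = 300, nFrames = 30,
                           dim = 2, locNoiseSd = 10, seed = 6)
    est <- estimateD(mx, r2Min = 0)
    fit <- dHistogramMixture(est$D, k = 2)
    expect_lt(abs(fit$components$weight[1] - 0.64), 0.10)
    expect_equal(fit$components$meanD[2], 1.4, tolerance = 0.25)

    one <- dHistogramMixture(10^rnorm(300, -1, 0.2), k = 1:2)
    expect_gte(max(one$components$weight), 0.9)
})

test_that("three-population data prefer k = 3 by BIC", {
    set.seed(7)
    D <- c(10^rnorm(150, log10(2.7), 0.15),
           10^rnorm(150, log10(0.61), 0.12),
           10^rnorm(150, log10(0.02), 0.15))
    fit <- dHistogramMixture(D, k = 2:3)
    expect_equal(fit$k, 3L)
    expect_equal(sort(fit$components$meanD),
                 sort(c(0.02, 0.61, 2.7)), tolerance = 0.2)
})

test_that("weight recovery degrades gracefully at 50 accepted fits", {
    pops <- data.frame(D = c(1.4, 0.017), fraction = c(0.36, 0.64))
    mx <- genMixtureTracks(pops, dt = 0.01, nTracks = 50, nFrames = 30,
                           dim = 2, locNoiseSd = 10, seed = 8)
    fit <- dHistogramMixture(estimateD(mx, r2Min = 0)$D, k = 2)
    expect_lt(abs(fit$components$weight[1] - 0.64), 0.15)
})
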