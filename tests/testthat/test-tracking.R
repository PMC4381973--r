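makeLocs <- function(ts) trackData(ts)[, c("frame", "x_nm", "y_nm", "z_nm")]

test_that("molecules farther apart than the search radius become separate tracks", {
    locs <- data.frame(frame = rep(1:5, 2),
                       x_nm = c(rep(0, 5), rep(5000, 5)),
                       y_nm = 0, z_nm = NA)
    lk <- linkTracks(locs, dt = 0.5, dMax = 0.05)
    expect_equal(length(lk), 2L)
    # every detection belongs to exactly one track
    expect_equal(nrow(trackData(lk)), 10L)
})

test_that("linking recovers generator identities at low density", {
    # ~0.05 tracks/um^2: 25 bound molecules in a 23 x 23 um field
    ts <- genBrownianTracks(0.001, dt = 0.5, nTracks = 25, nFrames = 10,
                            locNoiseSd = 15, fieldNm = 23000, seed = 21)
    truth <- trackData(ts)
    lk <- linkTracks(makeLocs(ts), dt = 0.5, dMax = 0.05)
    got <- trackData(lk)
    # match rows back to truth by coordinates, then check co-assignment
    key <- paste(round(truth$x_nm, 6), round(truth$y_nm, 6))
    gotKey <- paste(round(got$x_nm, 6), round(got$y_nm, 6))
    trueId <- truth$track_id[match(gotKey, key)]
    agree <- sapply(split(trueId, got$track_id),
                    function(v) length(unique(v)) == 1)
    expect_gte(mean(agree), 0.99)
    expect_equal(length(lk), 25L)
})

test_that("stable-site dwell criteria follow the displacement and duration rules", {
    # immobile 12-frame track at dt = 3 s: one site with residence 36 s
    im <- genBrownianTracks(0, dt = 3, nTracks = 1, nFrames = 12,
                            locNoiseSd = 2, seed = 1)
    s <- stableSites(im, maxDisp = 50, minDuration = 3)
    expect_equal(nrow(s), 1L)
    expect_equal(s$residence_s, 36)
    expect_equal(s$n_detections, 12L)

    # one 60 nm step disqualifies the whole track
    d <- trackData(im)
    d$x_nm[6] <- d$x_nm[6] + 60
    jump <- TrackSet(d, dt = 3)
    expect_equal(nrow(stableSites(jump, maxDisp = 50, minDuration = 3)), 0L)

    # end-to-end displacement alone can disqualify (many small steps drifting)
    drift <- data.frame(track_id = 1, frame = 1:10,
                        x_nm = seq(0, 90, by = 10), y_nm = 0, z_nm = 0)
    expect_equal(nrow(stableSites(TrackSet(drift, dt = 3),
                                  maxDisp = 50, minDuration = 3)), 0L)
})

test_that("identity limit and monotonicity of the site filter", {
    ts <- genBrownianTracks(0.02, dt = 1, nTracks = 30, nFrames = 8,
                            locNoiseSd = 10, seed = 5)
    all <- stableSites(ts, maxDisp = Inf, minDuration = 0,
                       singleFrame = "bound")
    expect_equal(nrow(all), 30L)
    nAt <- function(md, dur) nrow(stableSites(ts, maxDisp = md,
                                              minDuration = dur))
    expect_true(nAt(50, 2) >= nAt(50, 5))
    expect_true(nAt(30, 2) <= nAt(80, 2))
})

test_that("single-frame policy matches the slow-acquisition convention", {
    d <- data.frame(track_id = 1:3,
                    frame = c(1, 1, 2), x_nm = c(0, 9000, 4000),
                    y_nm = 0, z_nm = NA)
    ts <- TrackSet(d, dt = 0.5)
    bound <- stableSites(ts, maxDisp = 50, minDuration = 0.5,
                         singleFrame = "bound")
    expect_equal(nrow(bound), 3L)
    expect_equal(unique(bound$residence_s), 0.5)
    expect_equal(nrow(stableSites(ts, maxDisp = 50, minDuration = 0.5,
                                  singleFrame = "discard")), 0L)
})

test_that("mixture catalogs pass the dwell filter at close to the bound fraction", {
    pops <- data.frame(D = c(1.4, 1e-6), fraction = c(0.36, 0.64))
    mx <- genMixtureTracks(pops, dt = 0.5, nTracks = 200, nFrames = 8,
                           dim = 2, locNoiseSd = 8, seed = 31)
    s <- stableSites(mx, maxDisp = 50, minDuration = 2)
    frac <- nrow(s) / 200
    expect_lt(abs(frac - 0.64), 3 * sqrt(0.64 * 0.36 / 200) + 0.02)
    # and the passing tracks are overwhelmingly the labelled bound ones
    info <- trackInfo(mx)
    passPop <- info$population[match(s$track_id, info$track_id)]
    expect_gte(mean(passPop == 2), 0.98)
})

test_that("residence statistics and detection profiles tally correctly", {
    s <- data.frame(residence_s = c(3, 3, 3), start_frame = 1,
                    x_nm = 0, y_nm = 0, z_nm = 0)
    rs <- residenceStats(s)
    expect_equal(rs$mean, 3)
    expect_equal(rs$n, 3L)

    set.seed(2)
    rt <- rexp(400, 1 / 7) + 3
    rs2 <- residenceStats(data.frame(residence_s = rt))
    expect_equal(rs2$mean, mean(rt))
    expect_equal(sum(rs2$histogram$count), 400L)

    locs <- data.frame(frame = rep(1:20, each = 5))
    dpf <- detectionsPerFrame(locs)
    expect_equal(dpf$count, rep(5L, 20))
})

test_that("arrival CDFs distinguish step from uniform arrivals", {
    sites <- data.frame(start_frame = c(rep(1, 10), sample(1:100, 40,
                                                           replace = TRUE)),
                        x_nm = 0, y_nm = 0, z_nm = 0, residence_s = 3)
    regions <- c(rep(1L, 10), rep(2L, 40))
    cdfs <- arrivalCdf(sites, regions)
    expect_equal(cdfs[["1"]]$cdf[1], 0.1)
    expect_true(all(cdfs[["1"]]$frame == 1))
    # uniform arrivals: KS against uniform on the frame range is not rejected
    set.seed(3)
    u <- data.frame(start_frame = sample(1:1000, 300, replace = TRUE),
                    x_nm = 0, y_nm = 0, z_nm = 0, residence_s = 3)
    ks <- suppressWarnings(
        ks.test(u$start_frame, "punif", 1, 1000))
    expect_gt(ks$p.value, 1e-3)
    cd <- arrivalCdf(u, rep(1L, 300))[["1"]]
    expect_true(all(diff(cd$cdf) >= 0))
    expect_equal(tail(cd$cdf, 1), 1)
})

test_that("canopy clustering groups co-located sites at the canopy radius", {
    set.seed(4)
    a <- matrix(rnorm(60, 0, 50), ncol = 3)
    b <- matrix(rnorm(60, 0, 50), ncol = 3) +
         matrix(rep(c(3000, 0, 0), each = 20), ncol = 3)
    cat2 <- PointCatalog(rbind(a, b))
    id <- canopyCluster(cat2, radius = 400)
    expect_equal(length(unique(id[1:20])), 1L)
    expect_equal(length(unique(id[21:40])), 1L)
    expect_true(id[1] != id[21])
})
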