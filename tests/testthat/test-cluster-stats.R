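test_that("neighbour counts equal a brute-force scan and handle singletons", {
    cl <- genUniformPoints(100, sphereVolume(0.5), seed = 1)
    expect_equal(neighborDensity(cl, 400),
                 unname(bruteForceNeighborCounts(coords(cl), 400)))
    single <- PointCatalog(matrix(c(0, 0, 0), 1))
    expect_equal(neighborDensity(single, 400), 0L)
})

test_that("DD pair counts equal the brute-force histogram exactly", {
    cl <- genUniformPoints(800, sphereVolume(1), seed = 2)
    gr <- pairCorrelation3d(cl, deltaR = 50, rMax = 900, seed = 3)
    edges <- seq(0, 900 + 50 - 1e-9, by = 50)
    expect_equal(pairCounts(gr)$dd, as.numeric(
        bruteForcePairHist(coords(cl), edges)))
    expect_equal(sum(smTFmap:::cpp_pair_count(coords(cl),
                                              c(0, Inf))), 800 * 799 / 2)
})

test_that("fixed 10-point catalog matches an independent-pair CSR oracle", {
    set.seed(4)
    pts <- matrix(runif(30, 0, 1000), 10, 3)
    cl <- PointCatalog(pts)
    gr <- pairCorrelation3d(cl, deltaR = 200, randomFactor = 400,
                            rMax = 1000, volume = "convex-hull", seed = 5)
    # oracle: the CSR pair-distance density estimated from independent
    # random pairs in the same hull; g = DD / (N(N-1)/2 * p_bin)
    h <- convexHull3d(pts)
    set.seed(6)
    m <- 5e5
    a <- smTFmap:::runifHull3d(m, h, pts)
    b <- smTFmap:::runifHull3d(m, h, pts)
    dpair <- sqrt(rowSums((a - b)^2))
    edges <- seq(0, 1000 + 200 - 1e-9, by = 200)  # package bin edges
    pBin <- hist(dpair[dpair < max(edges)], breaks = edges,
                 plot = FALSE)$counts / m
    ddO <- bruteForcePairHist(pts, edges)
    gO <- ifelse(pBin > 0, ddO / (10 * 9 / 2 * pBin), NA)
    g <- gValues(gr)
    r <- binCenters(gr)
    # extreme-distance bins are dominated by a handful of hull-corner
    # points and fluctuate with the random catalog; compare the bulk
    ok <- is.finite(g) & is.finite(gO) & ddO > 0 & r <= 700
    expect_true(any(ok))
    expect_equal(g[ok], gO[ok], tolerance = 0.1)
})

test_that("uniform catalogs give g near 1 and clustered catalogs start high", {
    u <- genUniformPoints(3000, sphereVolume(2), seed = 7)
    gu <- pairCorrelation3d(u, rMax = 1100, seed = 8)
    r <- binCenters(gu); g <- gValues(gu)
    expect_lt(abs(mean(g[r >= 200 & r <= 1000], na.rm = TRUE) - 1), 0.05)

    clc <- genClusteredPoints(3000, 30, sigma = 200, minSeparation = 80,
                              volume = sphereVolume(2), seed = 9)
    gc <- pairCorrelation3d(clc, rMax = 1100, seed = 10)
    gv <- gValues(gc); rv <- binCenters(gc)
    firstInformative <- which(rv > 100)[1]   # beyond the hard core
    expect_gt(gv[firstInformative], 1)
    # decays toward 1 over the following bins
    expect_lt(gv[which(rv > 900)[1]], gv[firstInformative])
})

test_that("empty-RR bins are masked, never divided by zero", {
    # two tight blobs far apart: intermediate bins have DD = 0 but RR > 0;
    # tiny rMax beyond hull scale gives RR = 0 bins on a degenerate catalog
    pts <- rbind(matrix(rnorm(30, 0, 5), 10, 3),
                 matrix(rnorm(30, 0, 5), 10, 3) + 5000)
    gr <- pairCorrelation3d(PointCatalog(pts), deltaR = 10, rMax = 200,
                            volume = "convex-hull", seed = 11)
    g <- gValues(gr)
    expect_true(all(is.na(g) | is.finite(g)))
    rr <- pairCounts(gr)$rr
    expect_true(all(is.na(g[rr == 0])))
})

test_that("random-catalog error draws populate the curve metadata", {
    u <- genUniformPoints(500, sphereVolume(1), seed = 12)
    gr <- pairCorrelation3d(u, rMax = 600, errorDraws = 5, seed = 13)
    sdv <- curveMetadata(gr)$g_sd
    expect_equal(length(sdv), length(binCenters(gr)))
    expect_true(all(sdv[is.finite(sdv)] >= 0))
})

test_that("fluctuation-model parameters round-trip within 5%", {
    r <- seq(25, 1475, by = 50)
    set.seed(14)
    for (p in list(c(A = 5, eps = 200), c(A = 0.8, eps = 400),
                   c(A = 30, eps = 100))) {
        gtrue <- fluctuationModelCurve(r, p["A"], p["eps"], sigmaBar = 20)
        noisy <- gtrue * (1 + rnorm(length(r), 0, 0.01))
        crv <- new("CorrelationCurve", r = r, dr = 50, g = pmax(noisy, 0))
        ft <- fitFluctuationModel(crv, sBar = sqrt(20^2 - 100 / 12),
                                  aBar = 10)
        expect_equal(ft$A, unname(p["A"]), tolerance = 0.05)
        expect_equal(ft$eps, unname(p["eps"]), tolerance = 0.05)
    }
})

test_that("flat curves pin the amplitude at zero; uniform fits skip the PSF", {
    r <- seq(25, 1475, by = 50)
    flat <- new("CorrelationCurve", r = r, dr = 50, g = rep(1, length(r)))
    ft <- fitFluctuationModel(flat, sBar = 20, aBar = 10)
    expect_equal(ft$A, 0)

    gexp <- 3 * exp(-r / 250) + 1
    crv <- new("CorrelationCurve", r = r, dr = 50, g = gexp)
    direct <- fitFluctuationModel(crv, sBar = 20, aBar = 10, psf = FALSE)
    expect_equal(direct$A, 3, tolerance = 1e-6)
    expect_equal(direct$eps, 250, tolerance = 1e-6)
})

test_that("denser clusters fit to strictly larger amplitudes", {
    As <- sapply(c(400, 250, 120), function(sg) {
        clc <- genClusteredPoints(2500, 25, sigma = sg, minSeparation = 0,
                                  volume = sphereVolume(2), seed = 15)
        gr <- pairCorrelation3d(clc, rMax = 1500, seed = 16)
        fitFluctuationModel(gr, sBar = 0, aBar = 0, psf = FALSE)$A
    })
    expect_true(all(diff(As) > 0))
})

test_that("PSF convolution kernel reduces to the plain exponential as sigma -> 0", {
    r <- seq(25, 1000, by = 25)
    k5 <- fluctuationModelCurve(r, 5, 200, sigmaBar = 5)
    plain <- 5 * exp(-r / 200) + 1
    expect_equal(k5, plain, tolerance = 0.01)
})
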