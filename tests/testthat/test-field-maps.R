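test_that("KDE maps integrate to 1 and peak where the points are", {
    pts <- matrix(c(4000, 4000, 4010, 3990), 2, 2, byrow = TRUE)
    m <- kdeIntensity(pts, grid = 100, bandwidth = 2,
                      xlim = c(0, 8000), ylim = c(0, 8000))
    v <- mapValues(m)
    expect_equal(sum(v) * pixelSize(m)^2, 1, tolerance = 1e-3)
    peak <- arrayInd(which.max(v), dim(v))
    expect_equal(as.vector(peak), c(50, 50), tolerance = 1)
    expect_equal(pixelSize(m), 80)
    expect_error(kdeIntensity(pts[1, , drop = FALSE]), "at least 2")
})

test_that("mask thresholding matches direct thresholding and rejects zero maps", {
    set.seed(1)
    v <- matrix(runif(400), 20, 20)
    mk <- makeMask(IntensityMap(v, 100), threshold = 0.2)
    expect_identical(mk, v / max(v) >= 0.2)
    expect_true(all(makeMask(v, threshold = 0)))
    expect_error(makeMask(matrix(0, 5, 5)), "all-zero")
})

test_that("channel normalisation recovers background and scales to [0, 1]", {
    expect_true(all(mapValues(normalizeChannel(matrix(7, 10, 10))) == 0))
    ramp <- matrix(seq(0, 1, length.out = 100), 10, 10)
    nr <- normalizeChannel(ramp, bgQuantile = 0)
    expect_equal(max(mapValues(nr)), 1)
    set.seed(2)
    img <- matrix(rnorm(10000, 50, 2), 100, 100)
    img[30:60, 30:60] <- img[30:60, 30:60] + 200
    bg <- attr(mapValues(normalizeChannel(img)), "background")
    expect_equal(bg, 50, tolerance = 0.05)
})

test_that("FFT masked correlation equals shift-and-sum on toy grids", {
    set.seed(3)
    I1 <- matrix(runif(256, 0.1, 1), 16, 16)
    I2 <- matrix(runif(256, 0.1, 1), 16, 16)
    mask <- matrix(TRUE, 16, 16); mask[1:3, ] <- FALSE; mask[, 15:16] <- FALSE
    cc <- crossCorrelation(IntensityMap(I1, 100), IntensityMap(I2, 100),
                           mask, minOverlapPx = 1)
    md <- curveMetadata(cc)
    bf <- bruteMaskedCorrelation(I1, I2, mask, md$lagsX, md$lagsY)
    expect_identical(is.na(md$map2d), is.na(bf))
    expect_lt(max(abs(md$map2d - bf), na.rm = TRUE), 1e-10)
})

test_that("correlation results are invariant to zero-padding outside the mask", {
    set.seed(4)
    I1 <- matrix(runif(144, 0.2, 1), 12, 12)
    mask <- matrix(FALSE, 12, 12); mask[3:10, 3:10] <- TRUE
    a <- crossCorrelation(IntensityMap(I1, 100), IntensityMap(I1, 100),
                          mask, minOverlapPx = 1)
    I1z <- I1; I1z[!mask] <- 0
    b <- crossCorrelation(IntensityMap(I1z, 100), IntensityMap(I1z, 100),
                          mask, minOverlapPx = 1)
    expect_equal(gValues(a), gValues(b), tolerance = 1e-12)
})

test_that("permutation preserves the in-mask histogram and flattens correlations", {
    pr <- genIntensityPair(1, nSites = 40, seed = 5)
    pm <- permuteWithinMask(pr$mapA, pr$mask, seed = 6)
    expect_equal(sort(mapValues(pm)[pr$mask]),
                 sort(mapValues(pr$mapA)[pr$mask]))
    expect_equal(mapValues(pm)[!pr$mask], mapValues(pr$mapA)[!pr$mask])
    expect_equal(mean(mapValues(pm)[pr$mask]),
                 mean(mapValues(pr$mapA)[pr$mask]))
    # permutation nulls of the correlation hover at 1
    g <- sapply(1:8, function(s) {
        p2 <- permuteWithinMask(pr$mapA, pr$mask, seed = s)
        cc <- crossCorrelation(pr$mapA, p2, pr$mask)
        mean(gValues(cc)[binCenters(cc) < 3000], na.rm = TRUE)
    })
    expect_lt(abs(mean(g) - 1), 0.05)
})

test_that("pixel correlation hits its analytic limits", {
    set.seed(7)
    v <- matrix(runif(2500), 50, 50)
    mask <- matrix(TRUE, 50, 50)
    expect_equal(pixelCorrelation(v, v, mask)$rho, 1)
    w <- matrix(runif(2500), 50, 50)
    expect_lt(abs(pixelCorrelation(v, w, mask)$rho), 0.1)
    q <- pixelCorrelation(v, w, mask)$quadrants
    expect_equal(sum(q), 1)
})

test_that("RFI follows its defining ratio", {
    img <- matrix(10, 12, 12)
    img[1:4, 1:4] <- 30; img[9:12, 9:12] <- 50
    het <- img == 30; sur <- img == 50; bg <- img == 10
    expect_equal(rfi(img, het, sur, bg), 0.5)
    expect_equal(rfi(img, sur, sur, bg), 1)
    expect_equal(rfi(img, bg, sur, bg), 0)
})

test_that("outline registration recovers translations exactly", {
    base <- matrix(0, 40, 40)
    base[10:25, 12:28] <- 1
    expect_equal(registerByOutline(base, base), c(dx = 0, dy = 0))
    shifted <- matrix(0, 40, 40)
    shifted[(10 + 7):(25 + 7), (12 - 3):(28 - 3)] <- 1
    # shift to apply to B to align with A is the negative of the injection
    expect_equal(registerByOutline(base, shifted), c(dx = -7, dy = 3))
})
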