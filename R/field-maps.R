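#' Kernel-density intensity map of 2D localizations
#'
#' Renders point localizations to a smooth intensity map by 2D Gaussian
#' kernel density estimation on a square grid (default 100 x 100, kernel
#' S.D. 2 grid units). The density integrates to 1 over the field before
#' any rescaling; physical pixel size is the field edge divided by the grid
#' size.
#'
#' @param points2d n x 2 matrix of x/y positions, nm.
#' @param grid grid size (grid x grid pixels).
#' @param bandwidth kernel S.D. in grid units.
#' @param xlim,ylim field limits, nm; must span equal extents. Default:
#'   square bounding box of the data padded by 3 bandwidths.
#' @return an [IntensityMap-class]; rows index x, columns y. The density is
#'   evaluated at pixel centers (i - 0.5) * pixelSize, so
#'   sum(values) * pixelSize^2 is 1 up to kernel mass outside the field.
#' @examples
#' pts <- matrix(runif(200, 0, 16000), ncol = 2)
#' kdeIntensity(pts, xlim = c(0, 16000), ylim = c(0, 16000))
#' @importFrom stats dnorm
#' @export
kdeIntensity <- function(points2d, grid = 100, bandwidth = 2,
                         xlim = NULL, ylim = NULL) {
    points2d <- as.matrix(points2d)
    if (nrow(points2d) < 2) stop("need at least 2 points")
    if (is.null(xlim) || is.null(ylim)) {
        ctr <- c(mean(range(points2d[, 1])), mean(range(points2d[, 2])))
        half <- max(diff(range(points2d[, 1])), diff(range(points2d[, 2]))) / 2
        half <- half * (1 + 6 * bandwidth / grid)
        xlim <- ctr[1] + c(-half, half)
        ylim <- ctr[2] + c(-half, half)
    }
    if (abs(diff(xlim) - diff(ylim)) > 1e-6)
        stop("xlim and ylim must span equal extents (square pixels)")
    px <- diff(xlim) / grid
    bwNm <- bandwidth * px
    xc <- xlim[1] + (seq_len(grid) - 0.5) * px
    yc <- ylim[1] + (seq_len(grid) - 0.5) * px
    # separable Gaussian product kernel, averaged over points
    A <- dnorm(outer(xc, points2d[, 1], "-"), sd = bwNm)
    B <- dnorm(outer(yc, points2d[, 2], "-"), sd = bwNm)
    z <- (A %*% t(B)) / nrow(points2d)
    IntensityMap(pmax(z, 0), pixelSize = px)
}

#' Binary mask from an intensity map
#'
#' Mask = pixels whose max-normalised intensity reaches the threshold
#' (default 0.2), the rule used both to outline the nucleus and to define
#' enriched regions.
#'
#' @param map an [IntensityMap-class] or numeric matrix.
#' @param threshold cutoff on the max-normalised intensity.
#' @return logical matrix of the same shape.
#' @export
makeMask <- function(map, threshold = 0.2) {
    v <- if (is(map, "IntensityMap")) mapValues(map) else as.matrix(map)
    m <- max(v)
    if (m <= 0) stop("cannot threshold an all-zero map")
    v / m >= threshold
}

#' Background-subtract and max-normalise an image channel
#'
#' Subtracts a background level and divides by the resulting maximum,
#' mapping the channel to [0, 1]. The default background estimate is the
#' median pixel intensity, unbiased as long as signal covers less than
#' half the frame; pass a lower quantile for signal-dense images. A
#' constant image becomes all zeros.
#'
#' @param image numeric matrix.
#' @param pixelSize pixel edge, nm.
#' @param bgQuantile quantile used as the background estimate.
#' @return an [IntensityMap-class]; the estimated background is attached
#'   as attribute `background` on the values.
#' @importFrom stats quantile
#' @export
normalizeChannel <- function(image, pixelSize = 160, bgQuantile = 0.5) {
    image <- as.matrix(image)
    bg <- quantile(image, bgQuantile, names = FALSE)
    v <- pmax(image - bg, 0)
    m <- max(v)
    if (m > 0) v <- v / m
    out <- IntensityMap(v, pixelSize = pixelSize)
    attr(out@values, "background") <- bg
    out
}

# FFT-based masked correlation on zero-padded arrays. Returns the full 2D
# correlation (fftshifted) plus the mask-overlap normalisation map.
maskedCorrelation2d <- function(V1, V2, mask, minOverlapPx = 16) {
    stopifnot(all(dim(V1) == dim(V2)), all(dim(V1) == dim(mask)))
    if (!any(mask)) stop("mask is empty")
    rho1 <- mean(V1[mask]); rho2 <- mean(V2[mask])
    if (rho1 <= 0 || rho2 <= 0) stop("zero mean intensity inside the mask")
    n1 <- nrow(V1); n2 <- ncol(V1)
    P1 <- 2 * n1; P2 <- 2 * n2      # zero-pad to avoid circular wrap-around
    pad <- function(M) { out <- matrix(0, P1, P2); out[1:n1, 1:n2] <- M; out }
    A <- pad(V1 * mask); B <- pad(V2 * mask); Mk <- pad(mask * 1)
    FA <- fft(A); FB <- fft(B); FM <- fft(Mk)
    corr <- Re(fft(FA * Conj(FB), inverse = TRUE)) / (P1 * P2)
    Nmap <- Re(fft(FM * Conj(FM), inverse = TRUE)) / (P1 * P2)
    c2d <- ifelse(Nmap >= minOverlapPx, corr / (rho1 * rho2 * Nmap), NA_real_)
    # center zero lag: index shift k -> lag ((k-1+P/2) mod P) - P/2
    shift <- function(M) {
        i <- c((P1 / 2 + 1):P1, 1:(P1 / 2))
        j <- c((P2 / 2 + 1):P2, 1:(P2 / 2))
        M[i, j]
    }
    lagsX <- seq(-P1 / 2, P1 / 2 - 1)
    lagsY <- seq(-P2 / 2, P2 / 2 - 1)
    list(c2d = shift(c2d), Nmap = shift(Nmap), lagsX = lagsX, lagsY = lagsY,
         rho1 = rho1, rho2 = rho2)
}

#' Masked FFT cross-correlation of two intensity maps
#'
#' Computes c(r) = Re\{FFT^-1(FFT(I1) conj(FFT(I2)))\} / (rho1 rho2 N(r))
#' with N(r) = FFT^-1(|FFT(mask)|^2), the autocorrelation of the nucleus
#' mask, on arrays zero-padded to twice the linear size (so the circular
#' FFT implements the linear correlation and the mask normalisation is
#' exact). The 2D correlation is angularly averaged in radial bins of one
#' pixel. Two spatially unrelated maps give c = 1 at every r; a clustered
#' map correlated with itself starts above 1 and converges to 1 at large
#' r. Values are reported for r above the pixel scale, where the
#' diffraction/rendering scale no longer dominates.
#'
#' @param I1,I2 [IntensityMap-class] objects (or matrices) of equal shape;
#'   pass the same object twice for an autocorrelation.
#' @param mask logical matrix, TRUE inside the nucleus.
#' @param rMaxNm largest radius reported, nm.
#' @param rMinNm smallest radius reported; defaults to the pixel size.
#' @param minOverlapPx lags whose mask overlap has fewer pixels are
#'   undefined (NA) rather than noisily normalised.
#' @return a [CorrelationCurve-class]; metadata holds the full shifted 2D
#'   correlation (`map2d`), its lags in pixels, the overlap map and the
#'   surface densities.
#' @examples
#' pr <- genIntensityPair(0, nSites = 12, seed = 1)
#' cc <- crossCorrelation(pr$mapA, pr$mapB, pr$mask)
#' @export
crossCorrelation <- function(I1, I2, mask, rMaxNm = NULL, rMinNm = NULL,
                             minOverlapPx = 16) {
    px <- if (is(I1, "IntensityMap")) pixelSize(I1) else 160
    V1 <- if (is(I1, "IntensityMap")) mapValues(I1) else as.matrix(I1)
    V2 <- if (is(I2, "IntensityMap")) mapValues(I2) else as.matrix(I2)
    cc <- maskedCorrelation2d(V1, V2, mask, minOverlapPx = minOverlapPx)
    rPx <- sqrt(outer(cc$lagsX^2, cc$lagsY^2, "+"))
    rNm <- rPx * px
    if (is.null(rMinNm)) rMinNm <- px
    if (is.null(rMaxNm)) rMaxNm <- max(rNm) / 2
    edges <- seq(0, rMaxNm + px, by = px)
    centers <- edges[-length(edges)] + px / 2
    bin <- findInterval(rNm, edges, rightmost.closed = FALSE)
    ok <- is.finite(cc$c2d) & bin >= 1 & bin <= length(centers)
    sums <- tapply(cc$c2d[ok], bin[ok], mean)
    g <- rep(NA_real_, length(centers))
    g[as.integer(names(sums))] <- sums
    keep <- centers > rMinNm
    new("CorrelationCurve", r = centers[keep], dr = px,
        g = as.numeric(g[keep]), dd = numeric(0), rr = numeric(0),
        n = sum(mask), nr = 0,
        metadata = list(map2d = cc$c2d, lagsX = cc$lagsX, lagsY = cc$lagsY,
                        overlap = cc$Nmap, rho1 = cc$rho1, rho2 = cc$rho2,
                        pixelSizeNm = px))
}

#' Permute pixels within a mask
#'
#' Randomises pixel values spatially inside the mask (outside untouched):
#' the permutation null for map correlations. The intensity histogram and
#' the mean inside the mask are preserved exactly.
#'
#' @param map an [IntensityMap-class] or matrix.
#' @param mask logical matrix.
#' @param seed integer seed.
#' @return same type as `map`.
#' @export
permuteWithinMask <- function(map, mask, seed = NULL) {
    isMap <- is(map, "IntensityMap")
    v <- if (isMap) mapValues(map) else as.matrix(map)
    idx <- which(mask)
    v[idx] <- withSeed(seed, v[sample(idx)])
    if (isMap) IntensityMap(v, pixelSize(map)) else v
}

#' Pixel-wise intensity correlation between two channels
#'
#' Pearson correlation of per-pixel intensities of two max-normalised
#' channels inside a mask, excluding background pixels (both channels
#' below the gate), plus the fraction of mask pixels falling in each
#' intensity quadrant at the gate. Segregated channels give rho near or
#' below 0; co-localised channels approach 1.
#'
#' @param I1,I2 [IntensityMap-class] or matrices of equal shape.
#' @param mask logical matrix.
#' @param backgroundGate gate on the max-normalised intensity; pixels low
#'   in both channels are background.
#' @return list: `rho`, `n` (pixels used), `quadrants` (fractions of mask
#'   pixels: low_low, high_low, low_high, high_high).
#' @importFrom stats cor
#' @export
pixelCorrelation <- function(I1, I2, mask, backgroundGate = 0.2) {
    v1 <- if (is(I1, "IntensityMap")) mapValues(I1) else as.matrix(I1)
    v2 <- if (is(I2, "IntensityMap")) mapValues(I2) else as.matrix(I2)
    a <- v1[mask]; b <- v2[mask]
    if (max(a) > 0) a <- a / max(a)
    if (max(b) > 0) b <- b / max(b)
    bgd <- a < backgroundGate & b < backgroundGate
    quad <- c(low_low = mean(bgd),
              high_low = mean(a >= backgroundGate & b < backgroundGate),
              low_high = mean(a < backgroundGate & b >= backgroundGate),
              high_high = mean(a >= backgroundGate & b >= backgroundGate))
    use <- !bgd
    rho <- if (sum(use) > 2) cor(a[use], b[use]) else NA_real_
    list(rho = rho, n = sum(use), quadrants = quad)
}

#' Relative fluorescence intensity of a region
#'
#' RFI = (I_region - I_background) / (I_surround - I_background), the
#' background-corrected mean intensity of a region of interest relative to
#' its surroundings; 1 means no depletion or enrichment, 0 means the
#' region sits at background.
#'
#' @param image numeric matrix (or [IntensityMap-class]).
#' @param regionMask,surroundMask,backgroundMask logical matrices selecting
#'   the region of interest, its surroundings and a background area.
#' @return the RFI value.
#' @examples
#' img <- matrix(10, 10, 10); img[1:3, 1:3] <- 30; img[6:9, 6:9] <- 50
#' rfi(img, img == 30, img == 50, img == 10)   # 0.5
#' @export
rfi <- function(image, regionMask, surroundMask, backgroundMask) {
    v <- if (is(image, "IntensityMap")) mapValues(image) else as.matrix(image)
    iR <- mean(v[regionMask]); iS <- mean(v[surroundMask])
    iB <- mean(v[backgroundMask])
    if (iS == iB) stop("surround and background intensities coincide")
    (iR - iB) / (iS - iB)
}

#' Rigid registration of two maps by nucleus outline
#'
#' Aligns two images by their thresholded nucleus masks: the integer
#' translation maximising the mask cross-correlation (FFT on zero-padded
#' arrays). Identical outlines give a zero shift; a pure translation is
#' recovered exactly.
#'
#' @param mapA,mapB [IntensityMap-class] or matrices of equal shape.
#' @param threshold mask threshold on the max-normalised intensity.
#' @return integer c(dx, dy): shift (in pixels, row/col) to apply to
#'   `mapB` to align it to `mapA`.
#' @export
registerByOutline <- function(mapA, mapB, threshold = 0.2) {
    mA <- makeMask(mapA, threshold)
    mB <- makeMask(mapB, threshold)
    n1 <- nrow(mA); n2 <- ncol(mA)
    P1 <- 2 * n1; P2 <- 2 * n2
    pad <- function(M) { out <- matrix(0, P1, P2); out[1:n1, 1:n2] <- M; out }
    corr <- Re(fft(fft(pad(mA * 1)) * Conj(fft(pad(mB * 1))),
                   inverse = TRUE)) / (P1 * P2)
    k <- arrayInd(which.max(corr), dim(corr))
    toLag <- function(idx, P) { l <- idx - 1; if (l >= P / 2) l - P else l }
    c(dx = toLag(k[1], P1), dy = toLag(k[2], P2))
}
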