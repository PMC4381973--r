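#' Local neighbour counts (canopy density)
#'
#' Number of other catalog points within a fixed canopy radius of each
#' point; the colour scale of 3D site-density maps. Computed with a
#' cell-list index; exact (no approximation).
#'
#' @param catalog a [PointCatalog-class] (>= 1 point).
#' @param radius canopy radius, nm (default 400).
#' @return integer vector, one count per point (a single point gives 0).
#' @examples
#' cl <- genUniformPoints(500, sphereVolume(2), seed = 1)
#' summary(neighborDensity(cl))
#' @export
neighborDensity <- function(catalog, radius = 400) {
    P <- coords(catalog)
    if (nrow(P) < 1) stop("catalog must contain at least one point")
    radius <- checkPositive(radius, "radius")
    as.integer(cpp_neighbor_count(P, radius))
}

#' 3D pair-correlation function of a point catalog
#'
#' Pair-count estimator of g(r): non-redundant pairwise distances of the
#' data are histogrammed into half-open bins of width `deltaR` (DD), the
#' same is done for a random catalog `randomFactor` times larger drawn
#' uniform in the catalog's volume (RR), and
#' g(r) = \[NR(NR-1) / (N(N-1))\] DD(r) / RR(r),
#' the pair-count normalisation under which complete spatial randomness
#' gives g = 1 at every r. Clustered catalogs start well above 1 and decay
#' toward 1. Bins where RR = 0 are undefined and carry NA (never a division
#' by zero).
#'
#' The random catalog is drawn in the sphere declared on the catalog when
#' present (exact geometry, no hull bias); otherwise uniform in the 3D
#' convex hull of the data ([convexHull3d()]).
#'
#' @param catalog a [PointCatalog-class] with >= 2 points.
#' @param deltaR bin width, nm (default 50).
#' @param randomFactor random-catalog size as a multiple of the data size
#'   (default 10).
#' @param rMax largest separation histogrammed, nm.
#' @param volume "declared" (use the catalog's sphere, falling back to the
#'   hull), "convex-hull" (force the hull), or a [NuclearVolume-class]
#'   sphere to use explicitly.
#' @param errorDraws if > 0, the random catalog is redrawn this many times
#'   and the per-bin S.D. of g across draws is stored in the curve
#'   metadata as `g_sd`.
#' @param seed integer seed for the random catalog.
#' @return a [CorrelationCurve-class] with bin centers at
#'   deltaR/2, 3 deltaR/2, ...
#' @examples
#' cl <- genUniformPoints(2000, sphereVolume(2), seed = 1)
#' gr <- pairCorrelation3d(cl, seed = 2)
#' @export
pairCorrelation3d <- function(catalog, deltaR = 50, randomFactor = 10,
                              rMax = 1500, volume = "declared",
                              errorDraws = 0, seed = NULL) {
    P <- coords(catalog)
    N <- nrow(P)
    if (N < 2) stop("need at least 2 points")
    deltaR <- checkPositive(deltaR, "deltaR")
    edges <- seq(0, rMax + deltaR - 1e-9, by = deltaR)
    centers <- edges[-length(edges)] + deltaR / 2
    dd <- as.numeric(cpp_pair_count(P, edges))

    vol <- NULL
    if (is(volume, "NuclearVolume")) vol <- volume
    else if (identical(volume, "declared")) vol <- nuclearVolume(catalog)
    else if (!identical(volume, "convex-hull"))
        stop("volume must be 'declared', 'convex-hull' or a NuclearVolume")
    useSphere <- !is.null(vol) && vol@shape == "sphere"
    hull <- if (!useSphere) convexHull3d(P) else NULL

    NR <- as.integer(randomFactor * N)
    drawRR <- function() {
        rand <- if (useSphere) runifSphere(NR, vol@radius, vol@center)
                else runifHull3d(NR, hull, P)
        as.numeric(cpp_pair_count(rand, edges))
    }
    norm <- (NR * (NR - 1)) / (N * (N - 1))
    res <- withSeed(seed, {
        rr <- drawRR()
        gs <- NULL
        if (errorDraws > 0) {
            gs <- vapply(seq_len(errorDraws), function(i) {
                rrI <- drawRR()
                ifelse(rrI > 0, norm * dd / rrI, NA_real_)
            }, numeric(length(dd)))
        }
        list(rr = rr, gs = gs)
    })
    g <- ifelse(res$rr > 0, norm * dd / res$rr, NA_real_)
    meta <- list(seed = seed, randomFactor = randomFactor,
                 volume = if (useSphere) "sphere" else "convex-hull",
                 volumeNm3 = if (useSphere) (4 / 3) * pi * vol@radius^3
                             else hull$volume)
    if (!is.null(res$gs))
        meta$g_sd <- apply(res$gs, 1, stats::sd, na.rm = TRUE)
    new("CorrelationCurve", r = centers, dr = deltaR, g = as.numeric(g),
        dd = dd, rr = res$rr, n = N, nr = NR, metadata = meta)
}

#' Forward fluctuation-model curve
#'
#' The model pair-correlation of randomly placed clusters with no defined
#' shape, optionally blurred by the imaging PSF:
#' without blur G(r) = A exp(-r/eps) + 1; with blur the exponential term is
#' convolved (3D, isotropic) with the PSF pair-correlation
#' G_PSF(r) = exp(-r^2 / 4 sigmaBar^2) / (8 pi^(3/2) sigmaBar^3), a
#' unit-mass kernel, so the baseline 1 is preserved. `sigmaBar` is the
#' effective localization S.D., sigmaBar^2 = sBar^2 + aBar^2/12 for PSF
#' S.D. sBar and voxel size aBar. A is the fluctuation amplitude
#' (proportional to the in-cluster density enrichment), eps the fluctuation
#' range (proportional to cluster size).
#'
#' @param r separations, nm.
#' @param A fluctuation amplitude (>= 0).
#' @param eps fluctuation range, nm (> 0).
#' @param sigmaBar effective PSF S.D., nm; 0 skips the convolution.
#' @return model values at `r`.
#' @examples
#' fluctuationModelCurve(seq(25, 1000, 50), A = 5, eps = 200, sigmaBar = 20)
#' @export
fluctuationModelCurve <- function(r, A, eps, sigmaBar = 0) {
    if (sigmaBar <= 0) return(A * exp(-r / eps) + 1)
    1 + A * expPsfConvolution(r, eps, sigmaBar)
}

# 3D isotropic convolution of exp(-s/eps) with the Gaussian PSF
# pair-correlation kernel, reduced to a 1D integral:
# K(r) = 1/(2 sqrt(pi) sigma r) * Int_0^inf s exp(-s/eps)
#        [exp(-(r-s)^2/4sigma^2) - exp(-(r+s)^2/4sigma^2)] ds
# (exact radial form of the spherical convolution; K -> exp(-r/eps) as
# sigma -> 0). Evaluated by trapezoid quadrature on an adaptive grid.
expPsfConvolution <- function(r, eps, sigma) {
    smax <- max(r) + 8 * sigma + 20 * eps
    npts <- min(2e5, max(4000, ceiling(4 * smax / sigma)))
    s <- seq(0, smax, length.out = npts)
    ds <- s[2] - s[1]
    base <- s * exp(-s / eps)
    vapply(r, function(ri) {
        if (ri <= 0) ri <- 1e-6
        integ <- base * (exp(-(ri - s)^2 / (4 * sigma^2)) -
                         exp(-(ri + s)^2 / (4 * sigma^2)))
        sum(integ) * ds / (2 * sqrt(pi) * sigma * ri)
    }, numeric(1))
}

#' Fit the fluctuation model to a pair-correlation curve
#'
#' Least-squares fit of G(r) = (A exp(-r/eps) + 1) convolved with the PSF
#' pair-correlation (Levenberg-Marquardt trust region), yielding the
#' fluctuation amplitude A and range eps. The stochastic
#' repeat-localization term is taken as zero: stable sites are counted
#' once, at the average localization over their frames. For uniform
#' (simulated) catalogs the exponential form is fitted directly without
#' the PSF convolution (`psf = FALSE`).
#'
#' @param curve a [CorrelationCurve-class] with >= 10 defined bins.
#' @param sBar average PSF S.D., nm.
#' @param aBar average voxel size, nm.
#' @param psf convolve with the PSF kernel? (FALSE fits the plain
#'   exponential.)
#' @param rRange optional c(min, max) nm restricting the fitted bins.
#' @return object of class `FluctuationFit`: list with A, eps, sigmaBar,
#'   ci (95\% intervals), converged, fitted, r.
#' @examples
#' r <- seq(25, 1475, 50)
#' g <- fluctuationModelCurve(r, A = 5, eps = 200, sigmaBar = 20)
#' crv <- new("CorrelationCurve", r = r, dr = 50, g = g)
#' fitFluctuationModel(crv, sBar = 19, aBar = 10)
#' @importFrom minpack.lm nlsLM nls.lm.control
#' @importFrom stats coef confint predict
#' @export
fitFluctuationModel <- function(curve, sBar, aBar, psf = TRUE,
                                rRange = NULL) {
    r <- binCenters(curve); g <- gValues(curve)
    ok <- is.finite(g) & r > 0
    if (!is.null(rRange)) ok <- ok & r >= rRange[1] & r <= rRange[2]
    r <- r[ok]; g <- g[ok]
    if (length(r) < 10) stop("need at least 10 defined bins")
    sigmaBar <- if (psf) sqrt(sBar^2 + aBar^2 / 12) else 0

    # flat curves: amplitude pinned at zero
    if (max(g) - 1 < 0.02) {
        out <- list(A = 0, eps = NA_real_, sigmaBar = sigmaBar,
                    ci = NULL, converged = TRUE, fitted = rep(1, length(r)),
                    r = r, pinned = TRUE)
        class(out) <- "FluctuationFit"
        return(out)
    }
    A0 <- max(max(g) - 1, 0.05)
    # eps from where the excess decays to 1/e of its peak
    excess <- g - 1
    below <- which(excess < excess[which.max(excess)] / exp(1))
    eps0 <- if (length(below)) max(r[below[1]], 25) else max(r) / 3
    fit <- tryCatch(
        nlsLM(g ~ fluctuationModelCurve(r, A, eps, sigmaBar),
              data = data.frame(r = r, g = g),
              start = list(A = A0, eps = eps0),
              lower = c(A = 0, eps = 1),
              control = nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
    if (is.null(fit)) {
        out <- list(A = NA_real_, eps = NA_real_, sigmaBar = sigmaBar,
                    ci = NULL, converged = FALSE, fitted = NULL, r = r)
        class(out) <- "FluctuationFit"
        return(out)
    }
    cf <- coef(fit)
    ci <- tryCatch(suppressWarnings(suppressMessages(
                       confint(fit, level = 0.95))),
                   error = function(e) NULL)
    out <- list(A = unname(cf["A"]), eps = unname(cf["eps"]),
                sigmaBar = sigmaBar, ci = ci, converged = TRUE,
                fitted = predict(fit), r = r, pinned = FALSE)
    class(out) <- "FluctuationFit"
    out
}

#' @export
print.FluctuationFit <- function(x, ...) {
    if (!isTRUE(x$converged)) {
        cat("FluctuationFit: did not converge\n")
        return(invisible(x))
    }
    cat(sprintf("FluctuationFit: A = %.3g, eps = %.4g nm (sigmaBar = %.3g nm)\n",
                x$A, x$eps, x$sigmaBar))
    invisible(x)
}
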