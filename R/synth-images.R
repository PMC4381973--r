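#' Render a 3D spot image stack from the Gaussian PSF forward model
#'
#' Evaluates the 3D Gaussian point-spread-function model
#' I(x,y,z) = A0 exp(-(x-x0)^2/2s_xy^2) exp(-(y-y0)^2/2s_xy^2)
#' exp(-(z-z0)^2/2s_z^2) + B at voxel centers for each spot and, optionally,
#' replaces expected counts with Poisson draws (shot noise). Voxel centers
#' sit at (index - 0.5) * voxelSize with the stack corner as origin, the
#' same convention the fitter uses.
#'
#' @param positions k x 3 matrix of true spot positions, nm.
#' @param dims integer c(nx, ny, nz) voxels.
#' @param psfSigma c(xy, z) Gaussian S.D. of the PSF, nm.
#' @param amplitude peak amplitude A0, photons.
#' @param background constant background B, photons per voxel.
#' @param voxelSize c(ax, ay, az) voxel edge, nm (default isotropic 100 nm,
#'   as in bead PSF calibration stacks).
#' @param noise add Poisson noise on the expected counts?
#' @param seed integer seed (noise only).
#' @return a list: `stack` (nx x ny x nz array of counts), `truth`
#'   (positions and parameters used), `voxelSize`.
#' @examples
#' st <- genSpotStack(matrix(c(800, 700, 900), 1), dims = c(15, 15, 15),
#'                    noise = FALSE)
#' @export
genSpotStack <- function(positions, dims = c(15, 15, 15),
                         psfSigma = c(xy = 150, z = 350),
                         amplitude = 100, background = 5,
                         voxelSize = c(100, 100, 100),
                         noise = TRUE, seed = NULL) {
    positions <- matrix(as.numeric(positions), ncol = 3)
    if (amplitude < 0 || background < 0) stop("negative parameters rejected")
    if (any(psfSigma <= 0) || any(voxelSize <= 0))
        stop("psfSigma and voxelSize must be positive")
    xc <- (seq_len(dims[1]) - 0.5) * voxelSize[1]
    yc <- (seq_len(dims[2]) - 0.5) * voxelSize[2]
    zc <- (seq_len(dims[3]) - 0.5) * voxelSize[3]
    expected <- array(background, dim = dims)
    for (s in seq_len(nrow(positions))) {
        gx <- exp(-(xc - positions[s, 1])^2 / (2 * psfSigma[[1]]^2))
        gy <- exp(-(yc - positions[s, 2])^2 / (2 * psfSigma[[1]]^2))
        gz <- exp(-(zc - positions[s, 3])^2 / (2 * psfSigma[[2]]^2))
        expected <- expected + amplitude * (gx %o% gy %o% gz)
    }
    stack <- if (noise) {
        withSeed(seed, array(rpois(length(expected), expected), dim = dims))
    } else expected
    list(stack = stack,
         truth = list(positions = positions, psfSigma = psfSigma,
                      amplitude = amplitude, background = background),
         voxelSize = voxelSize)
}

#' Paired intensity maps with controlled co-localization
#'
#' Builds two 2D point sets that share a given fraction of cluster centers
#' (the rest private to each channel), renders both to intensity maps by
#' kernel density estimation inside a circular nucleus, and returns the
#' nucleus mask. At `colocalization = 1` the two maps share every cluster
#' (pixel correlation near 1); at 0 the channels are spatially independent
#' and their cross-correlation is flat at 1.
#'
#' @param colocalization fraction of shared cluster centers, in [0, 1].
#' @param nSites cluster centers per channel.
#' @param pointsPerSite localizations drawn per center.
#' @param clusterSigma in-plane cluster S.D., nm.
#' @param grid KDE grid size (grid x grid).
#' @param fieldNm field edge, nm (pixel size = fieldNm / grid).
#' @param nucleusRadiusFrac nucleus radius as a fraction of the field edge.
#' @param bandwidth KDE bandwidth in grid units.
#' @param seed integer seed.
#' @return list: `mapA`, `mapB` ([IntensityMap-class]), `mask` (logical
#'   matrix), `truth` (center coordinates, shared flags).
#' @examples
#' pair <- genIntensityPair(0.5, nSites = 10, seed = 1)
#' @export
genIntensityPair <- function(colocalization, nSites = 40, pointsPerSite = 60,
                             clusterSigma = 250, grid = 100, fieldNm = 16000,
                             nucleusRadiusFrac = 0.4, bandwidth = 2,
                             seed = NULL) {
    if (colocalization < 0 || colocalization > 1)
        stop("colocalization must be in [0, 1]")
    nShared <- round(colocalization * nSites)
    center <- c(fieldNm, fieldNm) / 2
    nucR <- nucleusRadiusFrac * fieldNm
    # centers extend one cluster/kernel width beyond the mask so the
    # intensity process is stationary within it (no dim rim that would
    # bias the mask-normalised correlation)
    margin <- 2 * clusterSigma + 2 * bandwidth * fieldNm / grid
    drawR <- nucR + margin

    withSeed(seed, {
        drawCenters <- function(k) {
            out <- matrix(NA_real_, k, 2); got <- 0
            while (got < k) {
                cand <- matrix(runif(2 * 2 * k, -drawR, drawR), ncol = 2)
                keep <- rowSums(cand^2) <= drawR^2
                take <- min(sum(keep), k - got)
                if (take > 0) {
                    out[(got + 1):(got + take), ] <-
                        cand[keep, , drop = FALSE][seq_len(take), ]
                    got <- got + take
                }
            }
            sweep(out, 2, center, "+")
        }
        shared <- drawCenters(nShared)
        privA <- drawCenters(nSites - nShared)
        privB <- drawCenters(nSites - nShared)
        centersA <- rbind(shared, privA)
        centersB <- rbind(shared, privB)
        scatter <- function(centers) {
            idx <- rep(seq_len(nrow(centers)), each = pointsPerSite)
            centers[idx, , drop = FALSE] +
                matrix(rnorm(length(idx) * 2, sd = clusterSigma), ncol = 2)
        }
        ptsA <- scatter(centersA)
        ptsB <- scatter(centersB)
        mapA <- kdeIntensity(ptsA, grid = grid, bandwidth = bandwidth,
                             xlim = c(0, fieldNm), ylim = c(0, fieldNm))
        mapB <- kdeIntensity(ptsB, grid = grid, bandwidth = bandwidth,
                             xlim = c(0, fieldNm), ylim = c(0, fieldNm))
        px <- fieldNm / grid
        cx <- (seq_len(grid) - 0.5) * px
        mask <- outer(cx, cx, function(a, b)
            (a - center[1])^2 + (b - center[2])^2 <= nucR^2)
        list(mapA = mapA, mapB = mapB, mask = mask,
             truth = list(centersA = centersA, centersB = centersB,
                          nShared = nShared, nucleusRadiusNm = nucR))
    })
}
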