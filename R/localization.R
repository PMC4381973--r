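#' Fit a 3D Gaussian PSF model to a spot subvolume
#'
#' Nonlinear least-squares fit of the model
#' I = A0 exp(-(x-x0)^2/2s_xy^2 - (y-y0)^2/2s_xy^2 - (z-z0)^2/2s_z^2) + B
#' to voxel counts (Levenberg-Marquardt). The x/y S.D. is shared, z is
#' fitted independently; the local background B is fitted per spot. Voxel
#' centers are at (index - 0.5) * voxelSize from the stack corner. Returns
#' the integrated photon count N (background-subtracted sum over voxels
#' within 3 sigma of the center) and tau = B / A0, the background-to-peak
#' ratio entering the localization-uncertainty estimator.
#'
#' @param subvolume 3D numeric array of voxel counts (>= 5 x 5 x 3).
#' @param voxelSize c(ax, ay, az) nm.
#' @param init optional named list of starting values (A0, x0, y0, z0,
#'   sigma_xy, sigma_z, B); defaults are seeded from the brightest voxel.
#' @param sigmaXyBounds,sigmaZBounds fit bounds on the S.D.s, nm.
#' @return an object of class `SpotFit`: list with A0, x0, y0, z0 (nm),
#'   sigma_xy, sigma_z (nm), B, N, tau, converged, residualNorm.
#' @examples
#' st <- genSpotStack(matrix(c(750, 750, 750), 1), noise = FALSE)
#' fitSpot(st$stack, st$voxelSize)
#' @importFrom minpack.lm nlsLM nls.lm.control
#' @importFrom stats coef resid
#' @export
fitSpot <- function(subvolume, voxelSize = c(100, 100, 100), init = NULL,
                    sigmaXyBounds = c(50, 500), sigmaZBounds = c(100, 1500)) {
    dims <- dim(subvolume)
    if (length(dims) != 3 || dims[1] < 5 || dims[2] < 5 || dims[3] < 3)
        stop("subvolume must be a 3D array of at least 5 x 5 x 3 voxels")
    xc <- (seq_len(dims[1]) - 0.5) * voxelSize[1]
    yc <- (seq_len(dims[2]) - 0.5) * voxelSize[2]
    zc <- (seq_len(dims[3]) - 0.5) * voxelSize[3]
    gridc <- expand.grid(x = xc, y = yc, z = zc)
    I <- as.numeric(subvolume)

    peak <- arrayInd(which.max(subvolume), dims)
    start <- list(A0 = max(I) - min(I), x0 = xc[peak[1]], y0 = yc[peak[2]],
                  z0 = zc[peak[3]], sxy = 150, sz = 350, B = min(I))
    if (!is.null(init)) {
        map <- c(A0 = "A0", x0 = "x0", y0 = "y0", z0 = "z0",
                 sigma_xy = "sxy", sigma_z = "sz", B = "B")
        for (nm in names(init)) if (nm %in% names(map)) start[[map[[nm]]]] <- init[[nm]]
    }
    start$A0 <- max(start$A0, 1e-3)
    start$sxy <- min(max(start$sxy, sigmaXyBounds[1]), sigmaXyBounds[2])
    start$sz <- min(max(start$sz, sigmaZBounds[1]), sigmaZBounds[2])

    fit <- tryCatch(
        nlsLM(I ~ A0 * exp(-(x - x0)^2 / (2 * sxy^2)
                           - (y - y0)^2 / (2 * sxy^2)
                           - (z - z0)^2 / (2 * sz^2)) + B,
              data = cbind(gridc, I = I), start = start,
              lower = c(A0 = 0, x0 = 0, y0 = 0, z0 = 0,
                        sxy = sigmaXyBounds[1], sz = sigmaZBounds[1],
                        B = 0),
              upper = c(A0 = Inf, x0 = max(xc) + voxelSize[1],
                        y0 = max(yc) + voxelSize[2],
                        z0 = max(zc) + voxelSize[3],
                        sxy = sigmaXyBounds[2], sz = sigmaZBounds[2],
                        B = Inf),
              control = nls.lm.control(maxiter = 200, ftol = 1e-12,
                                       ptol = 1e-12)),
        error = function(e) NULL)
    if (is.null(fit)) {
        out <- list(converged = FALSE)
        class(out) <- "SpotFit"
        return(out)
    }
    p <- as.list(coef(fit))
    within3s <- abs(gridc$x - p$x0) <= 3 * p$sxy &
                abs(gridc$y - p$y0) <= 3 * p$sxy &
                abs(gridc$z - p$z0) <= 3 * p$sz
    N <- sum(I[within3s] - p$B)
    out <- list(A0 = p$A0, x0 = p$x0, y0 = p$y0, z0 = p$z0,
                sigma_xy = p$sxy, sigma_z = p$sz, B = p$B,
                N = max(N, 0), tau = if (p$A0 > 0) p$B / p$A0 else Inf,
                converged = TRUE,
                residualNorm = sqrt(sum(resid(fit)^2)))
    class(out) <- "SpotFit"
    out
}

#' @export
print.SpotFit <- function(x, ...) {
    if (!isTRUE(x$converged)) {
        cat("SpotFit: did not converge\n")
        return(invisible(x))
    }
    cat(sprintf("SpotFit: pos (%.1f, %.1f, %.1f) nm, sigma_xy %.1f, sigma_z %.1f nm\n",
                x$x0, x$y0, x$z0, x$sigma_xy, x$sigma_z))
    cat(sprintf("  A0 %.2f, B %.2f, N %.0f photons, tau %.3f\n",
                x$A0, x$B, x$N, x$tau))
    invisible(x)
}

#' Photon-count localization-uncertainty estimator
#'
#' Per-axis localization uncertainty of a Gaussian-fitted spot:
#' Delta^2 = (sigma^2 + a^2/12) / N * (16/9 + 4 tau), with sigma the PSF
#' S.D. on that axis, a the voxel size on that axis, N the integrated
#' photon count and tau the background-to-peak intensity ratio. At tau = 0
#' this reduces to 16 (sigma^2 + a^2/12) / (9 N); the uncertainty vanishes
#' as N grows.
#'
#' @param sigma PSF S.D. per axis, nm (vectorised).
#' @param a voxel size per axis, nm.
#' @param N integrated photon count (> 0).
#' @param tau background-to-peak intensity ratio (>= 0).
#' @return uncertainty Delta per axis, nm.
#' @examples
#' localizationUncertainty(150, 100, 1000, 0.1)
#' @export
localizationUncertainty <- function(sigma, a, N, tau = 0) {
    if (any(N <= 0)) stop("N must be positive")
    if (any(tau < 0)) stop("tau must be non-negative")
    sqrt((sigma^2 + a^2 / 12) / N * (16 / 9 + 4 * tau))
}

#' Per-axis uncertainties for a fitted spot
#'
#' @param fit a `SpotFit` from [fitSpot()].
#' @param voxelSize c(ax, ay, az) nm.
#' @return named vector of Delta_x, Delta_y, Delta_z in nm.
#' @export
spotUncertainty <- function(fit, voxelSize = c(100, 100, 100)) {
    stopifnot(inherits(fit, "SpotFit"), isTRUE(fit$converged))
    c(x = localizationUncertainty(fit$sigma_xy, voxelSize[1], fit$N, fit$tau),
      y = localizationUncertainty(fit$sigma_xy, voxelSize[2], fit$N, fit$tau),
      z = localizationUncertainty(fit$sigma_z, voxelSize[3], fit$N, fit$tau))
}

#' Block-centroid drift correction
#'
#' Estimates stage drift as the displacement of the centroid of all
#' localizations in consecutive blocks of frames relative to the first
#' block, and subtracts it. Blocks without localizations carry the previous
#' displacement forward. With a frame interval supplied, datasets whose
#' block-to-block drift rate exceeds `maxDriftNmPerMin` are rejected
#' (heavily drifting acquisitions are not rescued, they are discarded).
#'
#' @param locs data.frame with frame, x_nm, y_nm, z_nm (z may be absent for
#'   2D data).
#' @param block block size in frames (default 50).
#' @param dt frame interval in s, used only for the drift-rate gate
#'   (NULL disables the gate).
#' @param maxDriftNmPerMin rejection threshold on the drift rate.
#' @return list: `locs` (corrected table), `trace` (data.frame with block,
#'   dx_nm, dy_nm, dz_nm; first block is zero by construction).
#' @examples
#' locs <- data.frame(frame = rep(1:100, each = 3),
#'                    x_nm = rnorm(300), y_nm = rnorm(300), z_nm = rnorm(300))
#' dc <- driftCorrect(locs, block = 50)
#' @export
driftCorrect <- function(locs, block = 50, dt = NULL,
                         maxDriftNmPerMin = 800) {
    stopifnot(all(c("frame", "x_nm", "y_nm") %in% names(locs)))
    has3d <- "z_nm" %in% names(locs) && !all(is.na(locs$z_nm))
    axes <- c("x_nm", "y_nm", if (has3d) "z_nm")
    blockIdx <- (locs$frame - min(locs$frame)) %/% block + 1
    nBlocks <- max(blockIdx)
    if (nBlocks < 2) stop("need at least 2 blocks of frames")

    disp <- matrix(0, nBlocks, length(axes),
                   dimnames = list(NULL, axes))
    ref <- colMeans(locs[blockIdx == 1, axes, drop = FALSE])
    prev <- rep(0, length(axes))
    for (b in seq_len(nBlocks)) {
        rows <- blockIdx == b
        disp[b, ] <- if (any(rows))
            colMeans(locs[rows, axes, drop = FALSE]) - ref else prev
        prev <- disp[b, ]
    }
    if (!is.null(dt)) {
        perBlockMin <- block * dt / 60
        rate <- max(sqrt(rowSums(diff(disp)^2))) / perBlockMin
        if (rate > maxDriftNmPerMin)
            stop(sprintf("drift rate %.0f nm/min exceeds %.0f nm/min; dataset rejected",
                         rate, maxDriftNmPerMin))
    }
    corrected <- locs
    for (j in seq_along(axes))
        corrected[[axes[j]]] <- locs[[axes[j]]] - disp[blockIdx, j]
    trace <- data.frame(block = seq_len(nBlocks),
                        dx_nm = disp[, "x_nm"], dy_nm = disp[, "y_nm"],
                        dz_nm = if (has3d) disp[, "z_nm"] else 0)
    list(locs = corrected, trace = trace)
}
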