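#' Split tracks at mask boundaries
#'
#' Cuts each trajectory wherever it crosses the mask boundary and labels
#' the fragments as inside or outside. Tracking itself is never redone:
#' splitting only partitions existing tracks, so fragment detections sum
#' exactly to the input detections. Fragments receive fresh ids; the
#' parent id is kept in `trackInfo()`.
#'
#' @param tracks a [TrackSet-class] (2D positions used).
#' @param mask logical matrix; pixel (i, j) spans
#'   x in \[(i-1), i\) * pixelSize, likewise y for j.
#' @param pixelSize mask pixel edge, nm.
#' @param origin c(x, y) of the mask corner, nm.
#' @return list of [TrackSet-class]: `inside`, `outside`.
#' @export
splitTracksByMask <- function(tracks, mask, pixelSize, origin = c(0, 0)) {
    d <- trackData(tracks)
    i <- floor((d$x_nm - origin[1]) / pixelSize) + 1
    j <- floor((d$y_nm - origin[2]) / pixelSize) + 1
    inField <- i >= 1 & i <= nrow(mask) & j >= 1 & j <= ncol(mask)
    inMask <- inField
    inMask[inField] <- mask[cbind(i[inField], j[inField])]

    newIn <- list(); newOut <- list()
    infoIn <- list(); infoOut <- list()
    nid <- 0L
    for (tid in unique(d$track_id)) {
        rows <- which(d$track_id == tid)
        state <- inMask[rows]
        runs <- rle(state)
        pos <- cumsum(c(1, runs$lengths))
        for (k in seq_along(runs$lengths)) {
            frag <- rows[pos[k]:(pos[k + 1] - 1)]
            nid <- nid + 1L
            seg <- d[frag, , drop = FALSE]
            seg$track_id <- nid
            info <- data.frame(track_id = nid, parent_id = tid)
            if (runs$values[k]) {
                newIn[[length(newIn) + 1]] <- seg
                infoIn[[length(infoIn) + 1]] <- info
            } else {
                newOut[[length(newOut) + 1]] <- seg
                infoOut[[length(infoOut) + 1]] <- info
            }
        }
    }
    toTS <- function(segs, infos) {
        if (!length(segs))
            return(TrackSet(data.frame(track_id = integer(0),
                                       frame = integer(0), x_nm = numeric(0),
                                       y_nm = numeric(0), z_nm = numeric(0)),
                            dt = frameInterval(tracks)))
        TrackSet(do.call(rbind, segs), dt = frameInterval(tracks),
                 trackInfo = do.call(rbind, infos))
    }
    list(inside = toTS(newIn, infoIn), outside = toTS(newOut, infoOut))
}

# time-averaged MSD of one track at the given integer lags
trackMsd <- function(P, lags) {
    vapply(lags, function(k) {
        n <- nrow(P)
        if (k >= n) return(NA_real_)
        diffs <- P[(k + 1):n, , drop = FALSE] - P[1:(n - k), , drop = FALSE]
        mean(rowSums(diffs^2))
    }, numeric(1))
}

#' Diffusion coefficients from MSD linear fits
#'
#' Per-track mean square displacement versus lag time, fitted linearly
#' over the first `nLags` lags (default 4, short lags limit correlation
#' between MSD points) and converted through MSD = 2 d D t, with d the
#' track dimensionality (2 or 3). Tracks shorter than `minFrames`
#' consecutive frames are skipped; fits with R^2 below `r2Min` are
#' reported but flagged unaccepted (the bound-population floor set by
#' localization noise is not corrected; see the package vignette).
#'
#' @param tracks a [TrackSet-class].
#' @param minFrames minimum consecutive frames per track (default 8).
#' @param r2Min acceptance threshold on the MSD fit R^2 (default 0.8).
#' @param nLags number of MSD lags fitted.
#' @return data.frame: track_id, D (um^2/s, floored at 0), r2, nPoints,
#'   accepted.
#' @examples
#' ts <- genBrownianTracks(1, dt = 0.01, nTracks = 10, nFrames = 20, seed = 1)
#' estimateD(ts)
#' @importFrom stats lm
#' @export
estimateD <- function(tracks, minFrames = 8, r2Min = 0.8, nLags = 4) {
    d <- trackData(tracks)
    dt <- frameInterval(tracks)
    has3d <- !all(is.na(d$z_nm))
    dim <- if (has3d) 3 else 2
    axes <- c("x_nm", "y_nm", if (has3d) "z_nm")
    out <- lapply(split(d, d$track_id), function(tr) {
        tr <- tr[order(tr$frame), ]
        # longest run of consecutive frames
        brk <- cumsum(c(0, diff(tr$frame) != 1))
        runs <- split(seq_len(nrow(tr)), brk)
        run <- runs[[which.max(lengths(runs))]]
        if (length(run) < minFrames) return(NULL)
        P <- as.matrix(tr[run, axes, drop = FALSE]) / 1000  # um
        lags <- seq_len(min(nLags, length(run) - 1))
        msd <- trackMsd(P, lags)
        fit <- lm(msd ~ I(lags * dt))
        slope <- coef(fit)[2]
        r2 <- summary(fit)$r.squared
        data.frame(track_id = tr$track_id[1],
                   D = max(slope / (2 * dim), 0), r2 = r2,
                   nPoints = length(lags),
                   accepted = is.finite(r2) && r2 >= r2Min)
    })
    res <- do.call(rbind, out)
    if (is.null(res))
        res <- data.frame(track_id = integer(0), D = numeric(0),
                          r2 = numeric(0), nPoints = integer(0),
                          accepted = logical(0))
    rownames(res) <- NULL
    res
}

#' Gaussian-mixture decomposition of a diffusion-coefficient histogram
#'
#' Fits a k-component Gaussian mixture to log10(D) (diffusion histograms
#' span decades, so components are Gaussian on the log axis) and reports
#' component means back-transformed to um^2/s with their weights. When
#' several k are supplied the best model by BIC is returned along with the
#' comparison table.
#'
#' @param D vector of diffusion coefficients, um^2/s (non-positive values
#'   are dropped before the log transform).
#' @param k number of components (2 or 3 typically); may be a vector.
#' @return object of class `MixtureFit`: list with `components`
#'   (data.frame meanD, sdLog10, weight, ordered by meanD), `k`, `logLik`,
#'   `bic`, `comparison` (k vs BIC), `degenerate` flag.
#' @examples
#' D <- c(10^rnorm(200, -1.8, 0.2), 10^rnorm(100, 0.1, 0.2))
#' dHistogramMixture(D, k = 2)
#' @importFrom mclust Mclust mclustBIC
#' @export
dHistogramMixture <- function(D, k = 2) {
    x <- log10(D[is.finite(D) & D > 0])
    if (length(x) < 10) stop("need at least 10 positive D values")
    fits <- lapply(k, function(g)
        tryCatch(Mclust(x, G = g, modelNames = "V", verbose = FALSE),
                 error = function(e) NULL))
    bics <- vapply(fits, function(f) if (is.null(f)) -Inf else as.numeric(f$bic),
                   numeric(1))
    if (all(!is.finite(bics))) stop("mixture fit failed for all k")
    best <- which.max(bics)
    f <- fits[[best]]
    ord <- order(f$parameters$mean)
    comp <- data.frame(meanD = 10^f$parameters$mean[ord],
                       sdLog10 = sqrt(f$parameters$variance$sigmasq)[ord],
                       weight = f$parameters$pro[ord])
    out <- list(components = comp, k = k[best],
                logLik = f$loglik, bic = bics[best],
                comparison = data.frame(k = k, bic = bics),
                degenerate = any(comp$weight < 0.01),
                n = length(x))
    class(out) <- "MixtureFit"
    out
}

#' @export
print.MixtureFit <- function(x, ...) {
    cat(sprintf("MixtureFit: %d components on log10(D), n = %d\n", x$k, x$n))
    comp <- x$components
    for (i in seq_len(nrow(comp)))
        cat(sprintf("  D = %.3g um^2/s (sd %.2f dex), weight %.2f\n",
                    comp$meanD[i], comp$sdLog10[i], comp$weight[i]))
    invisible(x)
}
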