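#' Brownian trajectories with known diffusion coefficient
#'
#' Simulates free diffusion as independent per-axis Gaussian increments of
#' variance 2 D dt per step (the discretised Einstein relation; the mean
#' square displacement grows as 2 d D t). Optional localization noise is
#' added per detection after the path is built.
#'
#' @param D diffusion coefficient, um^2/s (0 gives immobile tracks).
#' @param dt frame interval, s.
#' @param nTracks number of tracks.
#' @param nFrames frames per track.
#' @param dim 2 or 3 spatial dimensions (2D tracks carry NA z).
#' @param locNoiseSd localization noise S.D. per axis, nm.
#' @param fieldNm tracks start uniform in a cube/square of this edge, nm
#'   (0 = all start at the origin).
#' @param seed integer seed.
#' @return a [TrackSet-class]; `trackInfo()` records the true D per track.
#' @examples
#' ts <- genBrownianTracks(1, dt = 0.01, nTracks = 5, nFrames = 20, seed = 1)
#' @export
genBrownianTracks <- function(D, dt, nTracks, nFrames, dim = 3,
                              locNoiseSd = 0, fieldNm = 0, seed = NULL) {
    D <- checkPositive(D, "D", strict = FALSE)
    dt <- checkPositive(dt, "dt")
    nTracks <- checkCount(nTracks, "nTracks")
    nFrames <- checkCount(nFrames, "nFrames", min = 1)
    stopifnot(dim %in% c(2, 3))
    stepSd <- sqrt(2 * D * dt) * 1000   # nm per axis per step

    withSeed(seed, {
        rows <- vector("list", nTracks)
        for (i in seq_len(nTracks)) {
            start <- if (fieldNm > 0) runif(dim, 0, fieldNm) else rep(0, dim)
            steps <- matrix(rnorm((nFrames - 1) * dim, sd = stepSd),
                            ncol = dim)
            pos <- rbind(start, sweep(apply(steps, 2, cumsum), 2, start, "+"))
            if (nFrames == 1) pos <- matrix(start, 1, dim)
            if (locNoiseSd > 0)
                pos <- pos + matrix(rnorm(nFrames * dim, sd = locNoiseSd),
                                    ncol = dim)
            rows[[i]] <- data.frame(track_id = i, frame = seq_len(nFrames),
                                    x_nm = pos[, 1], y_nm = pos[, 2],
                                    z_nm = if (dim == 3) pos[, 3] else NA_real_)
        }
        TrackSet(do.call(rbind, rows), dt = dt,
                 trackInfo = data.frame(track_id = seq_len(nTracks),
                                        D_true = D, population = 1L))
    })
}

#' Mixture of diffusing populations
#'
#' Draws tracks from several diffusive populations (e.g. a fast freely
#' diffusing pool and a chromatin-bound pool) with fixed fractions, keeping
#' the ground-truth population label per track. Population counts are
#' apportioned deterministically from the fractions so the realised mixture
#' matches the requested fractions exactly.
#'
#' @param populations data.frame with columns `D` (um^2/s) and `fraction`
#'   (summing to 1).
#' @param dt frame interval, s.
#' @param nTracks total number of tracks.
#' @param nFrames frames per track.
#' @param dim 2 or 3.
#' @param locNoiseSd localization noise S.D. per axis, nm.
#' @param fieldNm starting-position field edge, nm.
#' @param seed integer seed.
#' @return a [TrackSet-class] with `population` and `D_true` in
#'   `trackInfo()`.
#' @examples
#' pops <- data.frame(D = c(1.4, 0.017), fraction = c(0.36, 0.64))
#' mix <- genMixtureTracks(pops, dt = 0.01, nTracks = 50, nFrames = 20,
#'                         dim = 2, seed = 1)
#' @export
genMixtureTracks <- function(populations, dt, nTracks, nFrames, dim = 2,
                             locNoiseSd = 0, fieldNm = 0, seed = NULL) {
    stopifnot(is.data.frame(populations),
              all(c("D", "fraction") %in% names(populations)))
    if (abs(sum(populations$fraction) - 1) > 1e-8)
        stop("population fractions must sum to 1")
    if (any(populations$D < 0)) stop("diffusion coefficients must be >= 0")
    nTracks <- checkCount(nTracks, "nTracks")

    counts <- diff(c(0, round(cumsum(populations$fraction) * nTracks)))
    popOf <- rep(seq_len(nrow(populations)), counts)

    sets <- vector("list", nrow(populations))
    withSeed(seed, {
        for (p in seq_len(nrow(populations))) {
            if (counts[p] == 0) next
            sets[[p]] <- genBrownianTracks(populations$D[p], dt, counts[p],
                                           nFrames, dim = dim,
                                           locNoiseSd = locNoiseSd,
                                           fieldNm = fieldNm, seed = NULL)
        }
        offset <- 0
        allRows <- list(); allInfo <- list()
        for (p in seq_len(nrow(populations))) {
            if (is.null(sets[[p]])) next
            d <- trackData(sets[[p]]); info <- trackInfo(sets[[p]])
            d$track_id <- d$track_id + offset
            info$track_id <- info$track_id + offset
            info$population <- p
            offset <- offset + counts[p]
            allRows[[p]] <- d; allInfo[[p]] <- info
        }
        TrackSet(do.call(rbind, allRows), dt = dt,
                 trackInfo = do.call(rbind, allInfo))
    })
}
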