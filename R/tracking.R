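#' Link localizations into trajectories
#'
#' Greedy nearest-neighbour frame-to-frame linking. A detection joins an
#' existing track if it lies within the search radius of the track's last
#' position and the frame gap is at most `maxGap`; assignments are made in
#' order of increasing distance (ties by earliest candidate index), each
#' track and detection used at most once per frame. Unassigned detections
#' start new tracks, so every detection belongs to exactly one track.
#'
#' The search radius follows the maximum-diffusion rule
#' r_max = sqrt(2 d D_max dt_eff) (per-gap effective interval), with
#' D_max = 0.05 um^2/s the default used when mapping slowly exchanging
#' bound molecules; alternatively pass `rMax` in nm directly.
#'
#' @param locs data.frame with frame, x_nm, y_nm and optionally z_nm.
#' @param dt frame interval, s.
#' @param dMax maximum diffusion coefficient for linking, um^2/s.
#' @param rMax explicit search radius in nm (overrides `dMax`).
#' @param maxGap maximum frame gap closed during linking (default 1, i.e.
#'   no missed frames).
#' @return a [TrackSet-class].
#' @examples
#' locs <- data.frame(frame = rep(1:5, each = 2),
#'                    x_nm = rep(c(0, 5000), 5) + rnorm(10, sd = 10),
#'                    y_nm = rnorm(10, sd = 10))
#' linkTracks(locs, dt = 0.5)
#' @export
linkTracks <- function(locs, dt, dMax = 0.05, rMax = NULL, maxGap = 1) {
    stopifnot(all(c("frame", "x_nm", "y_nm") %in% names(locs)))
    has3d <- "z_nm" %in% names(locs) && !all(is.na(locs$z_nm))
    d <- if (has3d) 3 else 2
    axes <- c("x_nm", "y_nm", if (has3d) "z_nm")
    locs <- locs[order(locs$frame), , drop = FALSE]
    n <- nrow(locs)
    trackOf <- integer(n)
    nextTrack <- 1L

    # active track state: last row index and last frame
    lastRow <- integer(0); lastFrame <- integer(0); trackIds <- integer(0)
    frames <- sort(unique(locs$frame))
    rowsOf <- split(seq_len(n), locs$frame)

    for (f in frames) {
        rows <- rowsOf[[as.character(f)]]
        keepActive <- f - lastFrame <= maxGap
        actIdx <- which(keepActive)
        lastRow <- lastRow[actIdx]; lastFrame <- lastFrame[actIdx]
        trackIds <- trackIds[actIdx]
        if (length(lastRow) && length(rows)) {
            A <- as.matrix(locs[lastRow, axes, drop = FALSE])
            B <- as.matrix(locs[rows, axes, drop = FALSE])
            gaps <- f - lastFrame
            radii <- if (!is.null(rMax)) rep(rMax, length(gaps)) else
                sqrt(2 * d * dMax * gaps * dt) * 1000
            dm <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
            dm[dm < 0] <- 0
            dm <- sqrt(dm)
            dm[dm > matrix(radii, nrow(dm), ncol(dm))] <- Inf
            usedT <- rep(FALSE, nrow(dm)); usedD <- rep(FALSE, ncol(dm))
            repeat {
                dm2 <- dm; dm2[usedT, ] <- Inf; dm2[, usedD] <- Inf
                m <- which.min(dm2)
                if (!length(m) || !is.finite(dm2[m])) break
                ti <- (m - 1) %% nrow(dm) + 1
                di <- (m - 1) %/% nrow(dm) + 1
                trackOf[rows[di]] <- trackIds[ti]
                lastRow[ti] <- rows[di]; lastFrame[ti] <- f
                usedT[ti] <- TRUE; usedD[di] <- TRUE
            }
            newRows <- rows[!usedD]
        } else newRows <- rows
        for (r in newRows) {
            trackOf[r] <- nextTrack
            lastRow <- c(lastRow, r); lastFrame <- c(lastFrame, f)
            trackIds <- c(trackIds, nextTrack)
            nextTrack <- nextTrack + 1L
        }
    }
    out <- data.frame(track_id = trackOf, frame = locs$frame,
                      x_nm = locs$x_nm, y_nm = locs$y_nm,
                      z_nm = if (has3d) locs$z_nm else NA_real_)
    TrackSet(out, dt = dt)
}

#' Extract stable binding sites from tracks
#'
#' A track qualifies as a stable binding event when every frame-to-frame
#' step AND the end-to-end displacement stay below `maxDisp` (default
#' 50 nm) and the dwell lasts at least `minDuration`. Track duration is
#' n_frames * dt, so a single-frame event lasts one frame interval; under
#' the slow acquisition convention single-frame detections may be counted
#' as bound ("bound") or discarded ("discard"). Each qualifying event
#' contributes one site at the average of its localizations.
#'
#' @param tracks a [TrackSet-class].
#' @param maxDisp displacement bound, nm.
#' @param minDuration dwell-time cutoff, s (3 s for 3D mapping, 2 s for 2D
#'   maps by convention).
#' @param singleFrame policy for single-frame tracks: "discard" (fast
#'   acquisition) or "bound" (slow acquisition; they get duration dt).
#' @return data.frame with x_nm, y_nm, z_nm (site mean position),
#'   residence_s, start_frame, n_detections, track_id.
#' @examples
#' ts <- genBrownianTracks(0, dt = 3, nTracks = 3, nFrames = 12,
#'                         locNoiseSd = 5, seed = 1)
#' stableSites(ts, minDuration = 3)
#' @export
stableSites <- function(tracks, maxDisp = 50, minDuration = 3,
                        singleFrame = c("discard", "bound")) {
    singleFrame <- match.arg(singleFrame)
    d <- trackData(tracks)
    dt <- frameInterval(tracks)
    has3d <- !all(is.na(d$z_nm))
    axes <- c("x_nm", "y_nm", if (has3d) "z_nm")
    parts <- split(d, d$track_id)
    keep <- lapply(parts, function(tr) {
        nf <- nrow(tr)
        if (nf == 1 && singleFrame == "discard") return(NULL)
        if (nf > 1) {
            P <- as.matrix(tr[, axes, drop = FALSE])
            steps <- sqrt(rowSums(diff(P)^2))
            ee <- sqrt(sum((P[nf, ] - P[1, ])^2))
            if (any(steps >= maxDisp) || ee >= maxDisp) return(NULL)
        }
        dur <- nf * dt
        if (dur < minDuration) return(NULL)
        data.frame(x_nm = mean(tr$x_nm), y_nm = mean(tr$y_nm),
                   z_nm = if (has3d) mean(tr$z_nm) else NA_real_,
                   residence_s = dur, start_frame = min(tr$frame),
                   n_detections = nf, track_id = tr$track_id[1])
    })
    out <- do.call(rbind, keep)
    if (is.null(out))
        out <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                          z_nm = numeric(0), residence_s = numeric(0),
                          start_frame = integer(0), n_detections = integer(0),
                          track_id = integer(0))
    rownames(out) <- NULL
    out
}

#' Convert stable sites to a PointCatalog
#'
#' @param sites data.frame from [stableSites()].
#' @param volume optional declared [NuclearVolume-class].
#' @return a [PointCatalog-class] (z = 0 for 2D sites); residence times
#'   travel in the metadata.
#' @export
sitesToCatalog <- function(sites, volume = NULL) {
    z <- ifelse(is.na(sites$z_nm), 0, sites$z_nm)
    PointCatalog(cbind(sites$x_nm, sites$y_nm, z), volume = volume,
                 metadata = list(residence_s = sites$residence_s,
                                 start_frame = sites$start_frame))
}

#' Residence-time summary of stable sites
#'
#' @param sites data.frame from [stableSites()].
#' @param binWidth histogram bin width, s.
#' @return list: `mean` (s), `sem`, `n`, `histogram` (data.frame mid,
#'   count).
#' @importFrom stats sd
#' @export
residenceStats <- function(sites, binWidth = 3) {
    rt <- sites$residence_s
    if (!length(rt)) return(list(mean = NA_real_, sem = NA_real_, n = 0L,
                                 histogram = data.frame(mid = numeric(0),
                                                        count = integer(0))))
    edges <- seq(0, max(rt) + binWidth, by = binWidth)
    h <- hist(rt, breaks = edges, plot = FALSE)
    list(mean = mean(rt),
         sem = if (length(rt) > 1) sd(rt) / sqrt(length(rt)) else NA_real_,
         n = length(rt),
         histogram = data.frame(mid = h$mids, count = h$counts))
}

#' Detections per frame
#'
#' Simple per-frame tally of localization counts; the temporal profile used
#' to check whether a labelling/bleaching equilibrium has been reached
#' (initial decay to a plateau).
#'
#' @param locs data.frame with a `frame` column.
#' @return data.frame(frame, count), covering the full observed frame range
#'   with zeros where no detections fall.
#' @export
detectionsPerFrame <- function(locs) {
    stopifnot("frame" %in% names(locs))
    fr <- seq(min(locs$frame), max(locs$frame))
    counts <- tabulate(locs$frame - min(locs$frame) + 1, nbins = length(fr))
    data.frame(frame = fr, count = counts)
}

#' Canopy clustering of sites
#'
#' Assigns points to clusters by the canopy rule: points are visited in
#' order of decreasing local neighbour count, each unassigned point opens a
#' new canopy and captures every unassigned point within the canopy
#' radius. The same 400 nm radius drives the neighbour-density colouring of
#' site maps.
#'
#' @param catalog a [PointCatalog-class].
#' @param radius canopy radius, nm.
#' @return integer cluster id per point.
#' @export
canopyCluster <- function(catalog, radius = 400) {
    P <- coords(catalog)
    n <- nrow(P)
    dens <- neighborDensity(catalog, radius)
    ord <- order(dens, decreasing = TRUE)
    id <- integer(n)
    nextId <- 0L
    for (i in ord) {
        if (id[i] != 0L) next
        nextId <- nextId + 1L
        d2 <- (P[, 1] - P[i, 1])^2 + (P[, 2] - P[i, 2])^2 +
              (P[, 3] - P[i, 3])^2
        members <- which(id == 0L & d2 <= radius^2)
        id[members] <- nextId
    }
    id
}

#' Cumulative arrival-time curves per cluster region
#'
#' For each region (e.g. a canopy cluster of stable sites) the empirical
#' cumulative distribution of site start frames: at what point in the
#' acquisition the sites of that region were first seen. Uniform arrival
#' gives a linear CDF; front-loaded arrival a step.
#'
#' @param sites data.frame from [stableSites()].
#' @param regions integer region id per site (e.g. from [canopyCluster()]).
#' @param minSites regions with fewer sites are dropped.
#' @return named list of data.frames (frame, cdf), one per region.
#' @export
arrivalCdf <- function(sites, regions, minSites = 5) {
    stopifnot(nrow(sites) == length(regions))
    out <- list()
    for (rg in sort(unique(regions))) {
        sf <- sort(sites$start_frame[regions == rg])
        if (length(sf) < minSites) next
        out[[as.character(rg)]] <-
            data.frame(frame = sf, cdf = seq_along(sf) / length(sf))
    }
    out
}
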