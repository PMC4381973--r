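#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib smTFmap, .registration = TRUE
NULL

#' Nuclear volume geometry
#'
#' Describes the volume in which point catalogs live: either an explicit
#' sphere (the usual synthetic-nucleus model) or the 3D convex hull of the
#' data themselves, computed lazily where needed.
#'
#' @slot shape `"sphere"` or `"convex-hull"`.
#' @slot radius sphere radius in nm (NA for convex hulls).
#' @slot center sphere center, 3-vector in nm.
#' @export
setClass("NuclearVolume",
    representation(shape = "character", radius = "numeric", center = "numeric"),
    prototype(shape = "sphere", radius = 5000, center = c(0, 0, 0)))

setValidity("NuclearVolume", function(object) {
    if (!object@shape %in% c("sphere", "convex-hull"))
        return("shape must be 'sphere' or 'convex-hull'")
    if (object@shape == "sphere" && (length(object@radius) != 1 ||
        !is.finite(object@radius) || object@radius <= 0))
        return("sphere radius must be a single positive number (nm)")
    if (length(object@center) != 3) return("center must be a 3-vector (nm)")
    TRUE
})

setClassUnion("NuclearVolumeOrNULL", c("NuclearVolume", "NULL"))

#' Construct a spherical nuclear volume
#'
#' @param radiusUm sphere radius in micrometres (default 5, a typical
#'   mammalian nucleus).
#' @param center center in nm, default the origin.
#' @return a [NuclearVolume-class] object.
#' @examples
#' sphereVolume(5)
#' @export
sphereVolume <- function(radiusUm = 5, center = c(0, 0, 0)) {
    new("NuclearVolume", shape = "sphere", radius = radiusUm * 1000,
        center = as.numeric(center))
}

#' Catalog of 3D point localizations
#'
#' The central container for stable binding-site positions: an n x 3 matrix
#' of coordinates in nm, the declared nuclear volume (if any), optional
#' ground-truth cluster labels from a generator, and free-form metadata
#' (e.g. residence times).
#'
#' @slot coords numeric matrix, n x 3, columns x/y/z in nm.
#' @slot volume the declared [NuclearVolume-class], or NULL.
#' @slot labels integer cluster labels (length n or 0).
#' @slot metadata list of additional per-catalog information.
#' @export
setClass("PointCatalog",
    representation(coords = "matrix", volume = "NuclearVolumeOrNULL",
                   labels = "integer", metadata = "list"),
    prototype(coords = matrix(numeric(0), 0, 3,
                  dimnames = list(NULL, c("x", "y", "z"))),
              volume = NULL, labels = integer(0), metadata = list()))

setValidity("PointCatalog", function(object) {
    if (ncol(object@coords) != 3) return("coords must have 3 columns (x, y, z nm)")
    if (!all(is.finite(object@coords))) return("coords must be finite")
    if (length(object@labels) && length(object@labels) != nrow(object@coords))
        return("labels must be empty or one per point")
    TRUE
})

#' Create a PointCatalog
#'
#' @param coords n x 3 numeric matrix (nm).
#' @param volume optional [NuclearVolume-class].
#' @param labels optional integer cluster labels.
#' @param metadata optional list.
#' @return a [PointCatalog-class].
#' @export
PointCatalog <- function(coords, volume = NULL, labels = integer(0),
                         metadata = list()) {
    coords <- as.matrix(coords)
    colnames(coords) <- c("x", "y", "z")
    new("PointCatalog", coords = coords, volume = volume,
        labels = as.integer(labels), metadata = metadata)
}

#' Set of linked single-particle trajectories
#'
#' Tracks are stored long-format: one row per detection with track id, frame
#' number and coordinates in nm (z is NA for 2D data). The frame interval
#' `dt` (seconds) travels with the object; ground-truth per-track population
#' labels from generators are kept in `trackInfo`.
#'
#' @slot data data.frame with columns track_id, frame, x_nm, y_nm, z_nm.
#' @slot dt frame interval in seconds.
#' @slot trackInfo data.frame of per-track annotation (track_id plus e.g.
#'   population, D_true).
#' @export
setClass("TrackSet",
    representation(data = "data.frame", dt = "numeric", trackInfo = "data.frame"),
    prototype(data = data.frame(track_id = integer(0), frame = integer(0),
                                x_nm = numeric(0), y_nm = numeric(0),
                                z_nm = numeric(0)),
              dt = 1, trackInfo = data.frame()))

setValidity("TrackSet", function(object) {
    need <- c("track_id", "frame", "x_nm", "y_nm", "z_nm")
    if (!all(need %in% names(object@data)))
        return(paste("data must have columns", paste(need, collapse = ", ")))
    if (length(object@dt) != 1 || !is.finite(object@dt) || object@dt <= 0)
        return("dt must be a single positive number (s)")
    d <- object@data
    if (nrow(d) > 1) {
        o <- order(d$track_id, d$frame)
        if (anyDuplicated(d[o, c("track_id", "frame")]))
            return("duplicated (track_id, frame) rows")
    }
    TRUE
})

#' Create a TrackSet
#'
#' @param data data.frame with columns track_id, frame, x_nm, y_nm, z_nm
#'   (z_nm may be NA throughout for 2D tracks).
#' @param dt frame interval in seconds.
#' @param trackInfo optional data.frame of per-track annotation.
#' @return a [TrackSet-class].
#' @export
TrackSet <- function(data, dt, trackInfo = data.frame()) {
    if (!"z_nm" %in% names(data)) data$z_nm <- NA_real_
    data <- data[order(data$track_id, data$frame), , drop = FALSE]
    rownames(data) <- NULL
    new("TrackSet", data = data, dt = dt, trackInfo = trackInfo)
}

#' Binned pair-correlation curve
#'
#' Holds g(r) (or an angularly averaged image correlation c(r)) together
#' with the raw DD/RR pair counts, bin geometry and sampling metadata, so a
#' fit can be audited from the object alone. Bins are half-open
#' [r - dr/2, r + dr/2); bins with RR = 0 carry NA in g (never a division
#' by zero).
#'
#' @slot r bin centers, nm.
#' @slot dr bin width, nm.
#' @slot g estimator values (>= 0 or NA for undefined bins).
#' @slot dd raw data-data pair counts per bin.
#' @slot rr raw random-random pair counts per bin (empty for image curves).
#' @slot n number of data points/pixels.
#' @slot nr size of the random catalog (0 when not used).
#' @slot metadata list (seed, volume used, error estimates, ...).
#' @export
setClass("CorrelationCurve",
    representation(r = "numeric", dr = "numeric", g = "numeric",
                   dd = "numeric", rr = "numeric", n = "numeric",
                   nr = "numeric", metadata = "list"),
    prototype(r = numeric(0), dr = NA_real_, g = numeric(0), dd = numeric(0),
              rr = numeric(0), n = 0, nr = 0, metadata = list()))

setValidity("CorrelationCurve", function(object) {
    if (length(object@g) != length(object@r))
        return("g and r must have the same length")
    if (any(object@g < 0, na.rm = TRUE)) return("g must be non-negative")
    if (length(object@dd) && length(object@dd) != length(object@r))
        return("dd must be empty or match r")
    if (length(object@rr) && length(object@rr) != length(object@r))
        return("rr must be empty or match r")
    TRUE
})

#' Absorbing-target geometry for the search simulator
#'
#' @slot centers n x 3 matrix of target centers, nm.
#' @slot radius capture radius of each target, nm.
#' @slot volume the bounding [NuclearVolume-class] (a sphere).
#' @slot labels integer cluster labels for clustered placements.
#' @export
setClass("TargetSet",
    representation(centers = "matrix", radius = "numeric",
                   volume = "NuclearVolume", labels = "integer"),
    prototype(centers = matrix(numeric(0), 0, 3), radius = 40,
              labels = integer(0)))

setValidity("TargetSet", function(object) {
    if (ncol(object@centers) != 3) return("centers must be n x 3 (nm)")
    if (object@radius <= 0) return("target radius must be positive")
    if (length(object@labels) && length(object@labels) != nrow(object@centers))
        return("labels must be empty or one per target")
    TRUE
})

#' First-passage simulation result
#'
#' Samples of the first-passage time tau3D (seconds from injection to first
#' entry into any target sphere), the index of the target hit, a censoring
#' flag for trials that exhausted the step cap, and an echo of the
#' configuration used. Censored trials are reported, never dropped.
#'
#' @slot tau numeric, tau3D per trial in seconds (censored trials hold the
#'   cap time).
#' @slot hitIndex integer, 1-based target index (0 = censored).
#' @slot censored logical per trial.
#' @slot config list echoing the simulation configuration.
#' @slot trajectory optional m x 3 matrix, the first trial's path (nm).
#' @export
setClass("FirstPassageResult",
    representation(tau = "numeric", hitIndex = "integer", censored = "logical",
                   config = "list", trajectory = "matrix"),
    prototype(tau = numeric(0), hitIndex = integer(0), censored = logical(0),
              config = list(), trajectory = matrix(numeric(0), 0, 3)))

setValidity("FirstPassageResult", function(object) {
    if (any(object@tau <= 0)) return("all tau3D must be positive")
    if (length(object@hitIndex) != length(object@tau) ||
        length(object@censored) != length(object@tau))
        return("tau, hitIndex and censored must align")
    TRUE
})

#' 2D intensity map
#'
#' A pixel grid of non-negative intensities with physical pixel size, the
#' working object of the map-correlation analyses (KDE renderings of
#' localizations or normalized wide-field channels).
#'
#' @slot values numeric matrix of intensities (rows = y, cols = x).
#' @slot pixelSize pixel edge length in nm.
#' @export
setClass("IntensityMap",
    representation(values = "matrix", pixelSize = "numeric"),
    prototype(values = matrix(0, 1, 1), pixelSize = 160))

setValidity("IntensityMap", function(object) {
    if (!all(is.finite(object@values))) return("intensities must be finite")
    if (any(object@values < 0)) return("intensities must be non-negative")
    if (length(object@pixelSize) != 1 || object@pixelSize <= 0)
        return("pixelSize must be a single positive number (nm)")
    TRUE
})

#' Create an IntensityMap
#'
#' @param values numeric matrix of non-negative intensities.
#' @param pixelSize pixel edge length in nm.
#' @return an [IntensityMap-class].
#' @export
IntensityMap <- function(values, pixelSize) {
    new("IntensityMap", values = as.matrix(values), pixelSize = pixelSize)
}

#' @rdname accessors
#' @export
mapValues <- function(object) object@values

#' @rdname accessors
#' @export
pixelSize <- function(object) object@pixelSize

setMethod("show", "IntensityMap", function(object) {
    cat(sprintf("IntensityMap: %d x %d pixels, %g nm/pixel, mean %.4g\n",
                nrow(object@values), ncol(object@values), object@pixelSize,
                mean(object@values)))
})

setMethod("show", "NuclearVolume", function(object) {
    if (object@shape == "sphere") {
        cat(sprintf("NuclearVolume: sphere, radius %.3g um, center (%g, %g, %g) nm\n",
                    object@radius / 1000, object@center[1], object@center[2],
                    object@center[3]))
    } else {
        cat("NuclearVolume: convex hull of the data\n")
    }
})

setMethod("show", "PointCatalog", function(object) {
    cat(sprintf("PointCatalog with %d points", nrow(object@coords)))
    if (length(object@labels))
        cat(sprintf(" in %d labelled clusters", length(unique(object@labels))))
    cat("\n")
    if (!is.null(object@volume)) show(object@volume)
})

setMethod("show", "TrackSet", function(object) {
    nt <- length(unique(object@data$track_id))
    cat(sprintf("TrackSet: %d tracks, %d detections, dt = %g s\n",
                nt, nrow(object@data), object@dt))
})

setMethod("show", "CorrelationCurve", function(object) {
    cat(sprintf("CorrelationCurve: %d bins, dr = %g nm, r in [%g, %g] nm\n",
                length(object@r), object@dr,
                if (length(object@r)) min(object@r) else NA,
                if (length(object@r)) max(object@r) else NA))
    if (object@nr > 0)
        cat(sprintf("  N = %d data points, NR = %d random points\n",
                    as.integer(object@n), as.integer(object@nr)))
})

setMethod("show", "TargetSet", function(object) {
    cat(sprintf("TargetSet: %d targets of radius %g nm\n",
                nrow(object@centers), object@radius))
    show(object@volume)
})

setMethod("show", "FirstPassageResult", function(object) {
    cat(sprintf("FirstPassageResult: %d trials, %d censored\n",
                length(object@tau), sum(object@censored)))
    if (length(object@tau))
        cat(sprintf("  mean tau3D = %.4g s (uncensored: %.4g s)\n",
                    mean(object@tau),
                    mean(object@tau[!object@censored])))
})
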