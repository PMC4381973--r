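#' Accessors for smTFmap containers
#'
#' Slot access goes through these accessors, never through `@`.
#'
#' @param object a package container object.
#' @return `coords` and `targetCenters` return an n x 3 matrix in nm;
#'   `nuclearVolume` a [NuclearVolume-class] or NULL; `clusterLabels` an
#'   integer vector; `trackData` a data.frame; `frameInterval` seconds;
#'   `tau3d` seconds; `binCenters`/`pairCounts` the curve geometry and raw
#'   counts.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("nuclearVolume", function(object) standardGeneric("nuclearVolume"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("trackData", function(object) standardGeneric("trackData"))

#' @rdname accessors
#' @export
setGeneric("trackInfo", function(object) standardGeneric("trackInfo"))

#' @rdname accessors
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))

#' @rdname accessors
#' @export
setGeneric("gValues", function(object) standardGeneric("gValues"))

#' @rdname accessors
#' @export
setGeneric("binCenters", function(object) standardGeneric("binCenters"))

#' @rdname accessors
#' @export
setGeneric("pairCounts", function(object) standardGeneric("pairCounts"))

#' @rdname accessors
#' @export
setGeneric("targetCenters", function(object) standardGeneric("targetCenters"))

#' @rdname accessors
#' @export
setGeneric("targetRadius", function(object) standardGeneric("targetRadius"))

#' @rdname accessors
#' @export
setGeneric("tau3d", function(object) standardGeneric("tau3d"))

#' @rdname accessors
#' @export
setMethod("coords", "PointCatalog", function(object) object@coords)

#' @rdname accessors
#' @export
setMethod("nuclearVolume", "PointCatalog", function(object) object@volume)

#' @rdname accessors
#' @export
setMethod("nuclearVolume", "TargetSet", function(object) object@volume)

#' @rdname accessors
#' @export
setMethod("clusterLabels", "PointCatalog", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("clusterLabels", "TargetSet", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("trackData", "TrackSet", function(object) object@data)

#' @rdname accessors
#' @export
setMethod("trackInfo", "TrackSet", function(object) object@trackInfo)

#' @rdname accessors
#' @export
setMethod("frameInterval", "TrackSet", function(object) object@dt)

#' @rdname accessors
#' @export
setMethod("gValues", "CorrelationCurve", function(object) object@g)

#' @rdname accessors
#' @export
setMethod("binCenters", "CorrelationCurve", function(object) object@r)

#' @rdname accessors
#' @export
setMethod("pairCounts", "CorrelationCurve",
          function(object) list(dd = object@dd, rr = object@rr))

#' @rdname accessors
#' @export
setMethod("targetCenters", "TargetSet", function(object) object@centers)

#' @rdname accessors
#' @export
setMethod("targetRadius", "TargetSet", function(object) object@radius)

#' @rdname accessors
#' @export
setMethod("tau3d", "FirstPassageResult", function(object) object@tau)

#' @rdname accessors
#' @export
setGeneric("isCensored", function(object) standardGeneric("isCensored"))

#' @rdname accessors
#' @export
setMethod("isCensored", "FirstPassageResult", function(object) object@censored)

#' @rdname accessors
#' @export
setGeneric("hitIndex", function(object) standardGeneric("hitIndex"))

#' @rdname accessors
#' @export
setMethod("hitIndex", "FirstPassageResult", function(object) object@hitIndex)

#' @rdname accessors
#' @export
setGeneric("simConfig", function(object) standardGeneric("simConfig"))

#' @rdname accessors
#' @export
setMethod("simConfig", "FirstPassageResult", function(object) object@config)

#' @rdname accessors
#' @export
setGeneric("curveMetadata", function(object) standardGeneric("curveMetadata"))

#' @rdname accessors
#' @export
setMethod("curveMetadata", "CorrelationCurve", function(object) object@metadata)

#' Number of points, tracks or targets in a container
#'
#' @param x a container object.
#' @return an integer count.
#' @export
setMethod("length", "PointCatalog", function(x) nrow(x@coords))

#' @rdname length-PointCatalog-method
#' @export
setMethod("length", "TargetSet", function(x) nrow(x@centers))

#' @rdname length-PointCatalog-method
#' @export
setMethod("length", "TrackSet", function(x) length(unique(x@data$track_id)))
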