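#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers; use these rather
#' than reaching into slots.
#'
#' @param x an object.
#' @return The corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("locData", function(x) standardGeneric("locData"))

#' @rdname accessors
#' @export
setGeneric("nLocalizations", function(x) standardGeneric("nLocalizations"))

#' @rdname accessors
#' @export
setGeneric("segmentLength", function(x) standardGeneric("segmentLength"))

#' @rdname accessors
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' @rdname accessors
#' @export
setGeneric("profileCounts", function(x) standardGeneric("profileCounts"))

#' @rdname accessors
#' @export
setGeneric("corLags", function(x) standardGeneric("corLags"))

#' @rdname accessors
#' @export
setGeneric("corValues", function(x) standardGeneric("corValues"))

#' @rdname accessors
#' @export
setGeneric("isDegenerate", function(x) standardGeneric("isDegenerate"))

#' @rdname accessors
#' @export
setGeneric("corAmplitude", function(x) standardGeneric("corAmplitude"))

#' @rdname accessors
#' @export
setGeneric("corPeriod", function(x) standardGeneric("corPeriod"))

#' @rdname accessors
#' @export
setGeneric("phaseRadians", function(x) standardGeneric("phaseRadians"))

#' @rdname accessors
#' @export
setGeneric("phaseStrength", function(x) standardGeneric("phaseStrength"))

#' @rdname accessors
#' @export
setGeneric("candidateIds", function(x) standardGeneric("candidateIds"))

#' @rdname accessors
#' @export
setGeneric("dnsafValues", function(x) standardGeneric("dnsafValues"))

#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("punctaCoords", function(x) standardGeneric("punctaCoords"))

#' @rdname accessors
#' @export
setGeneric("meanWidth", function(x) standardGeneric("meanWidth"))
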