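#' @rdname contactArea
#' @export
setGeneric("contactArea", function(graph, i, j) standardGeneric("contactArea"))

#' @rdname cellVolume
#' @export
setGeneric("cellVolume", function(graph, i) standardGeneric("cellVolume"))

#' @rdname tracksData
#' @export
setGeneric("tracksData", function(object) standardGeneric("tracksData"))

#' @rdname frameInterval
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))

#' @rdname templateValues
#' @export
setGeneric("templateValues", function(template, u) standardGeneric("templateValues"))

#' @rdname animalAxis
#' @export
setGeneric("animalAxis", function(surface, frame) standardGeneric("animalAxis"))

#' Access the underlying trajectory table
#'
#' @param object a \linkS4class{CellTracks} object.
#' @return The data.frame of (track, frame) rows.
#' @name tracksData
#' @export
setMethod("tracksData", "CellTracks", function(object) object@data)

#' Frame interval in minutes
#'
#' @param object a \linkS4class{CellTracks} object.
#' @return Minutes between consecutive frames.
#' @name frameInterval
#' @export
setMethod("frameInterval", "CellTracks", function(object) object@frameInterval)
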