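#' @rdname GasParadigm-class
#' @param object a \code{GasParadigm}
#' @export
setGeneric("totalDuration", function(object) standardGeneric("totalDuration"))

#' @rdname GasParadigm-class
#' @export
setGeneric("hcBlocks", function(object) standardGeneric("hcBlocks"))

#' @rdname GasParadigm-class
#' @export
setGeneric("hoBlocks", function(object) standardGeneric("hoBlocks"))

#' @rdname DualEchoSeries-class
#' @param object object to access
#' @export
setGeneric("seriesData", function(object) standardGeneric("seriesData"))

#' @rdname DualEchoSeries-class
#' @export
setGeneric("frameInfo", function(object) standardGeneric("frameInfo"))

#' @rdname DualEchoSeries-class
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))

#' @rdname GroundTruth-class
#' @param object a \code{GroundTruth}
#' @param name map name, e.g. \code{"cbf0"}, \code{"oef"}
#' @export
setGeneric("truthMap", function(object, name) standardGeneric("truthMap"))

#' @export
#' @rdname GasParadigm-class
setMethod("totalDuration", "GasParadigm", function(object) object@totalDuration)

#' @export
#' @rdname GasParadigm-class
setMethod("hcBlocks", "GasParadigm", function(object) object@hcBlocks)

#' @export
#' @rdname GasParadigm-class
setMethod("hoBlocks", "GasParadigm", function(object) object@hoBlocks)

#' @export
#' @rdname DualEchoSeries-class
setMethod("seriesData", "DualEchoSeries", function(object) object@data)

#' @export
#' @rdname DualEchoSeries-class
setMethod("frameInfo", "DualEchoSeries", function(object) object@frames)

#' @export
#' @rdname DualEchoSeries-class
setMethod("geometry", "DualEchoSeries", function(object) object@geometry)

#' @export
#' @rdname GroundTruth-class
setMethod("truthMap", "GroundTruth", function(object, name) {
  if (!name %in% names(object@maps))
    stop("unknown truth map: ", name)
  object@maps[[name]]
})
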