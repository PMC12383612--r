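#' @import methods
NULL

#' @rdname GridDef-class
#' @export
setGeneric("nRows", function(x) standardGeneric("nRows"))

#' @rdname GridDef-class
#' @export
setGeneric("nCols", function(x) standardGeneric("nCols"))

#' @rdname GridDef-class
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' @rdname GridDef-class
#' @export
setGeneric("gridExtent", function(x) standardGeneric("gridExtent"))

#' @rdname EnvStack-class
#' @export
setGeneric("gridDef", function(x) standardGeneric("gridDef"))

#' @rdname EnvStack-class
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' @rdname EnvStack-class
#' @export
setGeneric("getLayer", function(x, name) standardGeneric("getLayer"))

#' @rdname EnvStack-class
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname OccurrenceSet-class
#' @export
setGeneric("occRecords", function(x) standardGeneric("occRecords"))

#' @rdname OccurrenceSet-class
#' @export
setGeneric("isThinned", function(x) standardGeneric("isThinned"))
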