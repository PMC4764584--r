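#' @title Accessor generics
#' @description Accessors for the core data containers.
#' @param object an object of the documented class
#' @param x an object of the documented class
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname accessors
#' @export
setGeneric("channelName", function(x) standardGeneric("channelName"))

#' @rdname accessors
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' @rdname accessors
#' @export
setGeneric("meshTriangles", function(x) standardGeneric("meshTriangles"))

#' @rdname accessors
#' @export
setGeneric("meshVolume", function(x) standardGeneric("meshVolume"))

#' @rdname accessors
#' @export
setGeneric("meshArea", function(x) standardGeneric("meshArea"))

#' @rdname accessors
#' @export
setGeneric("eulerCharacteristic", function(x)
  standardGeneric("eulerCharacteristic"))

#' @rdname accessors
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname accessors
#' @export
setGeneric("semiAxes", function(x) standardGeneric("semiAxes"))

#' @rdname accessors
#' @export
setGeneric("sceneChannel", function(x, which) standardGeneric("sceneChannel"))
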