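#' @title Accessor generics
#' @description Accessors for the imaging classes. Pixel grids use the
#'   (row, col) convention, 0-based field indices, origin at the top-left.
#' @param object an ecmscreen S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("wellId", function(object) standardGeneric("wellId"))

#' @rdname accessors
#' @export
setGeneric("bitDepth", function(object) standardGeneric("bitDepth"))

#' @rdname accessors
#' @export
setGeneric("fieldIndex", function(object) standardGeneric("fieldIndex"))

#' @rdname accessors
#' @export
setGeneric("sourceFields", function(object) standardGeneric("sourceFields"))

#' @rdname accessors
#' @export
setGeneric("pixelSizeUm", function(object) standardGeneric("pixelSizeUm"))

#' @rdname accessors
#' @export
setGeneric("maskPixels", function(object) standardGeneric("maskPixels"))

#' @rdname accessors
#' @export
setGeneric("skeletonMask", function(object) standardGeneric("skeletonMask"))

#' @rdname accessors
#' @export
setGeneric("distanceMap", function(object) standardGeneric("distanceMap"))

#' @rdname accessors
#' @export
setGeneric("markerLabels", function(object) standardGeneric("markerLabels"))

#' @rdname accessors
#' @export
setGeneric("markerStats", function(object) standardGeneric("markerStats"))

#' @rdname accessors
#' @export
setGeneric("branchLabels", function(object) standardGeneric("branchLabels"))

#' @rdname accessors
#' @export
setGeneric("branchTable", function(object) standardGeneric("branchTable"))

#' @rdname accessors
#' @export
setGeneric("bandOffsets", function(object) standardGeneric("bandOffsets"))

#' @rdname accessors
#' @export
setGeneric("ec50", function(object) standardGeneric("ec50"))

#' @rdname accessors
#' @export
setGeneric("hillSlope", function(object) standardGeneric("hillSlope"))

#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setGeneric("trueBranchCount",
           function(object) standardGeneric("trueBranchCount"))
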