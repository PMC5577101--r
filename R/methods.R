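# Accessors and show methods.

#' @rdname accessors
#' @export
setMethod("pixels", "FieldImage", function(object) object@pixels)
#' @rdname accessors
#' @export
setMethod("pixels", "WellImage", function(object) object@pixels)
#' @rdname accessors
#' @export
setMethod("wellId", "FieldImage", function(object) object@wellId)
#' @rdname accessors
#' @export
setMethod("wellId", "WellImage", function(object) object@wellId)
#' @rdname accessors
#' @export
setMethod("bitDepth", "FieldImage", function(object) object@bitDepth)
#' @rdname accessors
#' @export
setMethod("bitDepth", "WellImage", function(object) object@bitDepth)
#' @rdname accessors
#' @export
setMethod("fieldIndex", "FieldImage", function(object) object@fieldIndex)
#' @rdname accessors
#' @export
setMethod("sourceFields", "WellImage", function(object) object@sourceFields)
#' @rdname accessors
#' @export
setMethod("pixelSizeUm", "WellImage", function(object) object@pixelSizeUm)
#' @rdname accessors
#' @export
setMethod("maskPixels", "SegmentationMask", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("skeletonMask", "Skeleton", function(object) object@skeletonMask)
#' @rdname accessors
#' @export
setMethod("distanceMap", "Skeleton", function(object) object@distance)
#' @rdname accessors
#' @export
setMethod("markerLabels", "MarkerRegions", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("markerStats", "MarkerRegions", function(object) object@markerStats)
#' @rdname accessors
#' @export
setMethod("branchLabels", "BranchSet", function(object) object@branchLabels)
#' @rdname accessors
#' @export
setMethod("branchTable", "BranchSet", function(object) object@branches)
#' @rdname accessors
#' @export
setMethod("bandOffsets", "BranchSet", function(object) object@band)
#' @rdname accessors
#' @export
setMethod("ec50", "Fit4PL", function(object) object@ec50)
#' @rdname accessors
#' @export
setMethod("hillSlope", "Fit4PL", function(object) object@hill)
#' @rdname accessors
#' @export
setMethod("isConverged", "Fit4PL", function(object) object@converged)
#' @rdname accessors
#' @export
setMethod("trueBranchCount", "GroundTruth",
          function(object) object@trueBranchCount)

#' @describeIn Fit4PL-class fitted parameters as a named vector.
#' @param object a `Fit4PL`.
#' @export
setMethod("coef", "Fit4PL", function(object) {
  c(bottom = object@bottom, top = object@top, ec50 = object@ec50,
    hill = object@hill)
})

setMethod("show", "FieldImage", function(object) {
  cat(sprintf("FieldImage %s field %d: %d x %d px, %d-bit\n",
              object@wellId, object@fieldIndex, nrow(object@pixels),
              ncol(object@pixels), object@bitDepth))
})

setMethod("show", "WellImage", function(object) {
  cat(sprintf("WellImage %s: %d x %d px, %d-bit%s\n", object@wellId,
              nrow(object@pixels), ncol(object@pixels), object@bitDepth,
              if (!anyNA(object@sourceFields))
                sprintf(", tiled from fields (%s)",
                        paste(object@sourceFields, collapse = ",")) else ""))
})

setMethod("show", "SegmentationMask", function(object) {
  cat(sprintf("SegmentationMask: %d x %d, %d foreground px (%.2f%%)\n",
              nrow(object@mask), ncol(object@mask), sum(object@mask),
              100 * mean(object@mask)))
})

setMethod("show", "Skeleton", function(object) {
  cat(sprintf("Skeleton: %d px on a %d x %d grid\n",
              sum(object@skeletonMask), nrow(object@skeletonMask),
              ncol(object@skeletonMask)))
})

setMethod("show", "MarkerRegions", function(object) {
  cat(sprintf("MarkerRegions: %d markers\n", nrow(object@markerStats)))
})

setMethod("show", "BranchSet", function(object) {
  b <- object@branches
  ret <- if (nrow(b) && !anyNA(b$retained)) sum(b$retained) else NA
  cat(sprintf("BranchSet: %d branches%s (band -%g/+%g counts)\n",
              nrow(b),
              if (!is.na(ret)) sprintf(", %d retained", ret) else
                " (unfiltered)",
              object@band[["lower"]], object@band[["upper"]]))
})

setMethod("show", "Fit4PL", function(object) {
  cat(sprintf(
    "Fit4PL: bottom %.4g, top %.4g, ec50 %.4g %s, hill %.3g (rss %.4g, %s)\n",
    object@bottom, object@top, object@ec50,
    ifelse(is.na(object@unit), "", object@unit), object@hill, object@rss,
    if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "FibrilSpec", function(object) {
  cat(sprintf(
    "FibrilSpec: %d major (w %.2g px) + %d mesh (w %.2g px) fibres, %d px image, seed %d\n",
    object@nMajorFibres, object@majorWidthPx, object@nMeshFibres,
    object@meshWidthPx, object@imageSize, object@seed))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d fibres, %d nodes, %d branches\n",
              length(object@segments), nrow(object@nodes),
              object@trueBranchCount))
})

setMethod("show", "DoseResponseSpec", function(object) {
  cat(sprintf(
    "DoseResponseSpec: 4PL(bottom %.3g, top %.3g, ec50 %.3g, hill %.3g), cv %.3g, %d conc x %d reps\n",
    object@bottom, object@top, object@ec50, object@hill, object@cv,
    length(object@concentrations), object@nReplicates))
})
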