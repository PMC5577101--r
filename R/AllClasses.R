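# Central S4 classes. Pixel grids are numeric matrices holding integer
# camera counts at native scale (no rescaling on load); coordinates are
# (row, col), 0-based in documentation, with the origin at the top-left.

#' FieldImage: one acquired camera field
#'
#' A single-plane grayscale intensity grid for one field of a well, kept at
#' the native integer camera scale. Native acquisitions are 1104 x 1104 px
#' (2 x 2 binned); synthetic fixtures may use any square size.
#'
#' @slot pixels numeric matrix of integer-valued counts.
#' @slot bitDepth 8L or 16L; all pixels must lie in `[0, 2^bitDepth - 1]`.
#' @slot wellId plate coordinate such as `"B03"`.
#' @slot fieldIndex integer 0-3.
#' @export
setClass("FieldImage",
  representation(pixels = "matrix", bitDepth = "integer",
                 wellId = "character", fieldIndex = "integer"))

setValidity("FieldImage", function(object) {
  msg <- character()
  if (!isCountMatrix(object@pixels))
    msg <- c(msg, "pixels must be a non-negative integer-valued matrix")
  if (!(object@bitDepth %in% c(8L, 16L)))
    msg <- c(msg, "bitDepth must be 8 or 16")
  else if (any(object@pixels > 2^object@bitDepth - 1))
    msg <- c(msg, "pixel values exceed the bit-depth range")
  if (length(object@wellId) != 1L || is.na(object@wellId))
    msg <- c(msg, "wellId must be a single string")
  if (length(object@fieldIndex) != 1L ||
      !(object@fieldIndex %in% 0:3))
    msg <- c(msg, "fieldIndex must be an integer in 0:3")
  if (length(msg)) msg else TRUE
})

#' @param pixels,bitDepth,wellId,fieldIndex see slots.
#' @rdname FieldImage-class
#' @export
FieldImage <- function(pixels, bitDepth = 16L, wellId = "A01",
                       fieldIndex = 0L) {
  new("FieldImage", pixels = pixels, bitDepth = as.integer(bitDepth),
      wellId = as.character(wellId), fieldIndex = as.integer(fieldIndex))
}

#' WellImage: the tiled per-well mosaic
#'
#' The 2 x 2 mosaic of the four fields of one well (2208 x 2208 px for
#' native fields); the unit on which all image analysis operates.
#'
#' @slot pixels numeric matrix of integer-valued counts.
#' @slot bitDepth 8L or 16L.
#' @slot wellId plate coordinate.
#' @slot sourceFields the field indices placed at (top-left, top-right,
#'   bottom-left, bottom-right), or NA for images not assembled from fields.
#' @slot pixelSizeUm optional micrometres per pixel (NA if unknown).
#' @export
setClass("WellImage",
  representation(pixels = "matrix", bitDepth = "integer",
                 wellId = "character", sourceFields = "integer",
                 pixelSizeUm = "numeric"))

setValidity("WellImage", function(object) {
  msg <- character()
  if (!isCountMatrix(object@pixels))
    msg <- c(msg, "pixels must be a non-negative integer-valued matrix")
  if (!(object@bitDepth %in% c(8L, 16L)))
    msg <- c(msg, "bitDepth must be 8 or 16")
  else if (any(object@pixels > 2^object@bitDepth - 1))
    msg <- c(msg, "pixel values exceed the bit-depth range")
  if (!(length(object@sourceFields) %in% c(1L, 4L)))
    msg <- c(msg, "sourceFields must be NA or four field indices")
  if (length(object@pixelSizeUm) != 1L)
    msg <- c(msg, "pixelSizeUm must be a single number or NA")
  if (length(msg)) msg else TRUE
})

#' @param pixels,bitDepth,wellId,sourceFields,pixelSizeUm see slots.
#' @rdname WellImage-class
#' @export
WellImage <- function(pixels, bitDepth = 16L, wellId = "A01",
                      sourceFields = NA_integer_, pixelSizeUm = NA_real_) {
  new("WellImage", pixels = pixels, bitDepth = as.integer(bitDepth),
      wellId = as.character(wellId),
      sourceFields = as.integer(sourceFields),
      pixelSizeUm = as.numeric(pixelSizeUm))
}

#' SegmentationMask: adaptive-threshold foreground
#'
#' @slot mask logical matrix, same shape as the source image.
#' @slot params list echoing the segmentation parameters
#'   (`method`, `window_px`, `offset_counts`).
#' @export
setClass("SegmentationMask",
  representation(mask = "matrix", params = "list"))

setValidity("SegmentationMask", function(object) {
  if (!is.matrix(object@mask) || !is.logical(object@mask))
    "mask must be a logical matrix" else TRUE
})

#' Skeleton: thin centreline of the segmented foreground
#'
#' @slot skeletonMask logical matrix; a subset of the foreground, with no
#'   2 x 2 all-true block.
#' @slot distance per-pixel fast-marching distance to background (px);
#'   0 on background.
#' @export
setClass("Skeleton",
  representation(skeletonMask = "matrix", distance = "matrix"))

setValidity("Skeleton", function(object) {
  msg <- character()
  if (!is.logical(object@skeletonMask))
    msg <- c(msg, "skeletonMask must be logical")
  if (!identical(dim(object@skeletonMask), dim(object@distance)))
    msg <- c(msg, "skeletonMask and distance must share dimensions")
  if (length(msg)) msg else TRUE
})

#' MarkerRegions: skeleton paths between junctions/endpoints
#'
#' @slot labels integer matrix over skeleton pixels (0 = none); labels are
#'   contiguous `1..K` and each label is one 8-connected component.
#' @slot markerStats data.frame with columns `label`, `pixel_count`,
#'   `mean_intensity` (native counts, from the original image).
#' @export
setClass("MarkerRegions",
  representation(labels = "matrix", markerStats = "data.frame"))

#' BranchSet: grown branch regions with audit flags
#'
#' @slot branchLabels integer matrix over the foreground; pixel value is the
#'   marker label whose flood front claimed it.
#' @slot branches data.frame with one row per branch: `marker_label`,
#'   `area_px`, `mean_intensity`, `marker_mean`, `retained`.
#' @slot band numeric `c(lower = 50, upper = 150)`: the inclusion band in
#'   native counts around the marker mean.
#' @slot pixelSizeUm optional micrometres per pixel.
#' @export
setClass("BranchSet",
  representation(branchLabels = "matrix", branches = "data.frame",
                 band = "numeric", pixelSizeUm = "numeric"))

#' Fit4PL: four-parameter logistic dose-response fit
#'
#' Model: `y = bottom + (top - bottom) / (1 + (ec50 / x)^hill)`, orientation
#' normalised so that `top >= bottom`.
#'
#' @slot bottom,top asymptotes (response units).
#' @slot ec50 half-maximal concentration, in the units of the input.
#' @slot hill dimensionless slope.
#' @slot rss residual sum of squares.
#' @slot converged honest convergence flag; FALSE for degenerate (flat)
#'   data, for which `bottom == top`.
#' @slot nPoints number of fitted points.
#' @slot unit concentration unit label carried through (never converted).
#' @export
setClass("Fit4PL",
  representation(bottom = "numeric", top = "numeric", ec50 = "numeric",
                 hill = "numeric", rss = "numeric", converged = "logical",
                 nPoints = "integer", unit = "character"))

setValidity("Fit4PL", function(object) {
  msg <- character()
  if (object@converged && !(is.finite(object@ec50) && object@ec50 > 0))
    msg <- c(msg, "ec50 must be positive")
  if (object@top < object@bottom)
    msg <- c(msg, "orientation must be normalised (top >= bottom)")
  if (is.finite(object@rss) && object@rss < 0)
    msg <- c(msg, "rss must be non-negative")
  if (length(msg)) msg else TRUE
})

#' FibrilSpec: parameters of the synthetic fibrillar network
#'
#' Emulates the two phenotypes seen in stained decellularised matrix: a
#' dense fine mesh interlinking a few major fibres (the stimulated
#' phenotype) versus sparse thicker fibrils with fewer interconnections.
#' Widths are Gaussian cross-section sigmas in px; intensities are native
#' counts. The same spec and seed always produce a bit-identical image.
#'
#' @slot nMajorFibres,majorWidthPx count and width of major fibres.
#' @slot nMeshFibres,meshWidthPx count and width of fine mesh fibres.
#' @slot fibreIntensity peak fibre intensity above background (counts).
#' @slot backgroundLevel background offset (counts).
#' @slot noiseSigma additive Gaussian noise sigma (counts), clipped to the
#'   bit-depth range.
#' @slot curvature maximum control-point deviation (px); 0 = straight.
#' @slot imageSize image side (px).
#' @slot bitDepth 8L or 16L.
#' @slot seed integer seed.
#' @export
setClass("FibrilSpec",
  representation(nMajorFibres = "integer", majorWidthPx = "numeric",
                 nMeshFibres = "integer", meshWidthPx = "numeric",
                 fibreIntensity = "numeric", backgroundLevel = "numeric",
                 noiseSigma = "numeric", curvature = "numeric",
                 imageSize = "integer", bitDepth = "integer",
                 seed = "integer"))

setValidity("FibrilSpec", function(object) {
  msg <- character()
  if (object@nMajorFibres < 0L || object@nMeshFibres < 0L)
    msg <- c(msg, "fibre counts must be >= 0")
  if (object@majorWidthPx <= 0 || object@meshWidthPx <= 0)
    msg <- c(msg, "fibre widths must be positive")
  if (object@fibreIntensity < 0 || object@backgroundLevel < 0 ||
      object@noiseSigma < 0 || object@curvature < 0)
    msg <- c(msg, "intensities, noise and curvature must be >= 0")
  maxw <- max(object@majorWidthPx, object@meshWidthPx)
  if (object@imageSize < ceiling(24 * maxw))
    msg <- c(msg, sprintf(
      "imageSize %d too small for fibre width %.1f px (need >= %d)",
      object@imageSize, maxw, ceiling(24 * maxw)))
  if (object@backgroundLevel + object@fibreIntensity > 2^object@bitDepth - 1)
    msg <- c(msg, "background + fibre intensity exceeds bit-depth range")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: exact topology of a synthetic network
#'
#' Nodes are fibre endpoints and pairwise fibre intersections; each fibre
#' contributes one edge between consecutive nodes along its length, and
#' `trueBranchCount` is the total edge count. This mirrors the operational
#' branch definition of the image pipeline (skeleton paths between
#' junctions/endpoints), making recovery well-posed.
#'
#' @slot segments list of polylines, one per fibre ((row, col) matrices,
#'   0-based continuous coordinates).
#' @slot nodes data.frame: `node`, `row`, `col`, `type`
#'   ("endpoint"/"junction").
#' @slot edges data.frame: `fibre`, `from_node`, `to_node`.
#' @slot trueBranchCount integer, `nrow(edges)`.
#' @slot trueMask logical matrix: rasterised foreground (within two
#'   cross-section sigmas of a centreline).
#' @export
setClass("GroundTruth",
  representation(segments = "list", nodes = "data.frame",
                 edges = "data.frame", trueBranchCount = "integer",
                 trueMask = "matrix"))

setValidity("GroundTruth", function(object) {
  if (object@trueBranchCount != nrow(object@edges))
    "trueBranchCount must equal the number of graph edges" else TRUE
})

#' DoseResponseSpec: generator for plate-level dose-response readouts
#'
#' ECM signals follow a four-parameter logistic in concentration with
#' multiplicative log-normal noise of coefficient of variation `cv`
#' (mean-one); viability signals are drawn near 1 to exercise
#' normalisation.
#'
#' @slot bottom,top,ec50,hill 4PL parameters (top > bottom, ec50 > 0).
#' @slot cv multiplicative noise CV (>= 0).
#' @slot concentrations dose series (same units as ec50).
#' @slot nReplicates replicates per concentration.
#' @slot viabilityCv CV of the viability signal around 1.
#' @slot seed integer seed.
#' @export
setClass("DoseResponseSpec",
  representation(bottom = "numeric", top = "numeric", ec50 = "numeric",
                 hill = "numeric", cv = "numeric",
                 concentrations = "numeric", nReplicates = "integer",
                 viabilityCv = "numeric", seed = "integer"))

setValidity("DoseResponseSpec", function(object) {
  msg <- character()
  if (object@top <= object@bottom) msg <- c(msg, "top must exceed bottom")
  if (object@ec50 <= 0) msg <- c(msg, "ec50 must be positive")
  if (object@cv < 0 || object@viabilityCv < 0)
    msg <- c(msg, "cv must be >= 0")
  if (any(object@concentrations <= 0))
    msg <- c(msg, "concentrations must be positive")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (length(msg)) msg else TRUE
})
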