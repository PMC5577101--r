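# The matrix-branching pipeline: adaptive segmentation -> fast-marching
# skeletonization -> marker regions -> intensity-priority flood fill ->
# inclusion band -> per-well branch count and mean area. 8-connectivity is
# used for foreground and skeleton throughout; background uses
# 4-connectivity (the standard digital-topology pairing).

#' Robust background noise scale of a well image
#'
#' `1.4826 * median absolute deviation` of all pixels; for fibrillar images
#' the background dominates, so this estimates the background sigma.
#'
#' @param image a [WellImage-class].
#' @return numeric scalar (counts).
#' @export
robustBackgroundSigma <- function(image) {
  stopifnot(is(image, "WellImage"))
  mad(as.numeric(pixels(image)), constant = 1.4826)
}

#' Adaptive per-pixel segmentation
#'
#' A pixel is foreground iff its intensity strictly exceeds the
#' Gaussian-weighted local mean (window of `windowPx` pixels, sigma
#' `windowPx / 6`, borders handled by reflection) plus `offsetCounts`.
#'
#' @param image a [WellImage-class].
#' @param windowPx odd window size >= 3 (px). Default 51.
#' @param offsetCounts constant offset in native counts; defaults to twice
#'   the robust background sigma, floored at 1 count.
#' @return a [SegmentationMask-class].
#' @export
adaptiveSegment <- function(image, windowPx = 51, offsetCounts = NULL) {
  stopifnot(is(image, "WellImage"))
  if (windowPx < 3 || windowPx %% 2 == 0)
    stop("windowPx must be an odd integer >= 3")
  if (is.null(offsetCounts))
    offsetCounts <- max(2 * robustBackgroundSigma(image), 1)
  px <- pixels(image)
  localMean <- cpp_gaussian_local_mean(px, as.integer(windowPx))
  new("SegmentationMask", mask = px > localMean + offsetCounts,
      params = list(method = "gaussian_local_mean", window_px = windowPx,
                    offset_counts = offsetCounts))
}

#' Skeletonize a segmentation mask via a fast-marching distance transform
#'
#' The distance field solves the Eikonal equation (unit speed, first-order
#' fast marching) from the background/foreground interface; background
#' pixels carry distance 0. The skeleton is extracted by distance-ordered
#' homotopic thinning: simple pixels are deleted in increasing distance
#' order, endpoints are preserved, so the result is a thin (no 2 x 2 block)
#' centreline with exactly one skeleton component per 8-connected mask
#' component and all holes preserved.
#'
#' @param mask a [SegmentationMask-class] or logical matrix.
#' @return a [Skeleton-class].
#' @export
skeletonizeMask <- function(mask) {
  m <- if (is(mask, "SegmentationMask")) maskPixels(mask) else mask
  stopifnot(is.logical(m), is.matrix(m))
  d <- cpp_fmm_distance(m)
  skel <- cpp_thin(m, d)
  new("Skeleton", skeletonMask = skel, distance = d)
}

#' Prune short terminal spurs from a skeleton
#'
#' Boundary irregularities of wide fibres leave short terminal twigs on the
#' skeleton; each twig adds a junction that would split a genuine fibre
#' path. Arms running from an endpoint to the first junction are removed
#' when shorter than `minSpurPx` (whole components are never removed, so
#' component counts are preserved).
#'
#' @param skeleton a [Skeleton-class].
#' @param minSpurPx spur length threshold in px (default 4).
#' @return a pruned [Skeleton-class].
#' @export
pruneSpurs <- function(skeleton, minSpurPx = 4) {
  stopifnot(is(skeleton, "Skeleton"))
  skel <- skeletonMask(skeleton)
  nr <- nrow(skel)
  offs <- c(-1L - nr, -nr, 1L - nr, -1L, 1L, nr - 1L, nr, nr + 1L)
  repeat {
    nc <- cpp_neighbour_count(skel)
    ends <- which(skel & nc == 1L)
    if (!length(ends)) break
    changed <- FALSE
    for (e in ends) {
      if (!skel[e]) next
      path <- e
      cur <- e
      prev <- -1L
      repeat {
        ri <- (cur - 1L) %% nr + 1L
        nbr <- cur + offs
        nbr <- nbr[abs(((nbr - 1L) %% nr + 1L) - ri) <= 1L &
                     nbr >= 1L & nbr <= length(skel)]
        nbr <- nbr[skel[nbr] & nbr != prev]
        nbr <- setdiff(nbr, path)
        if (length(nbr) != 1L) break        # junction cluster or dead end
        nxt <- nbr
        if (nc[nxt] >= 3L) {                # reached a junction
          if (length(path) < minSpurPx) {
            skel[path] <- FALSE
            changed <- TRUE
          }
          path <- NULL
          break
        }
        prev <- cur
        cur <- nxt
        path <- c(path, cur)
        if (length(path) >= minSpurPx) { path <- NULL; break }
      }
    }
    if (!changed) break
  }
  new("Skeleton", skeletonMask = skel, distance = distanceMap(skeleton))
}

# unique adjacent (labA > 0, labB > 0) pairs between two label images under
# 8-connectivity, via shifted overlays
.adjacentPairs <- function(labA, labB) {
  nr <- nrow(labA); ncl <- ncol(labA)
  pairs <- NULL
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ra <- max(1, 1 + dr):min(nr, nr + dr)
    ca <- max(1, 1 + dc):min(ncl, ncl + dc)
    rb <- ra - dr; cb <- ca - dc
    a <- labA[ra, ca]; b <- labB[rb, cb]
    sel <- a > 0L & b > 0L
    if (any(sel)) pairs <- rbind(pairs, unique(cbind(a[sel], b[sel])))
  }
  if (is.null(pairs)) matrix(integer(0), ncol = 2L) else unique(pairs)
}

#' Extract marker regions from a skeleton
#'
#' Skeleton pixels are classified by their 8-neighbour count within the
#' skeleton: junction if >= 3, endpoint if <= 1, path otherwise. Markers
#' are the 8-connected components of the skeleton after junction pixels are
#' removed (junction pixels belong to no marker); components shorter than
#' `minMarkerPx` are discarded as noise. A crossing of two fibres thins to
#' a pair of nearby junctions joined by a short path; such "connector"
#' components (touching at least two distinct junction clusters, shorter
#' than `maxConnectorPx`) are part of the junction and are assigned to no
#' marker. Mean marker intensity is measured on the original image.
#'
#' @param skeleton a [Skeleton-class].
#' @param image the original [WellImage-class].
#' @param minMarkerPx minimum marker length in px (default 3).
#' @param maxConnectorPx junction-merge radius: inter-junction paths
#'   shorter than this are treated as junction, not branch (default 12).
#' @return a [MarkerRegions-class] with labels contiguous `1..K`.
#' @export
extractMarkerRegions <- function(skeleton, image, minMarkerPx = 3,
                                 maxConnectorPx = 12) {
  stopifnot(is(skeleton, "Skeleton"), is(image, "WellImage"))
  skel <- skeletonMask(skeleton)
  ncnt <- cpp_neighbour_count(skel)
  junction <- skel & ncnt >= 3L
  nonJunction <- skel & ncnt < 3L
  lab <- cpp_label_components(nonJunction, 8L)
  px <- pixels(image)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab, nbins = max(lab))
    jlab <- cpp_label_components(junction, 8L)
    touches <- .adjacentPairs(lab, jlab)
    nClusters <- tabulate(touches[, 1L], nbins = max(lab))
    connector <- nClusters >= 2L & sizes < maxConnectorPx
    keep <- which(sizes >= minMarkerPx & !connector)
    remap <- integer(max(lab))
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
    stats <- if (length(keep)) {
      data.frame(
        label = seq_along(keep),
        pixel_count = sizes[keep],
        mean_intensity = as.numeric(
          tapply(px[lab > 0L], lab[lab > 0L], mean)))
    } else .emptyMarkerStats()
  } else stats <- .emptyMarkerStats()
  new("MarkerRegions", labels = lab, markerStats = stats)
}

.emptyMarkerStats <- function() {
  data.frame(label = integer(0), pixel_count = integer(0),
             mean_intensity = numeric(0))
}

#' Grow branches from markers by intensity-priority flood fill
#'
#' Marker-seeded region growing over the foreground of the original image:
#' a priority queue ordered by (pixel intensity descending, marker label
#' ascending, insertion order ascending) floods outward from the markers so
#' that every foreground pixel 8-connected to a marker is assigned to
#' exactly one marker; ties in intensity go to the lowest marker label,
#' making the partition deterministic. The result is unfiltered
#' (`retained` is NA until [filterBranches()]).
#'
#' @param image the original [WellImage-class].
#' @param mask the [SegmentationMask-class] the markers came from.
#' @param markers a [MarkerRegions-class].
#' @return a [BranchSet-class].
#' @export
growBranches <- function(image, mask, markers) {
  stopifnot(is(image, "WellImage"), is(mask, "SegmentationMask"),
            is(markers, "MarkerRegions"))
  px <- pixels(image)
  m <- maskPixels(mask)
  lab <- markerLabels(markers)
  if (any(lab > 0L & !m))
    stop("markers must lie within the foreground mask")
  stats <- markerStats(markers)
  if (!nrow(stats))
    return(new("BranchSet", branchLabels = matrix(0L, nrow(m), ncol(m)),
               branches = .emptyBranchTable(),
               band = c(lower = 50, upper = 150),
               pixelSizeUm = pixelSizeUm(image)))
  grown <- cpp_priority_flood(px, m, lab)
  k <- nrow(stats)
  sizes <- tabulate(grown[grown > 0L], nbins = k)
  sums <- vapply(seq_len(k), function(i) sum(px[grown == i]), numeric(1))
  branches <- data.frame(
    marker_label = seq_len(k),
    area_px = sizes,
    mean_intensity = ifelse(sizes > 0, sums / sizes, NA_real_),
    marker_mean = stats$mean_intensity,
    retained = NA)
  new("BranchSet", branchLabels = grown, branches = branches,
      band = c(lower = 50, upper = 150), pixelSizeUm = pixelSizeUm(image))
}

.emptyBranchTable <- function() {
  data.frame(marker_label = integer(0), area_px = integer(0),
             mean_intensity = numeric(0), marker_mean = numeric(0),
             retained = logical(0))
}

#' Apply the intensity inclusion band to grown branches
#'
#' A branch is retained iff its mean intensity lies within the closed
#' interval `[marker mean - lowerOffset, marker mean + upperOffset]`
#' (defaults -50/+150 native counts). Branches smaller than `minBranchPx2`
#' are discarded outright as noise before the band is applied; excluded
#' branches are kept with `retained = FALSE` for audit.
#'
#' @param branches a [BranchSet-class] from [growBranches()].
#' @param upperOffset,lowerOffset band half-widths in native counts
#'   (both must be >= 0).
#' @param minBranchPx2 minimum branch area in px^2 (default 5).
#' @return the filtered [BranchSet-class].
#' @export
filterBranches <- function(branches, upperOffset = 150, lowerOffset = 50,
                           minBranchPx2 = 5) {
  stopifnot(is(branches, "BranchSet"))
  if (upperOffset < 0 || lowerOffset < 0)
    stop("band offsets must be non-negative")
  b <- branchTable(branches)
  lab <- branchLabels(branches)
  small <- b$area_px < minBranchPx2
  if (any(small)) {
    lab[lab %in% b$marker_label[small]] <- 0L
    b <- b[!small, , drop = FALSE]
  }
  b$retained <- !is.na(b$mean_intensity) &
    b$mean_intensity >= b$marker_mean - lowerOffset &
    b$mean_intensity <= b$marker_mean + upperOffset
  new("BranchSet", branchLabels = lab, branches = b,
      band = c(lower = lowerOffset, upper = upperOffset),
      pixelSizeUm = branches@pixelSizeUm)
}

#' Summarise retained branches for a well
#'
#' @param branches a filtered [BranchSet-class].
#' @param wellId well id for the summary row.
#' @param pixelSizeUm optional micrometres per pixel; adds
#'   `mean_branch_area_um2`.
#' @return one-row data.frame: `well_id`, `n_branches`,
#'   `mean_branch_area_px2` (NA when no branch is retained),
#'   `mean_branch_area_um2`.
#' @export
summarizeBranches <- function(branches, wellId = "A01",
                              pixelSizeUm = NULL) {
  stopifnot(is(branches, "BranchSet"))
  b <- branchTable(branches)
  if (nrow(b) && anyNA(b$retained))
    stop("branches must be filtered (filterBranches) before summarising")
  psz <- pixelSizeUm %||% branches@pixelSizeUm
  n <- sum(b$retained)
  meanArea <- if (n > 0) mean(b$area_px[b$retained]) else NA_real_
  data.frame(well_id = wellId, n_branches = as.integer(n),
             mean_branch_area_px2 = meanArea,
             mean_branch_area_um2 = if (!is.na(psz)) meanArea * psz^2
                                    else NA_real_)
}

#' Default parameters of the branching pipeline
#'
#' @param windowPx,offsetCounts see [adaptiveSegment()].
#' @param minSpurPx see [pruneSpurs()].
#' @param minMarkerPx,maxConnectorPx see [extractMarkerRegions()].
#' @param upperOffset,lowerOffset,minBranchPx2 see [filterBranches()].
#' @param tilingOrder see [tileFields()].
#' @return named list of parameters.
#' @export
branchParams <- function(windowPx = 51, offsetCounts = NULL, minSpurPx = 4,
                         minMarkerPx = 3, maxConnectorPx = 12,
                         upperOffset = 150, lowerOffset = 50,
                         minBranchPx2 = 5, tilingOrder = 0:3) {
  list(windowPx = windowPx, offsetCounts = offsetCounts,
       minSpurPx = minSpurPx, minMarkerPx = minMarkerPx,
       maxConnectorPx = maxConnectorPx, upperOffset = upperOffset,
       lowerOffset = lowerOffset, minBranchPx2 = minBranchPx2,
       tilingOrder = tilingOrder)
}

#' Run the full branching pipeline on one well
#'
#' Composition: tile (if four fields are given) -> adaptive segmentation ->
#' fast-marching skeletonization -> spur pruning -> marker regions ->
#' intensity-priority flood fill -> inclusion band -> summary. Identical
#' inputs and parameters give identical results.
#'
#' @param x either a list of four [FieldImage-class] objects or a
#'   [WellImage-class].
#' @param params a [branchParams()] list.
#' @param details if TRUE, return all intermediate artefacts.
#' @return the one-row summary data.frame (see [summarizeBranches()]), or,
#'   with `details = TRUE`, a list with `summary`, `well`, `mask`,
#'   `skeleton`, `markers` and `branches`.
#' @export
analyzeWell <- function(x, params = branchParams(), details = FALSE) {
  well <- if (is(x, "WellImage")) x
          else tileFields(x, order = params$tilingOrder)
  mask <- adaptiveSegment(well, windowPx = params$windowPx,
                          offsetCounts = params$offsetCounts)
  skel <- pruneSpurs(skeletonizeMask(mask), minSpurPx = params$minSpurPx)
  markers <- extractMarkerRegions(skel, well,
                                  minMarkerPx = params$minMarkerPx,
                                  maxConnectorPx = params$maxConnectorPx)
  grown <- growBranches(well, mask, markers)
  filtered <- filterBranches(grown, upperOffset = params$upperOffset,
                             lowerOffset = params$lowerOffset,
                             minBranchPx2 = params$minBranchPx2)
  summary <- summarizeBranches(filtered, wellId = wellId(well))
  if (details)
    list(summary = summary, well = well, mask = mask, skeleton = skel,
         markers = markers, branches = filtered)
  else summary
}
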