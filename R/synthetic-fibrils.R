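# Synthetic fibrillar-matrix images with exact branch topology, plus
# plate-level dose-response readouts. Fibres are smooth polylines with a
# Gaussian cross-section painted onto a constant background; the ground
# truth graph is built from exact segment intersections, so the branch
# definition (edges between junction/endpoint nodes) matches the image
# pipeline's operational definition.

#' Construct a synthetic fibril network specification
#'
#' Defaults emulate the stimulated phenotype: a few major fibres linked by a
#' dense mesh of fine fibres. See [generatePhenotypePair()] for the sparse
#' thick-fibril alternative.
#'
#' @param nMajorFibres,majorWidthPx,nMeshFibres,meshWidthPx fibre counts and
#'   Gaussian cross-section sigmas (px).
#' @param fibreIntensity,backgroundLevel,noiseSigma native counts.
#' @param curvature maximum control-point deviation in px (0 = straight).
#' @param imageSize image side in px.
#' @param bitDepth 8 or 16.
#' @param seed integer seed; identical spec + seed gives a bit-identical
#'   image and graph.
#' @return a [FibrilSpec-class].
#' @export
fibrilSpec <- function(nMajorFibres = 3, majorWidthPx = 2.5,
                       nMeshFibres = 40, meshWidthPx = 1.2,
                       fibreIntensity = 120, backgroundLevel = 100,
                       noiseSigma = 6, curvature = 15, imageSize = 512,
                       bitDepth = 16, seed = 1) {
  new("FibrilSpec", nMajorFibres = as.integer(nMajorFibres),
      majorWidthPx = majorWidthPx, nMeshFibres = as.integer(nMeshFibres),
      meshWidthPx = meshWidthPx, fibreIntensity = fibreIntensity,
      backgroundLevel = backgroundLevel, noiseSigma = noiseSigma,
      curvature = curvature, imageSize = as.integer(imageSize),
      bitDepth = as.integer(bitDepth), seed = as.integer(seed))
}

# -- geometry helpers --------------------------------------------------------

# one random fibre polyline inside [margin, size-1-margin]^2, as an n x 2
# (row, col) matrix; straight if curvature == 0, else a quadratic Bezier
.randomFibre <- function(size, margin, curvature, minFrac = 0.45) {
  lo <- margin
  hi <- size - 1 - margin
  repeat {
    p <- runif(2, lo, hi)
    th <- runif(1, 0, pi)
    d <- c(sin(th), cos(th))
    # clip the line p + t*d to the box
    ts <- c()
    for (ax in 1:2) {
      if (abs(d[ax]) > 1e-12)
        ts <- rbind(ts, sort((c(lo, hi) - p[ax]) / d[ax]))
    }
    tmin <- max(ts[, 1]); tmax <- min(ts[, 2])
    if (tmax - tmin < minFrac * size) next
    t1 <- tmin + runif(1, 0, 0.2) * (tmax - tmin)
    t2 <- tmax - runif(1, 0, 0.2) * (tmax - tmin)
    if (t2 - t1 < minFrac * size) next
    a <- p + t1 * d
    b <- p + t2 * d
    if (curvature <= 0) return(rbind(a, b))
    perp <- c(-d[2], d[1])
    ctrl <- (a + b) / 2 + runif(1, -curvature, curvature) * perp
    tt <- seq(0, 1, length.out = 33)
    return(cbind((1 - tt)^2 * a[1] + 2 * tt * (1 - tt) * ctrl[1] + tt^2 * b[1],
                 (1 - tt)^2 * a[2] + 2 * tt * (1 - tt) * ctrl[2] + tt^2 * b[2]))
  }
}

# cumulative arc length at each vertex of a polyline
.arcLengths <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
}

# all transversal intersections between two polylines; returns a data.frame
# with the point and the arc position along each polyline. Hits closer than
# 1.5 px (e.g. a crossing exactly at a sampling vertex) are merged.
.polylineIntersections <- function(pa, pb) {
  arcs_a <- .arcLengths(pa)
  arcs_b <- .arcLengths(pb)
  out <- NULL
  for (i in seq_len(nrow(pa) - 1L)) {
    p1 <- pa[i, ]; r <- pa[i + 1L, ] - p1
    for (j in seq_len(nrow(pb) - 1L)) {
      q1 <- pb[j, ]; s <- pb[j + 1L, ] - q1
      denom <- r[1] * s[2] - r[2] * s[1]
      if (abs(denom) < 1e-12) next
      w <- q1 - p1
      t <- (w[1] * s[2] - w[2] * s[1]) / denom
      u <- (w[1] * r[2] - w[2] * r[1]) / denom
      if (t < -1e-9 || t > 1 + 1e-9 || u < -1e-9 || u > 1 + 1e-9) next
      pt <- p1 + t * r
      out <- rbind(out, c(pt[1], pt[2],
                          arcs_a[i] + t * sqrt(sum(r^2)),
                          arcs_b[j] + u * sqrt(sum(s^2))))
    }
  }
  if (is.null(out)) return(NULL)
  out <- as.data.frame(out)
  names(out) <- c("row", "col", "arc_a", "arc_b")
  # merge near-duplicates
  keep <- rep(TRUE, nrow(out))
  if (nrow(out) > 1L)
    for (i in 2:nrow(out))
      for (j in 1:(i - 1L))
        if (keep[j] &&
            sqrt((out$row[i] - out$row[j])^2 +
                 (out$col[i] - out$col[j])^2) < 1.5)
          keep[i] <- FALSE
  out[keep, , drop = FALSE]
}

#' Build the exact branch-topology graph of a set of fibre polylines
#'
#' Nodes are fibre endpoints and pairwise fibre intersections; every fibre
#' contributes one graph edge per span between consecutive nodes along its
#' arc length. The true branch count is the total number of edges: two
#' straight fibres crossing once give 1 junction, 4 endpoints and 4
#' branches.
#'
#' @param segments list of (row, col) polyline matrices, one per fibre.
#' @param widths per-fibre Gaussian cross-section sigma (px), recycled.
#' @param imageSize image side in px, used to rasterise `trueMask`.
#' @return a [GroundTruth-class].
#' @export
groundTruthFromSegments <- function(segments, widths, imageSize) {
  nf <- length(segments)
  widths <- rep_len(widths, max(nf, 1L))
  nodes <- NULL
  addNode <- function(nodes, row, col, type) {
    rbind(nodes, data.frame(node = (if (is.null(nodes)) 1L else
      nrow(nodes) + 1L), row = row, col = col, type = type))
  }
  # endpoints
  endNode <- matrix(NA_integer_, nrow = max(nf, 1L), ncol = 2L)
  for (f in seq_len(nf)) {
    p <- segments[[f]]
    nodes <- addNode(nodes, p[1L, 1L], p[1L, 2L], "endpoint")
    endNode[f, 1L] <- nrow(nodes)
    nodes <- addNode(nodes, p[nrow(p), 1L], p[nrow(p), 2L], "endpoint")
    endNode[f, 2L] <- nrow(nodes)
  }
  # junctions, with arc positions per incident fibre
  juncOn <- vector("list", nf)  # per fibre: data.frame(arc, node)
  if (nf >= 2L)
    for (a in 1:(nf - 1L))
      for (b in (a + 1L):nf) {
        hits <- .polylineIntersections(segments[[a]], segments[[b]])
        if (is.null(hits) || !nrow(hits)) next
        for (h in seq_len(nrow(hits))) {
          nodes <- addNode(nodes, hits$row[h], hits$col[h], "junction")
          id <- nrow(nodes)
          juncOn[[a]] <- rbind(juncOn[[a]],
                               data.frame(arc = hits$arc_a[h], node = id))
          juncOn[[b]] <- rbind(juncOn[[b]],
                               data.frame(arc = hits$arc_b[h], node = id))
        }
      }
  edges <- NULL
  for (f in seq_len(nf)) {
    total <- max(.arcLengths(segments[[f]]))
    j <- juncOn[[f]]
    ordered <- if (is.null(j)) integer(0) else j$node[order(j$arc)]
    chain <- c(endNode[f, 1L], ordered, endNode[f, 2L])
    for (k in seq_len(length(chain) - 1L))
      edges <- rbind(edges, data.frame(fibre = f, from_node = chain[k],
                                       to_node = chain[k + 1L]))
  }
  if (is.null(nodes))
    nodes <- data.frame(node = integer(0), row = numeric(0),
                        col = numeric(0), type = character(0))
  if (is.null(edges))
    edges <- data.frame(fibre = integer(0), from_node = integer(0),
                        to_node = integer(0))
  mask <- if (nf) {
    prox <- cpp_render_fibres(imageSize, imageSize, segments,
                              as.numeric(widths), rep(1, nf))
    prox >= exp(-2) - 1e-9   # within two cross-section sigmas
  } else matrix(FALSE, imageSize, imageSize)
  new("GroundTruth", segments = segments, nodes = nodes, edges = edges,
      trueBranchCount = nrow(edges), trueMask = mask)
}

# paint fibres, add background and noise, clip and round to counts
.composeImage <- function(segments, widths, spec, wellId) {
  nf <- length(segments)
  field <- if (nf)
    cpp_render_fibres(spec@imageSize, spec@imageSize, segments,
                      rep_len(widths, nf), rep(spec@fibreIntensity, nf))
  else matrix(0, spec@imageSize, spec@imageSize)
  px <- spec@backgroundLevel + field
  if (spec@noiseSigma > 0)
    px <- px + matrix(rnorm(length(px), 0, spec@noiseSigma),
                      nrow = nrow(px))
  px <- round(pmin(pmax(px, 0), 2^spec@bitDepth - 1))
  WellImage(px, bitDepth = spec@bitDepth, wellId = wellId)
}

#' Generate a synthetic fibrillar-matrix well image with ground truth
#'
#' Major and mesh fibres are drawn as smoothed polylines with Gaussian
#' cross-sections onto a constant background with additive Gaussian noise
#' (clipped to the bit-depth range). The returned ground truth holds the
#' exact fibre graph and rasterised foreground.
#'
#' @param spec a [fibrilSpec()].
#' @param wellId well id stamped on the image.
#' @return `list(well = WellImage, truth = GroundTruth)`.
#' @export
generateFibrilImage <- function(spec, wellId = "A01") {
  validObject(spec)
  withSeed(spec@seed, {
    margin <- max(6, 4 * max(spec@majorWidthPx, spec@meshWidthPx)) +
      spec@curvature
    if (2 * margin >= spec@imageSize - 2)
      stopTyped("ecms_image_too_small",
                "imageSize %d too small for widths/curvature (margin %.1f)",
                spec@imageSize, margin)
    nf <- spec@nMajorFibres + spec@nMeshFibres
    segments <- vector("list", nf)
    widths <- c(rep(spec@majorWidthPx, spec@nMajorFibres),
                rep(spec@meshWidthPx, spec@nMeshFibres))
    for (f in seq_len(nf))
      segments[[f]] <- .randomFibre(spec@imageSize, margin, spec@curvature)
    truth <- groundTruthFromSegments(segments, widths, spec@imageSize)
    well <- .composeImage(segments, widths, spec, wellId)
    list(well = well, truth = truth)
  })
}

#' Derive the altered (sparse, thick-fibril) phenotype from a control spec
#'
#' The altered network keeps the major fibres but has a quarter of the mesh
#' fibres (rounded) at twice the width, mimicking matrix that is more
#' sparsely dispersed, composed of thicker fibrils and less extensively
#' connected. Fewer fibres mean fewer crossings, hence fewer branches by
#' construction.
#'
#' @param base control [FibrilSpec-class].
#' @param meshFactor,widthFactor alteration factors.
#' @return `list(control = base, altered = FibrilSpec)`.
#' @export
generatePhenotypePair <- function(base, meshFactor = 0.25, widthFactor = 2) {
  validObject(base)
  altered <- base
  altered@nMeshFibres <- as.integer(round(base@nMeshFibres * meshFactor))
  altered@meshWidthPx <- base@meshWidthPx * widthFactor
  altered@majorWidthPx <- base@majorWidthPx * widthFactor
  validObject(altered)
  list(control = base, altered = altered)
}

# -- clean, well-separated networks for recovery studies ---------------------

.pointSegDist <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / max(sum(ab^2), 1e-12)
  t <- min(max(t, 0), 1)
  sqrt(sum((a + t * ab - p)^2))
}

.segSegDist <- function(a1, a2, b1, b2) {
  min(.pointSegDist(a1, b1, b2), .pointSegDist(a2, b1, b2),
      .pointSegDist(b1, a1, a2), .pointSegDist(b2, a1, a2))
}

#' Generate a clean synthetic network for branch-recovery studies
#'
#' Straight, noiseless fibres are rejection-sampled so that every pair
#' either crosses transversally (>= `minAngleDeg`) or stays far apart, and
#' all nodes (junctions and endpoints) are well separated. Under these
#' conditions the image pipeline should recover the true branch count
#' almost exactly, which is what the recovery tests assert.
#'
#' @param seed integer seed.
#' @param nFibres number of fibres.
#' @param imageSize image side (px).
#' @param widthPx fibre cross-section sigma (px).
#' @param fibreIntensity,backgroundLevel native counts.
#' @param minAngleDeg minimum crossing angle.
#' @param minNodeSep minimum distance between nodes (px).
#' @param wellId well id stamped on the image.
#' @return `list(well = WellImage, truth = GroundTruth)`.
#' @export
generateCleanNetwork <- function(seed, nFibres = 4, imageSize = 384,
                                 widthPx = 2, fibreIntensity = 120,
                                 backgroundLevel = 100, minAngleDeg = 35,
                                 minNodeSep = 30, wellId = "A01") {
  spec <- fibrilSpec(nMajorFibres = nFibres, majorWidthPx = widthPx,
                     nMeshFibres = 0, meshWidthPx = widthPx,
                     fibreIntensity = fibreIntensity,
                     backgroundLevel = backgroundLevel, noiseSigma = 0,
                     curvature = 0, imageSize = imageSize, seed = seed)
  margin <- max(20, 6 * widthPx)
  farDist <- 10 * widthPx + 4
  withSeed(seed, {
    for (attempt in 1:50) {
      fibres <- list()
      ok <- TRUE
      tries <- 0
      while (length(fibres) < nFibres && tries < 500) {
        tries <- tries + 1
        cand <- .randomFibre(imageSize, margin, 0, minFrac = 0.4)
        if (.cleanCompatible(cand, fibres, minAngleDeg, minNodeSep, farDist))
          fibres[[length(fibres) + 1L]] <- cand
      }
      if (length(fibres) == nFibres) { ok <- TRUE; break }
      ok <- FALSE
    }
    if (!ok) stop("could not place a clean network; relax the constraints")
    truth <- groundTruthFromSegments(fibres, widthPx, imageSize)
    well <- .composeImage(fibres, rep(widthPx, nFibres), spec, wellId)
    list(well = well, truth = truth)
  })
}

# is a candidate straight fibre compatible with the accepted ones?
.cleanCompatible <- function(cand, fibres, minAngleDeg, minNodeSep,
                             farDist) {
  allNodes <- rbind(cand[1, ], cand[2, ])
  crossPts <- NULL
  dc <- cand[2, ] - cand[1, ]
  for (f in fibres) {
    allNodes <- rbind(allNodes, f[1, ], f[2, ])
    hits <- .polylineIntersections(cand, f)
    if (!is.null(hits) && nrow(hits)) {
      if (nrow(hits) > 1) return(FALSE)
      df <- f[2, ] - f[1, ]
      cosang <- abs(sum(dc * df)) / sqrt(sum(dc^2) * sum(df^2))
      if (cosang > cos(minAngleDeg * pi / 180)) return(FALSE)
      crossPts <- rbind(crossPts, c(hits$row[1], hits$col[1]))
    } else {
      if (.segSegDist(cand[1, ], cand[2, ], f[1, ], f[2, ]) < farDist)
        return(FALSE)
    }
    # endpoints must not hover near the other fibre's body
    for (e in 1:2) {
      if (.pointSegDist(cand[e, ], f[1, ], f[2, ]) < minNodeSep) return(FALSE)
      if (.pointSegDist(f[e, ], cand[1, ], cand[2, ]) < minNodeSep)
        return(FALSE)
    }
  }
  pts <- rbind(allNodes, crossPts)
  if (nrow(pts) > 1) {
    d <- as.matrix(stats::dist(pts))
    diag(d) <- Inf
    if (min(d) < minNodeSep) return(FALSE)
  }
  TRUE
}

#' The two-crossing-fibre reference well
#'
#' A deterministic fixture: two straight fibres crossing once near the
#' image centre (1 junction, 4 endpoints), whose true branch count is 4.
#'
#' @param imageSize,widthPx,fibreIntensity,backgroundLevel as in
#'   [generateCleanNetwork()].
#' @return `list(well = WellImage, truth = GroundTruth)`.
#' @export
crossingFibreWell <- function(imageSize = 256, widthPx = 2,
                              fibreIntensity = 120, backgroundLevel = 100) {
  s <- imageSize
  segments <- list(
    rbind(c(0.47 * s, 0.12 * s), c(0.53 * s, 0.88 * s)),   # near-horizontal
    rbind(c(0.12 * s, 0.55 * s), c(0.88 * s, 0.45 * s)))   # near-vertical
  spec <- fibrilSpec(nMajorFibres = 2, majorWidthPx = widthPx,
                     nMeshFibres = 0, meshWidthPx = widthPx,
                     fibreIntensity = fibreIntensity,
                     backgroundLevel = backgroundLevel, noiseSigma = 0,
                     curvature = 0, imageSize = s, seed = 1)
  truth <- groundTruthFromSegments(segments, widthPx, s)
  well <- withSeed(1, .composeImage(segments, rep(widthPx, 2), spec, "A01"))
  list(well = well, truth = truth)
}

# -- plate-level dose-response readouts --------------------------------------

#' Construct a dose-response generator specification
#'
#' Defaults emulate a pro-fibrotic stimulation curve on the normalised ECM
#' intensity scale: a > 3-fold window (bottom 1, top 4), half-maximal
#' stimulation at 15 ng/mL, Hill slope 1.3, 10% multiplicative noise, a
#' half-log dose series of 8 concentrations with 4 replicates each.
#'
#' @param bottom,top,ec50,hill 4PL parameters.
#' @param cv multiplicative (log-normal, mean-one) noise CV.
#' @param concentrations dose series, same units as `ec50`.
#' @param nReplicates replicates per concentration.
#' @param viabilityCv CV of the viability signal around 1.
#' @param seed integer seed.
#' @return a [DoseResponseSpec-class].
#' @export
doseResponseSpec <- function(bottom = 1, top = 4, ec50 = 15, hill = 1.3,
                             cv = 0.1,
                             concentrations = c(0.1, 0.3, 1, 3, 10, 30,
                                                100, 300),
                             nReplicates = 4, viabilityCv = 0.05, seed = 1) {
  new("DoseResponseSpec", bottom = bottom, top = top, ec50 = ec50,
      hill = hill, cv = cv, concentrations = as.numeric(concentrations),
      nReplicates = as.integer(nReplicates), viabilityCv = viabilityCv,
      seed = as.integer(seed))
}

#' Simulate per-well dose-response readouts
#'
#' ECM signals are `4PL(concentration)` times mean-one log-normal noise of
#' the requested CV; viability signals are drawn near 1. With `cv = 0` the
#' signals lie exactly on the curve.
#'
#' @param spec a [doseResponseSpec()].
#' @return data.frame with `concentration`, `replicate`, `ecm_signal`,
#'   `viability_signal`.
#' @export
generatePlateReadouts <- function(spec) {
  validObject(spec)
  withSeed(spec@seed, {
    conc <- rep(spec@concentrations, each = spec@nReplicates)
    repl <- rep(seq_len(spec@nReplicates), length(spec@concentrations))
    mu <- fourPL(conc, spec@bottom, spec@top, spec@ec50, spec@hill)
    sl <- sqrt(log(1 + spec@cv^2))
    noise <- rlnorm(length(conc), meanlog = -sl^2 / 2, sdlog = sl)
    sv <- sqrt(log(1 + spec@viabilityCv^2))
    viab <- rlnorm(length(conc), meanlog = -sv^2 / 2, sdlog = sv)
    data.frame(concentration = conc, replicate = repl,
               ecm_signal = mu * noise, viability_signal = viab)
  })
}
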