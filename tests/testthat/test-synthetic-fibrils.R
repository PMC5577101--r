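test_that("an empty spec yields a background-only image with zero branches", {
  spec <- fibrilSpec(nMajorFibres = 0, nMeshFibres = 0, noiseSigma = 0,
                     imageSize = 64)
  g <- generateFibrilImage(spec)
  expect_true(all(pixels(g$well) == 100))
  expect_identical(trueBranchCount(g$truth), 0L)
  expect_false(any(g$truth@trueMask))
})

test_that("two crossing straight fibres give 1 junction, 4 endpoints, 4 branches", {
  segs <- list(rbind(c(10, 10), c(50, 50)), rbind(c(50, 10), c(10, 50)))
  gt <- groundTruthFromSegments(segs, widths = 1.5, imageSize = 64)
  expect_identical(sum(gt@nodes$type == "junction"), 1L)
  expect_identical(sum(gt@nodes$type == "endpoint"), 4L)
  expect_identical(trueBranchCount(gt), 4L)
  # crossing point is at the segment intersection
  j <- gt@nodes[gt@nodes$type == "junction", ]
  expect_equal(c(j$row, j$col), c(30, 30))
})

test_that("ground truth counts are invariant under translation of all segments", {
  g <- generateFibrilImage(fibrilSpec(nMajorFibres = 2, nMeshFibres = 6,
                                      imageSize = 200, seed = 11))
  segs <- g$truth@segments
  shifted <- lapply(segs, function(p) p + 7.3)
  gt2 <- groundTruthFromSegments(shifted, widths = 1.5, imageSize = 256)
  expect_identical(trueBranchCount(gt2), trueBranchCount(g$truth))
})

test_that("adding a crossing fibre never decreases the branch count", {
  base <- list(rbind(c(20, 10), c(20, 90)), rbind(c(60, 10), c(60, 90)))
  gt0 <- groundTruthFromSegments(base, 1.5, 100)
  withNew <- c(base, list(rbind(c(10, 50), c(90, 50))))
  gt1 <- groundTruthFromSegments(withNew, 1.5, 100)
  expect_gte(trueBranchCount(gt1), trueBranchCount(gt0))
  # here the new fibre crosses both: 2 + 2*1 existing splits + 3 new spans
  expect_identical(trueBranchCount(gt1), 7L)
})

test_that("the rasterised mask contains every polyline pixel", {
  g <- generateFibrilImage(fibrilSpec(nMajorFibres = 3, nMeshFibres = 8,
                                      imageSize = 160, seed = 4))
  mask <- g$truth@trueMask
  for (p in g$truth@segments) {
    # sample points along each polyline and check their nearest pixels
    for (k in seq_len(nrow(p) - 1)) {
      for (a in seq(0, 1, by = 0.2)) {
        pt <- round(p[k, ] * (1 - a) + p[k + 1, ] * a) + 1
        expect_true(mask[pt[1], pt[2]])
      }
    }
  }
})

test_that("identical spec and seed reproduce images and graphs bit-exactly", {
  spec <- fibrilSpec(seed = 42, imageSize = 128, nMeshFibres = 6)
  g1 <- generateFibrilImage(spec)
  g2 <- generateFibrilImage(spec)
  expect_identical(pixels(g1$well), pixels(g2$well))
  expect_identical(g1$truth@edges, g2$truth@edges)
  g3 <- generateFibrilImage(fibrilSpec(seed = 43, imageSize = 128,
                                       nMeshFibres = 6))
  expect_false(identical(pixels(g1$well), pixels(g3$well)))
})

test_that("the altered phenotype has fewer, wider fibres and fewer true branches", {
  base <- fibrilSpec(nMeshFibres = 40, majorWidthPx = 2)
  pair <- generatePhenotypePair(base)
  expect_identical(pair$altered@nMeshFibres, 10L)
  expect_equal(pair$altered@majorWidthPx, 4)
  expect_equal(pair$altered@meshWidthPx, base@meshWidthPx * 2)
  # paired over 20 seeds the altered ground truth always has fewer branches
  small <- generatePhenotypePair(fibrilSpec(nMeshFibres = 16,
                                            imageSize = 256))
  cmp <- vapply(1:20, function(s) {
    sc <- small$control; sc@seed <- 500L + s
    sa <- small$altered; sa@seed <- 500L + s
    c(trueBranchCount(generateFibrilImage(sc)$truth),
      trueBranchCount(generateFibrilImage(sa)$truth))
  }, numeric(2))
  expect_true(all(cmp[2, ] < cmp[1, ]))
})

test_that("too-small images for the requested widths are rejected", {
  expect_error(fibrilSpec(imageSize = 16, majorWidthPx = 3), "too small")
  expect_error(generateFibrilImage(fibrilSpec(imageSize = 70,
                                              curvature = 40)),
               class = "ecms_image_too_small")
})

test_that("plate readouts follow the 4PL exactly when noise is off", {
  spec <- doseResponseSpec(cv = 0, viabilityCv = 0)
  ro <- generatePlateReadouts(spec)
  expect_equal(ro$ecm_signal,
               fourPL(ro$concentration, 1, 4, 15, 1.3))
  expect_true(all(ro$viability_signal == 1))
  # the midpoint identity: response at x = ec50 is (top + bottom) / 2
  mid <- generatePlateReadouts(doseResponseSpec(cv = 0, viabilityCv = 0,
                                                concentrations = 15))
  expect_equal(unique(mid$ecm_signal), (4 + 1) / 2)
  # determinism under the seed, and mean-one multiplicative noise
  s1 <- generatePlateReadouts(doseResponseSpec(seed = 9))
  s2 <- generatePlateReadouts(doseResponseSpec(seed = 9))
  expect_identical(s1, s2)
  expect_false(identical(s1$ecm_signal,
                         generatePlateReadouts(doseResponseSpec(seed = 10))$ecm_signal))
})

test_that("the clean-network generator produces separated, recoverable layouts", {
  g <- generateCleanNetwork(seed = 3, nFibres = 3, imageSize = 256)
  nodes <- g$truth@nodes
  d <- as.matrix(dist(nodes[, c("row", "col")]))
  diag(d) <- Inf
  expect_gte(min(d), 30)
  expect_true(all(pixels(g$well) >= 100))
})
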