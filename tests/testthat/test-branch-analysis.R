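test_that("adaptive segmentation follows the local-mean-plus-offset rule", {
  # constant image: nothing exceeds its own local mean + 1
  w <- wellFromMatrix(matrix(100, 16, 16))
  expect_false(any(maskPixels(adaptiveSegment(w, 5, 1))))
  # a single bright pixel dominates its local mean
  px <- matrix(0, 60, 60); px[30, 30] <- 1000
  m <- maskPixels(adaptiveSegment(wellFromMatrix(px), 51, 10))
  expect_true(m[30, 30])
  # 8x8 bright stripe: exact agreement with the per-pixel brute force rule
  px <- matrix(10, 8, 8); px[, 4:5] <- 200
  w <- wellFromMatrix(px)
  got <- maskPixels(adaptiveSegment(w, 5, 2.37))
  expect_identical(got, px > bfLocalMean(px, 5) + 2.37)
  # parameter validation
  expect_error(adaptiveSegment(w, 4, 1), "odd")
  expect_error(adaptiveSegment(w, 1, 1), "odd|>= 3")
})

test_that("skeletonization keeps thin structures and empties cleanly", {
  # a 1-px line is already a skeleton
  line <- matrix(FALSE, 9, 9); line[5, 2:8] <- TRUE
  sk <- skeletonizeMask(line)
  expect_identical(skeletonMask(sk), line)
  # empty mask: empty skeleton, all distances zero
  empty <- matrix(FALSE, 6, 6)
  sk0 <- skeletonizeMask(empty)
  expect_false(any(skeletonMask(sk0)))
  expect_true(all(distanceMap(sk0) == 0))
  # a filled disk thins to something thin, contained, same component count
  disk <- outer(1:21, 1:21, function(i, j) (i - 11)^2 + (j - 11)^2 <= 49)
  skd <- skeletonizeMask(disk)
  s <- skeletonMask(skd)
  expect_true(all(disk[s]))
  expect_false(hasTwoByTwoBlock(s))
  expect_identical(max(bfComponents(s)), max(bfComponents(disk)))
  # distances are positive inside the foreground, zero outside
  expect_true(all(distanceMap(skd)[disk] > 0))
  expect_true(all(distanceMap(skd)[!disk] == 0))
})

test_that("skeleton topology is preserved on random multi-component masks", {
  for (s in 1:25) {
    m <- randomCountImage(12, 12, maxval = 99, seed = 100 + s) < 35
    sk <- skeletonMask(skeletonizeMask(m))
    expect_true(all(m[sk]))
    expect_false(hasTwoByTwoBlock(sk))
    expect_identical(max(bfComponents(sk)), max(bfComponents(m)))
  }
})

test_that("marker extraction splits skeleton paths at junctions", {
  img <- wellFromMatrix(matrix(100, 15, 15))
  # straight segment: one marker
  line <- matrix(FALSE, 15, 15); line[8, 3:13] <- TRUE
  mk <- extractMarkerRegions(new("Skeleton", skeletonMask = line,
                                 distance = matrix(0, 15, 15)), img)
  expect_identical(nrow(markerStats(mk)), 1L)
  expect_equal(markerStats(mk)$mean_intensity, 100)
  # "+" shape: the centre has 4 neighbours, its flanks 4 as well; removing
  # the junction cluster leaves the four arms
  plus <- matrix(FALSE, 15, 15)
  plus[8, 3:13] <- TRUE; plus[3:13, 8] <- TRUE
  mkp <- extractMarkerRegions(new("Skeleton", skeletonMask = plus,
                                  distance = matrix(0, 15, 15)), img)
  expect_identical(nrow(markerStats(mkp)), 4L)
  lab <- markerLabels(mkp)
  expect_true(all(sort(unique(lab[lab > 0])) == 1:4))
  # empty skeleton: no markers
  mk0 <- extractMarkerRegions(new("Skeleton",
                                  skeletonMask = matrix(FALSE, 5, 5),
                                  distance = matrix(0, 5, 5)),
                              wellFromMatrix(matrix(0, 5, 5)))
  expect_identical(nrow(markerStats(mk0)), 0L)
})

test_that("flood growth assigns the reachable foreground to markers", {
  # markers == mask: nothing to grow
  px <- randomCountImage(8, 8, seed = 5)
  mask <- matrix(FALSE, 8, 8); mask[4, 2:7] <- TRUE
  img <- wellFromMatrix(px)
  segm <- new("SegmentationMask", mask = mask, params = list())
  sk <- new("Skeleton", skeletonMask = mask, distance = matrix(0, 8, 8))
  mk <- extractMarkerRegions(sk, img)
  bs <- growBranches(img, segm, mk)
  expect_identical(branchLabels(bs) > 0, mask)
  # one marker inside a single component grows to the whole component
  blob <- matrix(FALSE, 12, 12); blob[3:10, 3:10] <- TRUE
  seed <- matrix(0L, 12, 12); seed[6, 6] <- 1L
  mk1 <- new("MarkerRegions", labels = seed,
             markerStats = data.frame(label = 1L, pixel_count = 1L,
                                      mean_intensity = px[6, 6] * 1.0))
  px2 <- randomCountImage(12, 12, seed = 6)
  bs1 <- growBranches(wellFromMatrix(px2),
                      new("SegmentationMask", mask = blob, params = list()),
                      mk1)
  expect_identical(branchLabels(bs1) > 0, blob)
  # foreground outside any marker's component stays unassigned
  two <- blob; two[1, 12] <- TRUE
  bs2 <- growBranches(wellFromMatrix(px2),
                      new("SegmentationMask", mask = two, params = list()),
                      mk1)
  expect_identical(branchLabels(bs2)[1, 12], 0L)
})

test_that("priority flood matches the brute-force queue simulation", {
  for (s in 1:6) {
    px <- randomCountImage(10, 10, maxval = 500, seed = 200 + s)
    mask <- matrix(TRUE, 10, 10)
    markers <- matrix(0L, 10, 10)
    markers[2, 2] <- 1L; markers[9, 9] <- 2L
    got <- growBranches(wellFromMatrix(px),
                        new("SegmentationMask", mask = mask, params = list()),
                        new("MarkerRegions", labels = markers,
                            markerStats = data.frame(
                              label = 1:2, pixel_count = 1L,
                              mean_intensity = c(px[2, 2], px[9, 9]))))
    expect_identical(branchLabels(got), bfPriorityFlood(px, mask, markers))
  }
  # intensity ties resolve to the lowest marker label
  flat <- matrix(7, 5, 5)
  markers <- matrix(0L, 5, 5); markers[3, 1] <- 1L; markers[3, 5] <- 2L
  lab <- bfPriorityFlood(flat, matrix(TRUE, 5, 5), markers)
  expect_identical(lab, branchLabels(growBranches(
    wellFromMatrix(flat),
    new("SegmentationMask", mask = matrix(TRUE, 5, 5), params = list()),
    new("MarkerRegions", labels = markers,
        markerStats = data.frame(label = 1:2, pixel_count = 1L,
                                 mean_intensity = 7)))))
  expect_gte(sum(lab == 1L), sum(lab == 2L))
})

test_that("the inclusion band retains branches within [-50, +150] of the marker mean", {
  mkBranch <- function(branchMean, markerMean, area = 20) {
    new("BranchSet", branchLabels = matrix(1L, 5, 5),
        branches = data.frame(marker_label = 1L, area_px = area,
                              mean_intensity = branchMean,
                              marker_mean = markerMean, retained = NA),
        band = c(lower = 50, upper = 150), pixelSizeUm = NA_real_)
  }
  expect_true(branchTable(filterBranches(mkBranch(300, 300)))$retained)
  expect_true(branchTable(filterBranches(mkBranch(450, 300)))$retained)   # +150
  expect_false(branchTable(filterBranches(mkBranch(451, 300)))$retained)  # +151
  expect_true(branchTable(filterBranches(mkBranch(250, 300)))$retained)   # -50
  expect_false(branchTable(filterBranches(mkBranch(249, 300)))$retained)
  expect_error(filterBranches(mkBranch(300, 300), upperOffset = -1),
               "non-negative")
  # branches below the minimum area are discarded outright, not audited
  small <- filterBranches(mkBranch(300, 300, area = 3))
  expect_identical(nrow(branchTable(small)), 0L)
  expect_true(all(branchLabels(small) == 0L))
})

test_that("branch summaries count retained branches and average their areas", {
  bs <- new("BranchSet", branchLabels = matrix(0L, 2, 2),
            branches = data.frame(
              marker_label = 1:5, area_px = c(10, 20, 7, 8, 9),
              mean_intensity = 100, marker_mean = 100,
              retained = c(TRUE, TRUE, FALSE, FALSE, TRUE)),
            band = c(lower = 50, upper = 150), pixelSizeUm = NA_real_)
  s <- summarizeBranches(bs, wellId = "D07")
  expect_identical(s$n_branches, 3L)
  expect_equal(s$mean_branch_area_px2, 13)
  s2 <- summarizeBranches(bs, pixelSizeUm = 2)
  expect_equal(s2$mean_branch_area_um2, 13 * 4)
  none <- bs; none@branches$retained <- FALSE
  s0 <- summarizeBranches(none)
  expect_identical(s0$n_branches, 0L)
  expect_true(is.na(s0$mean_branch_area_px2))
  areas <- new("BranchSet", branchLabels = matrix(0L, 2, 2),
               branches = data.frame(marker_label = 1:2, area_px = c(10, 20),
                                     mean_intensity = 1, marker_mean = 1,
                                     retained = TRUE),
               band = c(lower = 50, upper = 150), pixelSizeUm = NA_real_)
  expect_equal(summarizeBranches(areas)$mean_branch_area_px2, 15)
})

test_that("the full pipeline handles blank wells and the crossing fixture", {
  blank <- lapply(0:3, function(i)
    FieldImage(matrix(100, 64, 64), wellId = "A01", fieldIndex = i))
  s <- analyzeWell(blank)
  expect_identical(s$n_branches, 0L)
  cf <- crossingFibreWell()
  expect_identical(trueBranchCount(cf$truth), 4L)
  expect_identical(analyzeWell(cf$well)$n_branches, 4L)
})

test_that("the pipeline is deterministic and invariant to translation and rotation", {
  g <- generateCleanNetwork(seed = 7, nFibres = 3, imageSize = 256)
  s1 <- analyzeWell(g$well)
  s2 <- analyzeWell(g$well)
  expect_identical(s1, s2)
  px <- pixels(g$well)
  # translation by 9 px (margin-safe: the generator keeps a >= 20 px border)
  shifted <- px
  shifted[10:nrow(px), 10:ncol(px)] <- px[1:(nrow(px) - 9), 1:(ncol(px) - 9)]
  shifted[1:9, ] <- 100; shifted[, 1:9] <- 100
  expect_identical(analyzeWell(wellFromMatrix(shifted))$n_branches,
                   s1$n_branches)
  # 90 degree rotation
  rot <- t(px)[, nrow(px):1]
  expect_identical(analyzeWell(wellFromMatrix(rot))$n_branches,
                   s1$n_branches)
})
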