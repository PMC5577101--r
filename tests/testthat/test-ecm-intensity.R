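test_that("total intensity above a fixed threshold sums strict exceedances", {
  m <- matrix(c(0, 10, 20, 30, 40, 50, 60, 70, 80), 3, 3, byrow = TRUE)
  w <- wellFromMatrix(m)
  expect_equal(totalIntensityAboveThreshold(w, 40), 260)  # 50+60+70+80
  expect_equal(totalIntensityAboveThreshold(w, 1000), 0)
  pos <- wellFromMatrix(matrix(1:9, 3, 3))
  expect_equal(totalIntensityAboveThreshold(pos, 0), sum(1:9))
  # monotone non-increasing in the threshold
  img <- wellFromMatrix(randomCountImage(20, 20, seed = 3))
  tots <- vapply(seq(0, 1000, by = 50),
                 function(th) totalIntensityAboveThreshold(img, th),
                 numeric(1))
  expect_true(all(diff(tots) <= 0))
})

test_that("viability and radioactivity normalisations are plain ratios with guards", {
  expect_equal(normalizeToViability(100, 1), 100)
  expect_equal(normalizeToViability(200, 2), 100)
  expect_equal(normalizeToViability(0, 5), 0)
  expect_error(normalizeToViability(10, 0), class = "ecms_dead_well")
  expect_equal(normalizeRadioactive(500, 1000), 0.5)
  expect_equal(normalizeRadioactive(0, 1000), 0)
  expect_equal(normalizeRadioactive(3 * 7, 5 * 7),
               normalizeRadioactive(3, 5))
  expect_error(normalizeRadioactive(10, 0), class = "ecms_dead_well")
})

test_that("percent inhibition anchors controls at 0% and 100% and is affine-invariant", {
  expect_equal(percentInhibition(10, 10, 2), 0)
  expect_equal(percentInhibition(2, 10, 2), 100)
  expect_equal(percentInhibition(6, 10, 2), 50)
  expect_error(percentInhibition(5, 7, 7), class = "ecms_no_window")
  for (s in 1:5) {
    v <- localSeed(s, runif(3, 0, 10))
    a <- localSeed(s + 10, runif(1, 0.1, 5))
    b <- localSeed(s + 20, runif(1, -3, 3))
    expect_equal(percentInhibition(a * v[1] + b, a * v[2] + b, a * v[3] + b),
                 percentInhibition(v[1], v[2], v[3]))
  }
})

test_that("fold change is a guarded ratio", {
  expect_equal(foldChange(3, 1), 3)
  expect_equal(foldChange(1, 1), 1)
  expect_equal(foldChange(1, 4), 0.25)
  expect_error(foldChange(1, 0), class = "ecms_bad_control")
})

test_that("delta-delta-Ct references the housekeeper panel and a calibrator", {
  hk <- c(B2M = 20, HMBS = 21, TBP = 22)
  cal <- ctRecord("ctrl", targetCt = 25, housekeeperCts = hk)
  same <- ctRecord("s1", targetCt = 25, housekeeperCts = hk)
  expect_equal(deltaDeltaCt(same, cal), 1)
  # one cycle earlier = doubled expression
  up <- ctRecord("s2", targetCt = 24, housekeeperCts = hk)
  expect_equal(deltaDeltaCt(up, cal), 2)
  # the housekeeper reference is the arithmetic mean of the Cts
  expect_equal(mean(hk), 21)
  # plate-offset invariance: adding a constant to every Ct changes nothing
  off <- 1.7
  upShift <- ctRecord("s2", targetCt = 24 + off, housekeeperCts = hk + off)
  calShift <- ctRecord("ctrl", targetCt = 25 + off, housekeeperCts = hk + off)
  expect_equal(deltaDeltaCt(upShift, calShift), deltaDeltaCt(up, cal))
  # missing housekeeper errors
  broken <- ctRecord("s3", targetCt = 24,
                     housekeeperCts = c(B2M = 20, HMBS = 21, TBP = NA))
  expect_error(deltaDeltaCt(broken, cal),
               class = "ecms_missing_housekeeper")
})

test_that("the fixed threshold estimate is background mode plus three sigma", {
  px <- matrix(100, 50, 50)
  px[1:5, 1:5] <- 500  # a bright patch should not move the mode
  w <- wellFromMatrix(px)
  th <- estimateFixedThreshold(w)
  expect_gte(th, 100)
  expect_lt(th, 500)
  # pure constant background: threshold collapses to the mode
  expect_equal(estimateFixedThreshold(wellFromMatrix(matrix(7, 10, 10))), 7)
})
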