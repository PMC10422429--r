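test_that("radius queries match a brute-force scan and handle the empty index", {
  emptyIdx <- buildMotionIndex(data.frame(x = integer(), y = integer(),
                                          w = integer(), h = integer(),
                                          area = numeric()))
  expect_identical(queryRadius(emptyIdx, c(10, 10), 1000), integer())

  one <- data.frame(x = 98, y = 98, w = 4, h = 4, area = 1000)  # center (100, 100)
  idx <- buildMotionIndex(one)
  expect_identical(queryRadius(idx, c(100, 149), 50), 1L)   # distance 49
  expect_identical(queryRadius(idx, c(100, 151), 50), integer())

  set.seed(33)
  for (rep in 1:5) {
    n <- sample(c(3, 50, 500), 1)
    regions <- data.frame(x = runif(n, 0, 1900), y = runif(n, 0, 1060),
                          w = sample(10:60, n, TRUE),
                          h = sample(10:60, n, TRUE), area = 1000)
    idx <- buildMotionIndex(regions)
    centers <- regionCenter(regions)
    for (q in 1:20) {
      query <- c(runif(1, 0, 1920), runif(1, 0, 1080))
      r <- runif(1, 10, 200)
      expect_identical(queryRadius(idx, query, r),
                       bfRadiusHits(centers, query, r))
    }
  }
})

test_that("alignment includes the exact 50 px boundary and respects absence
           of regions", {
  det <- makeDetections(-2, -2, 2, 2, 0.9)  # center (0, 0)
  regionAt <- function(cx, cy) {
    data.frame(x = cx - 2, y = cy - 2, w = 4, h = 4, area = 1000)
  }
  fa <- alignDetections(det, regionAt(0, 50), AlignmentParams(50))
  expect_identical(nrow(alignedDetections(fa)), 1L)
  expect_equal(alignedDetections(fa)$matchDistance, 50)

  faOut <- alignDetections(det, regionAt(0, 50.001), AlignmentParams(50))
  expect_identical(nrow(alignedDetections(faOut)), 0L)
  expect_identical(nrow(unalignedDetections(faOut)), 1L)

  empty <- data.frame(x = integer(), y = integer(), w = integer(),
                      h = integer(), area = numeric())
  faNone <- alignDetections(det, empty, AlignmentParams(50))
  expect_identical(nrow(alignedDetections(faNone)), 0L)
  expect_identical(nrow(unalignedDetections(faNone)), 1L)
})

test_that("alignment equals brute force, conserves detections and matches the
           nearest region with deterministic ties", {
  set.seed(44)
  params <- AlignmentParams(50)
  for (rep in 1:10) {
    nR <- sample(0:40, 1); nD <- sample(0:15, 1)
    regions <- data.frame(x = runif(nR, 0, 600), y = runif(nR, 0, 400),
                          w = sample(5:50, max(nR, 1), TRUE)[seq_len(nR)],
                          h = sample(5:50, max(nR, 1), TRUE)[seq_len(nR)],
                          area = 1000)
    dets <- if (nD) {
      x1 <- runif(nD, 0, 600); y1 <- runif(nD, 0, 400)
      makeDetections(x1, y1, x1 + runif(nD, 5, 40), y1 + runif(nD, 5, 40),
                     runif(nD, 0.7, 1))
    } else makeDetections()
    fa <- alignDetections(dets, regions, params)
    expect_identical(nrow(alignedDetections(fa)) +
                       nrow(unalignedDetections(fa)), nD)
    centers <- regionCenter(regions)
    for (i in seq_len(nD)) {
      hits <- bfRadiusHits(centers, c(dets$cx[i], dets$cy[i]), 50)
      inAligned <- any(abs(alignedDetections(fa)$cx - dets$cx[i]) < 1e-12 &
                         abs(alignedDetections(fa)$cy - dets$cy[i]) < 1e-12)
      expect_identical(inAligned, length(hits) > 0)
    }
  }

  # equidistant regions: tie breaks to the lowest region index
  det <- makeDetections(48, 48, 52, 52, 0.9)  # center (50, 50)
  regions <- data.frame(x = c(28, 68), y = c(48, 48), w = 4, h = 4,
                        area = 1000)  # centers (30,50) and (70,50), both d=20
  fa <- alignDetections(det, regions, params)
  expect_identical(alignedDetections(fa)$matchedRegion, 1L)
})

test_that("growing the radius never shrinks the aligned set", {
  set.seed(55)
  regions <- data.frame(x = runif(30, 0, 600), y = runif(30, 0, 400),
                        w = 10, h = 10, area = 1000)
  x1 <- runif(12, 0, 600); y1 <- runif(12, 0, 400)
  dets <- makeDetections(x1, y1, x1 + 20, y1 + 20, runif(12, 0.7, 1))
  sizes <- vapply(c(10, 30, 50, 120, 400), function(r) {
    nrow(alignedDetections(alignDetections(dets, regions, AlignmentParams(r))))
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("the pipeline counts motion-aligned detections across frames", {
  # static video: no motion regions, so nothing aligns regardless of detections
  sc <- stationaryScene(nFrames = 6)
  det <- makeOracleDetector(sc$truth, OracleDetectorConfig(seed = 2L))
  res <- runPipeline(sc$frames, det, testMotionParams())
  expect_identical(trafficCount(res), 0L)
  nDet <- sum(vapply(frameAlignments(res), function(fa) {
    nrow(unalignedDetections(fa))
  }, numeric(1)))
  expect_identical(nDet, 5)  # detector fired every processed frame, unaligned

  expect_error(runPipeline(sc$frames[1], det, testMotionParams()),
               "at least 2 frames")

  # a bee moving through k frames is counted k times: conservation of the
  # per-frame aligned/unaligned partition against the score-filtered input
  cfg <- flyingSimConfig(seed = 12L, nBees = 2L, nFrames = 10L)
  scene <- simulateBeeScene(cfg)
  oracle <- makeOracleDetector(scene$truth, OracleDetectorConfig(seed = 6L))
  out <- runPipeline(scene$frames, oracle, testMotionParams())
  expected <- sum(scene$truth$frame >= 2)
  expect_identical(trafficCount(out), as.integer(expected))
  for (fa in frameAlignments(out)) {
    fi <- fa@frameIndex
    nTruth <- sum(scene$truth$frame == fi)
    expect_identical(nrow(alignedDetections(fa)) +
                       nrow(unalignedDetections(fa)), nTruth)
  }
})
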