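test_that("the decision table covers every event configuration exactly once", {
  expect_identical(classifyEvent("FLYING", TRUE, TRUE), "BTP_BFLMTP")
  expect_identical(classifyEvent("CRAWLING", TRUE, TRUE), "BTP_BCRMTP")
  expect_identical(classifyEvent("STATIONARY", TRUE, FALSE), "BTP_BMTN")
  expect_identical(classifyEvent("FLYING", TRUE, FALSE), "BTP_BMFN")
  expect_identical(classifyEvent("CRAWLING", TRUE, FALSE), "BTP_BMFN")
  expect_identical(classifyEvent("FLYING", FALSE, TRUE), "BFN_BFLMTP")
  expect_identical(classifyEvent("FLYING", FALSE, FALSE), "BFN_BFLMFN")
  expect_identical(classifyEvent(NULL, TRUE, FALSE), "BFP")
  expect_identical(classifyEvent(NULL, TRUE, TRUE), "BFP")
  # residual motion on a detected stationary bee counts as crawling-motion TP
  expect_identical(classifyEvent("STATIONARY", TRUE, TRUE), "BTP_BCRMTP")
  # undetected non-flying truth is outside the taxonomy
  expect_true(is.na(classifyEvent("STATIONARY", FALSE, FALSE)))
  expect_error(classifyEvent(NULL, FALSE, FALSE), "needs")

  # every (state, detected, motion) configuration maps to exactly one category
  for (st in c("FLYING", "CRAWLING", "STATIONARY")) {
    for (dm in c(TRUE, FALSE)) {
      for (mp in c(TRUE, FALSE)) {
        out <- classifyEvent(st, dm, mp)
        expect_length(out, 1L)
        expect_true(is.na(out) || out %in% evalCategories())
      }
    }
  }
})

test_that("motion support requires both proximity (C1) and overlap (C2)", {
  params <- AlignmentParams(50)
  box <- c(100, 100, 140, 130)
  near_overlap <- data.frame(x = 130, y = 120, w = 30, h = 30, area = 1000)
  expect_identical(motionSupport(box, near_overlap, params), 1L)
  # close center but disjoint rectangle: C1 holds, C2 fails
  near_disjoint <- data.frame(x = 141, y = 131, w = 30, h = 30, area = 1000)
  expect_true(is.na(motionSupport(box, near_disjoint, params)))
  # overlapping but center far away: C2 holds, C1 fails
  big_far <- data.frame(x = 120, y = 110, w = 300, h = 300, area = 1e5)
  expect_true(is.na(motionSupport(box, big_far, params)))
  expect_true(is.na(motionSupport(box, NULL, params)))
})

test_that("greedy IoU matching is one-to-one, deterministic and optimal on
           planted instances", {
  boxes <- data.frame(x1 = c(0, 100, 200), y1 = c(0, 0, 0),
                      x2 = c(50, 150, 250), y2 = c(50, 50, 50))
  m <- matchDetectionsToTruth(boxes, boxes)
  expect_identical(nrow(m$pairs), 3L)
  expect_identical(m$pairs$gtIndex, m$pairs$detIndex)
  expect_length(m$unmatchedTruth, 0L)
  expect_length(m$unmatchedDetections, 0L)

  far <- boxes + 1000
  m2 <- matchDetectionsToTruth(far, boxes)
  expect_identical(nrow(m2$pairs), 0L)
  expect_identical(m2$unmatchedTruth, 1:3)
  expect_identical(m2$unmatchedDetections, 1:3)

  # planted unambiguous overlaps: greedy equals exhaustive optimal assignment
  set.seed(66)
  for (rep in 1:8) {
    nt <- sample(2:4, 1)
    truth <- data.frame(x1 = seq_len(nt) * 120, y1 = 10)
    truth$x2 <- truth$x1 + 60
    truth$y2 <- truth$y1 + 40
    det <- truth
    det$x1 <- det$x1 + runif(nt, -8, 8)
    det$y1 <- det$y1 + runif(nt, -8, 8)
    det$x2 <- det$x2 + runif(nt, -8, 8)
    det$y2 <- det$y2 + runif(nt, -8, 8)
    extra <- data.frame(x1 = 2000, y1 = 2000, x2 = 2050, y2 = 2050)
    det <- rbind(det, extra)[sample(nt + 1), ]
    rownames(det) <- NULL
    got <- matchDetectionsToTruth(det, truth)
    opt <- bfOptimalMatching(det, truth)
    expect_identical(nrow(got$pairs), nrow(opt$pairs))
    gotPairs <- got$pairs[order(got$pairs$gtIndex), c("gtIndex", "detIndex")]
    optPairs <- as.data.frame(opt$pairs[order(opt$pairs[, 1]), , drop = FALSE])
    expect_equal(unname(as.matrix(gotPairs)), unname(as.matrix(optPairs)))
  }
})

test_that("category tallies map to TP/FN/FP and pool by summation", {
  t1 <- tallyCategories(rep("BTP_BFLMTP", 4))
  expect_identical(c(t1@TP, t1@FN, t1@FP), c(4L, 0L, 0L))
  t2 <- tallyCategories(c("BFN_BFLMTP", "BFN_BFLMFN", "BFP"))
  expect_identical(c(t2@TP, t2@FN, t2@FP), c(0L, 2L, 1L))
  expect_error(tallyCategories("NOT_A_CATEGORY"), "unknown")

  set.seed(77)
  cats <- sample(evalCategories(), 200, replace = TRUE)
  tt <- tallyCategories(cats)
  hist <- table(factor(cats, levels = evalCategories()))
  expect_identical(tt@TP, sum(hist[1:4]))
  expect_identical(tt@FN, sum(hist[5:6]))
  expect_identical(tt@FP, sum(hist[7]))

  pooled <- poolCounts(list(ConfusionCounts(377, 581, 0),
                            ConfusionCounts(833, 2577, 0)))
  expect_identical(c(pooled@TP, pooled@FN, pooled@FP), c(1210L, 3158L, 0L))
  single <- ConfusionCounts(5, 6, 7)
  p1 <- poolCounts(list(single))
  expect_identical(c(p1@TP, p1@FN, p1@FP), c(5L, 6L, 7L))
  set.seed(78)
  strata <- lapply(1:5, function(i) {
    ConfusionCounts(sample(0:100, 1), sample(0:100, 1), sample(0:100, 1))
  })
  ps <- poolCounts(strata)
  expect_identical(ps@TP, sum(vapply(strata, slot, integer(1), "TP")))
  expect_identical(ps@FN, sum(vapply(strata, slot, integer(1), "FN")))
  expect_identical(ps@FP, sum(vapply(strata, slot, integer(1), "FP")))
})

test_that("as-printed metrics use the swapped denominators verbatim", {
  m <- asPrintedMetrics(computeMetrics(ConfusionCounts(377, 581, 0)))
  expect_equal(unname(m), c(0.39, 1.00, 0.56, 0.39))

  m2 <- asPrintedMetrics(computeMetrics(ConfusionCounts(250, 3836, 24)))
  expect_equal(unname(m2), c(0.06, 0.91, 0.11, 0.06))

  perfect <- computeMetrics(ConfusionCounts(10, 0, 0))
  expect_equal(asPrintedMetrics(perfect), c(precision = 1, recall = 1,
                                            f1 = 1, iou = 1))

  expect_warning(computeMetrics(ConfusionCounts(0, 0, 5)), "undefined")

  # unrounded values follow the formulas exactly
  mm <- computeMetrics(ConfusionCounts(271, 695, 300))
  expect_equal(mm@precision, 271 / (271 + 695))
  expect_equal(mm@recall, 271 / (271 + 300))
  expect_equal(mm@iou, 271 / (271 + 300 + 695))
  expect_equal(mm@f1, 2 * mm@precision * mm@recall / (mm@precision + mm@recall))

  # pooled-count metrics differ from the mean of stratum metrics
  strata <- list(ConfusionCounts(377, 581, 0), ConfusionCounts(833, 2577, 0))
  pooledPrec <- computeMetrics(poolCounts(strata))@precision
  expect_equal(beetraffic:::roundHalfUp(pooledPrec, 2), 0.28)
  # the mean of the printed per-stratum metrics is a different number
  meanPrinted <- mean(vapply(strata, function(cc) {
    asPrintedMetrics(computeMetrics(cc))["precision"]
  }, numeric(1)))
  expect_equal(meanPrinted, 0.315)
  expect_gt(abs(meanPrinted - beetraffic:::roundHalfUp(pooledPrec, 2)), 0.01)
})

test_that("scene evaluation is perfect for a perfect detector on flying bees
           and respects ignore regions", {
  cfg <- flyingSimConfig(seed = 19L, nBees = 3L, nFrames = 12L)
  scene <- simulateBeeScene(cfg)
  det <- makeOracleDetector(scene$truth, OracleDetectorConfig(seed = 5L))
  res <- runPipeline(scene$frames, det, testMotionParams())
  ev <- evaluateScene(res, scene$truth)
  expect_true(all(evalRecords(ev)$category == "BTP_BFLMTP"))
  expect_equal(unname(asPrintedMetrics(metricSet(ev))), rep(1, 4))

  # spurious detections landing in an IGNORE region are excluded from tallies
  sc <- stationaryScene(nFrames = 4)
  ignore <- data.frame(frame = 2:4, bee = 99L, x1 = 0, y1 = 0, x2 = 320,
                       y2 = 240, state = "IGNORE", pattern = "NONE")
  truthIg <- rbind(sc$truth[sc$truth$frame >= 2, ], ignore)
  spurCfg <- OracleDetectorConfig(missRate = 1, spuriousRate = 4, seed = 8L)
  resIg <- runPipeline(sc$frames[1:4], makeOracleDetector(sc$truth, spurCfg),
                       testMotionParams())
  evIg <- evaluateScene(resIg, truthIg)
  expect_identical(confusionCounts(evIg)@FP, 0L)
  # without the ignore mask the same detections are false positives
  evNoIg <- evaluateScene(resIg, sc$truth[sc$truth$frame >= 2, ])
  expect_gt(confusionCounts(evNoIg)@FP, 0L)
})
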