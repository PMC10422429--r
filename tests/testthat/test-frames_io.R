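test_that("middle-frame selection centers the window and rejects bad input", {
  expect_identical(selectMiddleFrames(744, 30), c(first = 358L, last = 387L))
  expect_identical(selectMiddleFrames(1, 1), c(first = 1L, last = 1L))
  expect_error(selectMiddleFrames(10, 11), "exceeds")

  # enumeration oracle: the window of length n whose first index is
  # floor((total - n) / 2) + 1, consistent with the (744, 30) anchor
  for (total in c(2, 7, 10, 30, 744, 745)) {
    for (n in intersect(c(1, 2, 4, 30), seq_len(total))) {
      w <- selectMiddleFrames(total, n)
      expect_identical(unname(w["last"] - w["first"] + 1L), as.integer(n))
      expect_identical(unname(w["first"]),
                       as.integer(floor((total - n) / 2) + 1))
    }
  }
  expect_identical(selectMiddleFrames(10, 4), c(first = 4L, last = 7L))
})

test_that("frame sequences round-trip through PNG in order", {
  dir <- withr::local_tempdir()
  set.seed(11)
  frames <- lapply(1:5, function(i) {
    matrix(sample(0:255, 8 * 10, replace = TRUE), 8, 10)
  })
  writeFrames(frames, dir)

  all5 <- loadFrames(dir)
  expect_length(all5, 5L)
  for (i in 1:5) {
    expect_equal(round(all5[[i]]), frames[[i]], ignore_attr = TRUE)
    expect_identical(attr(all5[[i]], "frameIndex"), i)
  }

  sub <- loadFrames(dir, first = 2, last = 4)
  expect_length(sub, 3L)
  expect_equal(round(sub[[1]]), frames[[2]], ignore_attr = TRUE)

  one <- loadFrames(dir, first = 1, last = 1)
  expect_length(one, 1L)

  expect_error(loadFrames(dir, first = 4, last = 3), "invalid frame range")
  expect_error(loadFrames(dir, first = 1, last = 99), "exceeds")
  expect_error(loadFrames(file.path(dir, "nope")), "does not exist")

  # an undecodable frame is reported with its index
  writeLines("not a png", file.path(dir, "frame_000003.png"))
  expect_error(loadFrames(dir), "frame 3")
})

test_that("video containers are rejected with guidance to pre-extract", {
  f <- withr::local_tempfile(fileext = ".mp4")
  writeLines("x", f)
  expect_error(loadFrames(f), "Extract frames to PNG")
})

test_that("labels round-trip losslessly at 6-decimal precision", {
  dir <- withr::local_tempdir()

  f <- file.path(dir, "one.txt")
  writeLabels(data.frame(classId = 0L, cx = 0.5, cy = 0.5, w = 0.1, h = 0.1), f)
  got <- readLabels(f)
  expect_equal(got$cx, 0.5)
  expect_equal(got$w, 0.1)

  writeLines(character(), f)
  expect_identical(nrow(readLabels(f)), 0L)

  writeLines(c("0 0.5 0.5 0.1 0.1", "0 0.2 bad 0.1 0.1"), f)
  expect_error(readLabels(f), "line 2")

  # bulk round trip at annotation-campaign scale: 23173 boxes over 5819 files
  set.seed(42)
  nFiles <- 5819L
  counts <- diff(c(0L, sort(sample(23173L, nFiles - 1L)), 23173L))
  total <- 0L
  for (i in which(counts > 0)) {
    n <- counts[i]
    cx <- round(runif(n, 0.05, 0.95), 6)
    cy <- round(runif(n, 0.05, 0.95), 6)
    w <- round(runif(n, 0.01, 0.1), 6)
    h <- round(runif(n, 0.01, 0.1), 6)
    boxes <- data.frame(classId = 0L, cx = cx, cy = cy, w = w, h = h)
    fp <- file.path(dir, sprintf("f_%05d.txt", i))
    writeLabels(boxes, fp)
    back <- readLabels(fp)
    expect_equal(back, boxes)
    total <- total + nrow(back)
  }
  expect_identical(total, 23173L)
})

test_that("pixel/normalized box conversions invert each other", {
  set.seed(3)
  boxes <- data.frame(
    x1 = runif(50, 0, 200), y1 = runif(50, 0, 100)
  )
  boxes$x2 <- boxes$x1 + runif(50, 1, 60)
  boxes$y2 <- boxes$y1 + runif(50, 1, 60)
  labels <- pixelBoxesToLabels(boxes, width = 320, height = 240)
  back <- labelsToPixelBoxes(labels, width = 320, height = 240)
  expect_equal(back, boxes, tolerance = 1e-12)
})

test_that("marked frames use the color scheme and leave the input intact", {
  frame <- matrix(128, 60, 80)
  attr(frame, "frameIndex") <- 1L

  blank <- renderMarkedFrame(frame)
  expect_equal(dim(blank), c(60, 80, 3))
  expect_true(all(blank == 128))

  det <- makeDetections(10, 20, 30, 40, 0.9)
  marked <- renderMarkedFrame(frame, aligned = det)
  diffIdx <- which(apply(marked != 128, c(1, 2), any), arr.ind = TRUE)
  # changed pixels are exactly the rectangle perimeter (0-based 10..30 x 20..40)
  rows <- diffIdx[, 1]; cols <- diffIdx[, 2]
  expect_true(all(rows >= 21 & rows <= 41 & cols >= 11 & cols <= 31))
  onPerimeter <- rows %in% c(21, 41) | cols %in% c(11, 31)
  expect_true(all(onPerimeter))
  expect_identical(
    sum(marked[, , 1] == 255 & marked[, , 2] == 165 & marked[, , 3] == 0),
    length(rows))
  expect_true(all(frame == 128))  # input untouched

  red <- renderMarkedFrame(frame, unaligned = det)
  expect_gt(sum(red[, , 1] == 255 & red[, , 2] == 0 & red[, , 3] == 0), 0)

  a <- matrix(0, 60, 80); b <- a; b[25:45, 30:60] <- 255
  regions <- detectMotionRegions(a, b, MotionParams(minContourArea = 50))
  rm2 <- renderMarkedFrame(frame, regions = regions)
  expect_gt(sum(rm2[, , 1] == 0 & rm2[, , 2] == 0 & rm2[, , 3] == 255), 0)
  expect_gt(sum(rm2[, , 1] == 255 & rm2[, , 2] == 255 & rm2[, , 3] == 0), 0)
})
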