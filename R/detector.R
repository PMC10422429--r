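# Pluggable detector interface.
#
# A detector is any function(frameIndex, frame) returning a detection
# data.frame; the pipeline is agnostic to how boxes are produced. Detection
# boxes use 0-based pixel corners (x1, y1) top-left and (x2, y2)
# bottom-right with x1 < x2, y1 < y2, a confidence score in [0, 1], and the
# derived geometric center cx = x1 + (x2 - x1)/2, cy = y1 + (y2 - y1)/2.

#' Build a detection data.frame
#'
#' Validates corner ordering and scores and computes box centers.
#'
#' @param x1,y1,x2,y2 box corners, 0-based pixels (x = column, y = row).
#' @param score confidence in [0, 1].
#' @return data.frame with columns x1, y1, x2, y2, score, cx, cy.
#' @export
makeDetections <- function(x1 = numeric(), y1 = numeric(), x2 = numeric(),
                           y2 = numeric(), score = numeric()) {
  if (any(x1 >= x2) || any(y1 >= y2)) {
    stopInput("detection boxes must satisfy x1 < x2 and y1 < y2")
  }
  if (any(score < 0 | score > 1)) {
    stopInput("detection scores must be in [0, 1]")
  }
  data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2, score = score,
             cx = x1 + (x2 - x1) / 2, cy = y1 + (y2 - y1) / 2)
}

emptyDetections <- function() makeDetections()

#' Filter detections by confidence score
#'
#' Keeps detections with \code{score >= threshold} (the 0.7 default keeps a
#' score of exactly 0.7), preserving order. Idempotent.
#'
#' @param detections detection data.frame.
#' @param threshold score threshold in [0, 1].
#' @return the filtered detection data.frame.
#' @export
filterByScore <- function(detections, threshold = 0.7) {
  checkScalarNumber(threshold, "threshold", min = 0, max = 1)
  out <- detections[detections$score >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Synthetic oracle detection from ground truth
#'
#' Emits detections derived from ground-truth boxes under a configurable
#' error model: each true box independently survives with probability
#' \code{1 - missRate}, surviving corners are jittered with Gaussian noise of
#' sd \code{jitterPx}, scores are drawn uniformly from \code{scoreRange}, and
#' \code{Poisson(spuriousRate)} extra boxes are placed uniformly at random in
#' the frame. Output is reproducible: the RNG stream for frame i is seeded
#' with \code{config@seed + i}.
#'
#' @param truthBoxes data.frame of ground-truth pixel boxes for one frame
#'   (columns x1, y1, x2, y2).
#' @param config an [OracleDetectorConfig-class].
#' @param frameIndex 1-based frame index (seeds the per-frame RNG stream).
#' @param frameSize c(height, width) in pixels, used to place spurious boxes.
#' @return detection data.frame (see [makeDetections()]).
#' @export
oracleDetect <- function(truthBoxes, config, frameIndex, frameSize) {
  validObject(config)
  withSeed(config@seed + as.integer(frameIndex), {
    n <- nrow(truthBoxes)
    kept <- if (n) which(stats::runif(n) < 1 - config@missRate) else integer()
    if (length(kept)) {
      b <- truthBoxes[kept, c("x1", "y1", "x2", "y2"), drop = FALSE]
      if (config@jitterPx > 0) {
        jit <- matrix(stats::rnorm(4L * nrow(b), sd = config@jitterPx),
                      ncol = 4L)
        b <- b + jit
        # restore corner ordering; degenerate boxes get a minimal extent
        x1 <- pmin(b$x1, b$x2); x2 <- pmax(b$x1, b$x2)
        y1 <- pmin(b$y1, b$y2); y2 <- pmax(b$y1, b$y2)
        x2 <- ifelse(x2 - x1 < 1, x1 + 1, x2)
        y2 <- ifelse(y2 - y1 < 1, y1 + 1, y2)
        b <- data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2)
      }
      scores <- stats::runif(nrow(b), config@scoreRange[1], config@scoreRange[2])
      out <- makeDetections(b$x1, b$y1, b$x2, b$y2, scores)
    } else {
      out <- emptyDetections()
    }
    nSpur <- stats::rpois(1L, config@spuriousRate)
    if (nSpur > 0L) {
      H <- frameSize[1]; W <- frameSize[2]
      w <- stats::runif(nSpur, config@spuriousSizePx[1], config@spuriousSizePx[2])
      h <- stats::runif(nSpur, config@spuriousSizePx[1], config@spuriousSizePx[2])
      cx <- stats::runif(nSpur, 0, W - 1)
      cy <- stats::runif(nSpur, 0, H - 1)
      x1 <- clamp(cx - w / 2, 0, W - 2)
      y1 <- clamp(cy - h / 2, 0, H - 2)
      x2 <- clamp(cx + w / 2, x1 + 1, W - 1)
      y2 <- clamp(cy + h / 2, y1 + 1, H - 1)
      scores <- stats::runif(nSpur, config@scoreRange[1], config@scoreRange[2])
      out <- rbind(out, makeDetections(x1, y1, x2, y2, scores))
    }
    rownames(out) <- NULL
    out
  })
}

#' Detector adapters for the pipeline
#'
#' \code{makeOracleDetector()} wraps [oracleDetect()] over a per-frame
#' ground-truth table; \code{makeFileDetector()} replays externally produced
#' detections read with [readDetections()]. Both return a
#' \code{function(frameIndex, frame)} usable with [runPipeline()].
#'
#' @param truth data.frame with columns frame, x1, y1, x2, y2 (pixel boxes).
#' @param config an [OracleDetectorConfig-class].
#' @return a detector function.
#' @export
makeOracleDetector <- function(truth, config = OracleDetectorConfig()) {
  force(truth); force(config)
  function(frameIndex, frame) {
    boxes <- truth[truth$frame == frameIndex, , drop = FALSE]
    oracleDetect(boxes, config, frameIndex, frameDims(frame))
  }
}

#' @param detections data.frame with columns frame, x1, y1, x2, y2, score.
#' @rdname makeOracleDetector
#' @export
makeFileDetector <- function(detections) {
  force(detections)
  function(frameIndex, frame) {
    d <- detections[detections$frame == frameIndex, , drop = FALSE]
    makeDetections(d$x1, d$y1, d$x2, d$y2, d$score)
  }
}

#' Read and write detection exchange files
#'
#' Whitespace-separated text, one detection per line:
#' \code{frame_index x1 y1 x2 y2 score}.
#'
#' @param path file path.
#' @return \code{readDetections()}: data.frame with columns frame, x1, y1,
#'   x2, y2, score.
#' @export
readDetections <- function(path) {
  if (!file.exists(path)) stopInput("detection file does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(frame = integer(), x1 = numeric(), y1 = numeric(),
                      x2 = numeric(), y2 = numeric(), score = numeric()))
  }
  parsed <- lapply(seq_along(lines), function(i) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]),
                                                 "[[:space:]]+")[[1]]))
    if (length(vals) != 6L || anyNA(vals)) {
      stopInput("malformed detection line %d in %s: '%s'", i, path, lines[i])
    }
    vals
  })
  m <- do.call(rbind, parsed)
  data.frame(frame = as.integer(m[, 1]), x1 = m[, 2], y1 = m[, 3],
             x2 = m[, 4], y2 = m[, 5], score = m[, 6])
}

#' @param detections data.frame with columns frame, x1, y1, x2, y2, score.
#' @rdname readDetections
#' @export
writeDetections <- function(detections, path) {
  lines <- sprintf("%d %.6f %.6f %.6f %.6f %.6f",
                   as.integer(detections$frame), detections$x1, detections$y1,
                   detections$x2, detections$y2, detections$score)
  writeLines(lines, path)
  invisible(path)
}
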