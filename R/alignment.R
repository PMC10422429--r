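# Object--motion alignment: partition score-filtered detections into
# motion-aligned and motion-unaligned sets by kd-tree radius queries against
# motion-region centers.

# recursive 2-d kd-tree over the rows of a point matrix
kdBuild <- function(pts, idx, depth = 0L) {
  n <- length(idx)
  if (n == 0L) return(NULL)
  axis <- depth %% 2L + 1L
  ord <- idx[order(pts[idx, axis], idx)]
  med <- (n + 1L) %/% 2L
  list(
    i = ord[med],
    axis = axis,
    left = kdBuild(pts, ord[seq_len(med - 1L)], depth + 1L),
    right = if (med < n) kdBuild(pts, ord[seq(med + 1L, n)], depth + 1L)
            else NULL
  )
}

kdRadius <- function(node, pts, q, r) {
  if (is.null(node)) return(integer())
  p <- pts[node$i, ]
  hits <- integer()
  if (sum((p - q)^2) <= r^2) hits <- node$i
  delta <- q[node$axis] - p[node$axis]
  near <- if (delta <= 0) node$left else node$right
  far <- if (delta <= 0) node$right else node$left
  hits <- c(hits, kdRadius(near, pts, q, r))
  if (abs(delta) <= r) hits <- c(hits, kdRadius(far, pts, q, r))
  hits
}

#' Build a spatial index over motion-region centers
#'
#' Stores the centers \code{(x + w/2, y + h/2)} of the regions in a kd-tree
#' supporting Euclidean radius queries.
#'
#' @param regions motion-region data.frame from [detectMotionRegions()]
#'   (an empty data.frame yields an index whose every query returns nothing).
#' @return an object of class \code{MotionIndex}.
#' @export
buildMotionIndex <- function(regions) {
  centers <- regionCenter(regions)
  structure(
    list(
      centers = centers,
      tree = kdBuild(centers, seq_len(nrow(centers))),
      regions = regions
    ),
    class = "MotionIndex"
  )
}

#' @export
print.MotionIndex <- function(x, ...) {
  cat(sprintf("MotionIndex over %d region centers\n", nrow(x$centers)))
  invisible(x)
}

#' Radius query against a motion index
#'
#' @param index a \code{MotionIndex} from [buildMotionIndex()].
#' @param query length-2 numeric (x, y) query point.
#' @param radius Euclidean search radius in pixels (boundary inclusive).
#' @return sorted integer vector of region row indices within the radius.
#' @export
queryRadius <- function(index, query, radius) {
  sort(kdRadius(index$tree, index$centers, as.numeric(query), radius))
}

#' Align detections to motion regions
#'
#' A detection is \emph{motion-aligned} if at least one motion-region center
#' lies within \code{maxDistancePx} (inclusive) of the detection's center,
#' and \emph{motion-unaligned} otherwise. An aligned detection records its
#' nearest region (distance ties broken by lowest region row index). The
#' aligned and unaligned sets are disjoint and together contain every input
#' detection.
#'
#' @param detections score-filtered detection data.frame.
#' @param index a \code{MotionIndex}, or a motion-region data.frame (an index
#'   is then built internally).
#' @param params an [AlignmentParams-class].
#' @param frameIndex frame attribution for the returned object.
#' @return a [FrameAlignment-class] object.
#' @export
alignDetections <- function(detections, index, params = AlignmentParams(),
                            frameIndex = NA_integer_) {
  validObject(params)
  if (is.data.frame(index)) index <- buildMotionIndex(index)
  n <- nrow(detections)
  matched <- rep(NA_integer_, n)
  dist <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    hits <- queryRadius(index, c(detections$cx[i], detections$cy[i]),
                        params@maxDistancePx)
    if (length(hits)) {
      dd <- sqrt((index$centers[hits, 1] - detections$cx[i])^2 +
                 (index$centers[hits, 2] - detections$cy[i])^2)
      best <- hits[which.min(dd)]  # ties: lowest index (hits are sorted)
      matched[i] <- best
      dist[i] <- min(dd)
    }
  }
  aligned <- detections[!is.na(matched), , drop = FALSE]
  if (nrow(aligned)) {
    aligned$matchedRegion <- matched[!is.na(matched)]
    aligned$matchDistance <- dist[!is.na(matched)]
  } else {
    aligned$matchedRegion <- integer()
    aligned$matchDistance <- numeric()
  }
  unaligned <- detections[is.na(matched), , drop = FALSE]
  rownames(aligned) <- NULL
  rownames(unaligned) <- NULL
  new("FrameAlignment", frameIndex = as.integer(frameIndex),
      regions = index$regions, aligned = aligned, unaligned = unaligned)
}

#' Run the traffic-quantification pipeline over a frame sequence
#'
#' For each frame i >= 2: run the detector, drop detections below the score
#' threshold, detect motion regions between frames i - 1 and i, and align
#' detections to region centers. Frame 1 has no preceding frame and is not
#' processed. The video-level omnidirectional traffic measurement is the
#' total count of motion-aligned detections across processed frames; no
#' trajectory tracking is attempted, so a bee moving through k consecutive
#' frames contributes k.
#'
#' @param frames list of frames (see [loadFrames()]).
#' @param detector a \code{function(frameIndex, frame)} returning a detection
#'   data.frame (see [makeOracleDetector()]).
#' @param motionParams a [MotionParams-class].
#' @param alignParams an [AlignmentParams-class].
#' @param scoreThreshold detector confidence threshold (kept if >= threshold).
#' @return a [BeeTrafficResult-class].
#' @export
runPipeline <- function(frames, detector, motionParams = MotionParams(),
                        alignParams = AlignmentParams(),
                        scoreThreshold = 0.7) {
  if (length(frames) < 2L) {
    stopInput("pipeline needs at least 2 frames, got %d", length(frames))
  }
  alignments <- vector("list", length(frames) - 1L)
  total <- 0L
  for (i in seq(2L, length(frames))) {
    dets <- filterByScore(detector(i, frames[[i]]), scoreThreshold)
    regions <- detectMotionRegions(frames[[i - 1L]], frames[[i]], motionParams)
    fa <- alignDetections(dets, regions, alignParams, frameIndex = i)
    alignments[[i - 1L]] <- fa
    total <- total + nrow(fa@aligned)
  }
  new("BeeTrafficResult", alignments = alignments,
      trafficCount = as.integer(total))
}
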