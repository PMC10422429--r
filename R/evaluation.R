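# Seven-category accuracy taxonomy and as-printed metrics.
#
# Each ground-truth-vs-pipeline event is labeled jointly by detection
# correctness and motion status. A motion region "supports" a box when it
# satisfies both alignment criteria: C1, its center lies within the alignment
# radius of the box center, and C2, its enclosing rectangle has strictly
# positive intersection area with the box.

EVAL_CATEGORIES <- c(
  "BTP_BFLMTP",  # bee TP, flight motion TP
  "BTP_BCRMTP",  # bee TP, crawling/residual motion TP
  "BTP_BMTN",    # bee TP, motion true negative (stationary bee, no motion)
  "BTP_BMFN",    # bee TP, motion false negative (moving bee, motion missed)
  "BFN_BFLMTP",  # bee FN, flight motion TP (motion caught, detector missed)
  "BFN_BFLMFN",  # bee FN, flight motion FN (both missed)
  "BFP"          # bee false positive
)
TP_CATEGORIES <- EVAL_CATEGORIES[1:4]
FN_CATEGORIES <- EVAL_CATEGORIES[5:6]

#' The seven event categories
#'
#' @return character vector of the seven category names, in taxonomy order:
#'   four true-positive categories, two false-negative categories, and the
#'   false-positive category.
#' @export
evalCategories <- function() EVAL_CATEGORIES

# rectangle intersection area; boxes are (x1, y1, x2, y2)
boxIntersection <- function(a, b) {
  w <- pmin(a[3], b[3]) - pmax(a[1], b[1])
  h <- pmin(a[4], b[4]) - pmax(a[2], b[2])
  if (w <= 0 || h <= 0) 0 else w * h
}

boxIoU <- function(a, b) {
  inter <- boxIntersection(a, b)
  if (inter <= 0) return(0)
  areaA <- (a[3] - a[1]) * (a[4] - a[2])
  areaB <- (b[3] - b[1]) * (b[4] - b[2])
  inter / (areaA + areaB - inter)
}

#' Find a motion region supporting a box
#'
#' Returns the row index of the nearest motion region satisfying C1 (region
#' center within \code{params@maxDistancePx} of the box center, inclusive)
#' and C2 (strictly positive rectangle intersection with the box), or
#' \code{NA} if none does. Distance ties break to the lowest region index.
#'
#' @param box length-4 numeric (x1, y1, x2, y2).
#' @param regions motion-region data.frame.
#' @param params an [AlignmentParams-class].
#' @export
motionSupport <- function(box, regions, params = AlignmentParams()) {
  if (is.null(regions) || nrow(regions) == 0L) return(NA_integer_)
  centers <- regionCenter(regions)
  bc <- c(box[1] + (box[3] - box[1]) / 2, box[2] + (box[4] - box[2]) / 2)
  d <- sqrt((centers[, 1] - bc[1])^2 + (centers[, 2] - bc[2])^2)
  c1 <- d <= params@maxDistancePx
  c2 <- vapply(seq_len(nrow(regions)), function(i) {
    rb <- c(regions$x[i], regions$y[i],
            regions$x[i] + regions$w[i], regions$y[i] + regions$h[i])
    boxIntersection(box, rb) > 0
  }, logical(1))
  ok <- which(c1 & c2)
  if (!length(ok)) return(NA_integer_)
  as.integer(unname(ok[which.min(d[ok])]))
}

#' Classify one ground-truth-vs-pipeline event
#'
#' Decision table over the presence of a ground-truth bee, a matched
#' detection, and a supporting motion region (one satisfying C1 and C2):
#' \itemize{
#'   \item gt + detection + motion, gt FLYING: \code{BTP_BFLMTP}
#'   \item gt + detection + motion, gt CRAWLING or STATIONARY:
#'     \code{BTP_BCRMTP} (residual motion on a non-flying bee)
#'   \item gt + detection, no motion, gt STATIONARY: \code{BTP_BMTN}
#'   \item gt + detection, no motion, gt FLYING or CRAWLING: \code{BTP_BMFN}
#'   \item gt FLYING, no detection, motion present: \code{BFN_BFLMTP}
#'   \item gt FLYING, no detection, no motion: \code{BFN_BFLMFN}
#'   \item detection with no ground truth: \code{BFP}
#' }
#' An undetected non-flying ground-truth bee has no category in the taxonomy
#' (only flying bees were annotated in the source protocol) and yields
#' \code{NA}.
#'
#' @param gtState ground-truth motion state (\code{"FLYING"},
#'   \code{"CRAWLING"} or \code{"STATIONARY"}), or \code{NULL} if no
#'   ground-truth bee underlies the event.
#' @param detectionMatched logical: was a detection matched to the bee (or,
#'   with \code{gtState = NULL}, is the event a bare detection)?
#' @param motionPresent logical: does a motion region satisfying C1 and C2
#'   support the event's box?
#' @return a category name, or \code{NA_character_}.
#' @export
classifyEvent <- function(gtState = NULL, detectionMatched = FALSE,
                          motionPresent = FALSE) {
  if (is.null(gtState) && !detectionMatched) {
    stopInput("an event needs a ground-truth bee or a detection")
  }
  if (is.null(gtState)) return("BFP")
  gtState <- match.arg(gtState, c("FLYING", "CRAWLING", "STATIONARY"))
  if (detectionMatched) {
    if (motionPresent) {
      if (gtState == "FLYING") "BTP_BFLMTP" else "BTP_BCRMTP"
    } else {
      if (gtState == "STATIONARY") "BTP_BMTN" else "BTP_BMFN"
    }
  } else {
    if (gtState != "FLYING") return(NA_character_)
    if (motionPresent) "BFN_BFLMTP" else "BFN_BFLMFN"
  }
}

#' Match detections to ground-truth boxes
#'
#' Greedy one-to-one matching by descending box intersection-over-union,
#' accepting pairs with IoU > 0; ties break deterministically by (ground
#' truth index, detection index).
#'
#' @param detections detection data.frame (pixel boxes x1, y1, x2, y2).
#' @param truthBoxes ground-truth data.frame (same box columns).
#' @return list with \code{pairs} (data.frame gtIndex, detIndex, iou),
#'   \code{unmatchedTruth} and \code{unmatchedDetections} (integer row
#'   indices).
#' @export
matchDetectionsToTruth <- function(detections, truthBoxes) {
  nd <- nrow(detections); nt <- nrow(truthBoxes)
  pairs <- data.frame(gtIndex = integer(), detIndex = integer(),
                      iou = numeric())
  if (nd == 0L || nt == 0L) {
    return(list(pairs = pairs, unmatchedTruth = seq_len(nt),
                unmatchedDetections = seq_len(nd)))
  }
  iou <- matrix(0, nt, nd)
  for (i in seq_len(nt)) {
    tb <- c(truthBoxes$x1[i], truthBoxes$y1[i], truthBoxes$x2[i],
            truthBoxes$y2[i])
    for (j in seq_len(nd)) {
      db <- c(detections$x1[j], detections$y1[j], detections$x2[j],
              detections$y2[j])
      iou[i, j] <- boxIoU(tb, db)
    }
  }
  freeT <- rep(TRUE, nt); freeD <- rep(TRUE, nd)
  repeat {
    m <- iou
    m[!freeT, ] <- -1
    m[, !freeD] <- -1
    best <- max(m)
    if (best <= 0) break
    cand <- which(m == best, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    pairs <- rbind(pairs,
                   data.frame(gtIndex = i, detIndex = j, iou = best))
    freeT[i] <- FALSE; freeD[j] <- FALSE
  }
  list(pairs = pairs, unmatchedTruth = which(freeT),
       unmatchedDetections = which(freeD))
}

#' Tally event categories into confusion counts
#'
#' The four \code{BTP_*} categories count as true positives, the two
#' \code{BFN_*} categories as false negatives, and \code{BFP} as false
#' positives. \code{NA} categories (events outside the taxonomy) are dropped.
#'
#' @param categories character vector of category names.
#' @param nf,nv number of frames / videos the events came from.
#' @return a [ConfusionCounts-class].
#' @export
tallyCategories <- function(categories, nf = NA_integer_, nv = NA_integer_) {
  categories <- categories[!is.na(categories)]
  bad <- setdiff(unique(categories), EVAL_CATEGORIES)
  if (length(bad)) stopInput("unknown categories: %s", paste(bad, collapse = ", "))
  ConfusionCounts(
    TP = sum(categories %in% TP_CATEGORIES),
    FN = sum(categories %in% FN_CATEGORIES),
    FP = sum(categories == "BFP"),
    NF = nf, NV = nv
  )
}

#' Compute the four as-printed metrics from confusion counts
#'
#' The metric definitions are implemented verbatim from the evaluation
#' protocol, \emph{including its nonstandard denominator assignment}:
#' \deqn{precision = TP / (TP + FN), \quad recall = TP / (TP + FP),}
#' \deqn{F1 = 2 \, precision \cdot recall / (precision + recall), \quad
#'       IoU = TP / (TP + FP + FN).}
#' Relative to standard usage the precision and recall denominators are
#' swapped; consumers comparing against conventionally defined metrics should
#' read \code{precision} here as standard recall and vice versa. Undefined
#' metrics (zero denominator) are returned as \code{NaN} with a warning.
#'
#' @param counts a [ConfusionCounts-class].
#' @return a [MetricSet-class].
#' @examples
#' m <- computeMetrics(ConfusionCounts(377, 581, 0))
#' asPrintedMetrics(m)  # 0.39 1.00 0.56 0.39
#' @export
computeMetrics <- function(counts) {
  validObject(counts)
  TP <- counts@TP; FN <- counts@FN; FP <- counts@FP
  if (TP + FN == 0L || TP + FP == 0L) {
    warning("confusion counts leave one or more metrics undefined (NaN)",
            call. = FALSE)
  }
  precision <- TP / (TP + FN)
  recall <- TP / (TP + FP)
  f1 <- 2 * precision * recall / (precision + recall)
  if (is.finite(precision) && is.finite(recall) && precision + recall == 0) {
    f1 <- NaN
  }
  iou <- TP / (TP + FP + FN)
  MetricSet(precision = precision, recall = recall, f1 = f1, iou = iou)
}

#' Metrics rounded for table reporting
#'
#' Rounds half away from zero to \code{digits} decimals, the convention used
#' in the reported tables.
#'
#' @param metrics a [MetricSet-class].
#' @param digits decimals to keep.
#' @return named numeric vector (precision, recall, f1, iou).
#' @export
asPrintedMetrics <- function(metrics, digits = 2) {
  c(precision = roundHalfUp(metrics@precision, digits),
    recall = roundHalfUp(metrics@recall, digits),
    f1 = roundHalfUp(metrics@f1, digits),
    iou = roundHalfUp(metrics@iou, digits))
}

#' Pool confusion counts across strata
#'
#' Elementwise sums of TP/FN/FP (and NF/NV where known). Metrics of the
#' pooled counts are the correct stratified totals; the arithmetic mean of
#' per-stratum metrics, available via [metricMeans()], is generally
#' different and kept only as a secondary summary.
#'
#' @param counts list of [ConfusionCounts-class] objects.
#' @return a [ConfusionCounts-class].
#' @export
poolCounts <- function(counts) {
  if (!length(counts)) stopInput("poolCounts needs a non-empty list")
  sumNA <- function(x) if (anyNA(x)) NA_integer_ else sum(x)
  ConfusionCounts(
    TP = sum(vapply(counts, slot, integer(1), "TP")),
    FN = sum(vapply(counts, slot, integer(1), "FN")),
    FP = sum(vapply(counts, slot, integer(1), "FP")),
    NF = sumNA(vapply(counts, slot, integer(1), "NF")),
    NV = sumNA(vapply(counts, slot, integer(1), "NV"))
  )
}

#' Arithmetic means of per-stratum metrics
#'
#' @param metricSets list of [MetricSet-class] objects.
#' @return named numeric vector of the four averaged metrics.
#' @export
metricMeans <- function(metricSets) {
  c(precision = mean(vapply(metricSets, slot, numeric(1), "precision")),
    recall = mean(vapply(metricSets, slot, numeric(1), "recall")),
    f1 = mean(vapply(metricSets, slot, numeric(1), "f1")),
    iou = mean(vapply(metricSets, slot, numeric(1), "iou")))
}

#' Evaluate a pipeline run against ground truth
#'
#' Classifies every event in the processed frames of a pipeline result:
#' matched (ground truth, detection) pairs via [matchDetectionsToTruth()],
#' unmatched detections as false positives, and unmatched flying ground
#' truth as false negatives, with motion support per [motionSupport()].
#' Ground-truth rows with state \code{"IGNORE"} mark regions where unlabeled
#' bees may appear (e.g. partially occluded); unmatched detections
#' intersecting an ignore box are excluded from all tallies.
#'
#' @param result a [BeeTrafficResult-class] from [runPipeline()].
#' @param truth data.frame with columns frame, x1, y1, x2, y2, state
#'   (FLYING / CRAWLING / STATIONARY / IGNORE).
#' @param params the [AlignmentParams-class] used for motion support (C1).
#' @param nv number of videos the truth spans, for reporting.
#' @return a [SceneEvaluation-class].
#' @export
evaluateScene <- function(result, truth, params = AlignmentParams(), nv = 1L) {
  records <- data.frame(frame = integer(), category = character(),
                        gtIndex = integer(), detIndex = integer())
  for (fa in result@alignments) {
    fi <- fa@frameIndex
    dets <- rbind(
      fa@aligned[, c("x1", "y1", "x2", "y2", "score", "cx", "cy")],
      fa@unaligned[, c("x1", "y1", "x2", "y2", "score", "cx", "cy")]
    )
    gt <- truth[truth$frame == fi, , drop = FALSE]
    rownames(gt) <- NULL
    ignores <- gt[gt$state == "IGNORE", , drop = FALSE]
    gt <- gt[gt$state != "IGNORE", , drop = FALSE]
    m <- matchDetectionsToTruth(dets, gt)
    addRecord <- function(cat, gtIdx, detIdx) {
      if (is.na(cat)) return()
      records[nrow(records) + 1L, ] <<- list(fi, cat, gtIdx, detIdx)
    }
    for (k in seq_len(nrow(m$pairs))) {
      i <- m$pairs$gtIndex[k]; j <- m$pairs$detIndex[k]
      db <- c(dets$x1[j], dets$y1[j], dets$x2[j], dets$y2[j])
      mot <- motionSupport(db, fa@regions, params)
      addRecord(classifyEvent(gt$state[i], TRUE, !is.na(mot)), i, j)
    }
    for (i in m$unmatchedTruth) {
      tb <- c(gt$x1[i], gt$y1[i], gt$x2[i], gt$y2[i])
      mot <- motionSupport(tb, fa@regions, params)
      addRecord(classifyEvent(gt$state[i], FALSE, !is.na(mot)), i,
                NA_integer_)
    }
    for (j in m$unmatchedDetections) {
      db <- c(dets$x1[j], dets$y1[j], dets$x2[j], dets$y2[j])
      inIgnore <- FALSE
      for (k in seq_len(nrow(ignores))) {
        ib <- c(ignores$x1[k], ignores$y1[k], ignores$x2[k], ignores$y2[k])
        if (boxIntersection(db, ib) > 0) { inIgnore <- TRUE; break }
      }
      if (!inIgnore) addRecord("BFP", NA_integer_, j)
    }
  }
  counts <- tallyCategories(records$category,
                            nf = length(result@alignments), nv = nv)
  metrics <- suppressWarnings(computeMetrics(counts))
  new("SceneEvaluation", records = records, counts = counts,
      metrics = metrics)
}
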