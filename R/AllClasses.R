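#' @import methods
NULL

# ---------------------------------------------------------------------------
# Parameter containers
# ---------------------------------------------------------------------------

#' Motion-detection parameters
#'
#' Parameters of the frame-differencing operator chain: both frames are
#' grayscaled, Gaussian-blurred with a \code{blurKernel} x \code{blurKernel}
#' kernel, their pixelwise absolute difference is dilated with a
#' \code{dilateKernel} x \code{dilateKernel} rectangular structuring element
#' (one iteration), binarized with foreground = value > \code{diffThreshold},
#' and external contours with polygon area below \code{minContourArea} are
#' discarded as too small to contain one flying bee.
#'
#' @slot blurKernel odd positive integer, Gaussian blur kernel side (default 5).
#' @slot dilateKernel odd positive integer, dilation kernel side (default 5).
#' @slot diffThreshold intensity threshold in [0, 255] (default 20); a pixel
#'   of the dilated difference is foreground iff strictly greater.
#' @slot minContourArea minimum contour polygon area in pixels (default 1000,
#'   calibrated for 1080-row frames; scale by frame area for smaller frames,
#'   see [scaledMotionParams()]).
#' @slot blurSigma Gaussian sigma; \code{NA} derives it from the kernel size k
#'   as \code{0.3 * ((k - 1)/2 - 1) + 0.8}, the de-facto convention for
#'   kernel-only blurs.
#' @seealso [detectMotionRegions()]
#' @export
setClass("MotionParams",
  representation(
    blurKernel = "integer",
    dilateKernel = "integer",
    diffThreshold = "numeric",
    minContourArea = "numeric",
    blurSigma = "numeric"
  )
)

setValidity("MotionParams", function(object) {
  msg <- character()
  for (s in c("blurKernel", "dilateKernel")) {
    k <- slot(object, s)
    if (length(k) != 1L || is.na(k) || k < 1L || k %% 2L == 0L) {
      msg <- c(msg, sprintf("%s must be a single odd integer >= 1", s))
    }
  }
  if (object@diffThreshold < 0 || object@diffThreshold > 255) {
    msg <- c(msg, "diffThreshold must be in [0, 255]")
  }
  if (object@minContourArea <= 0) {
    msg <- c(msg, "minContourArea must be > 0")
  }
  if (!is.na(object@blurSigma) && object@blurSigma <= 0) {
    msg <- c(msg, "blurSigma must be > 0 (or NA to derive from kernel size)")
  }
  if (length(msg)) msg else TRUE
})

#' @param blurKernel,dilateKernel,diffThreshold,minContourArea,blurSigma see
#'   the corresponding slots.
#' @return \code{MotionParams()} returns a validated parameter object.
#' @examples
#' MotionParams()
#' MotionParams(minContourArea = 37)  # rescaled for 240 x 320 frames
#' @rdname MotionParams-class
#' @export
MotionParams <- function(blurKernel = 5L, dilateKernel = 5L,
                         diffThreshold = 20, minContourArea = 1000,
                         blurSigma = NA_real_) {
  new("MotionParams",
    blurKernel = as.integer(blurKernel),
    dilateKernel = as.integer(dilateKernel),
    diffThreshold = as.numeric(diffThreshold),
    minContourArea = as.numeric(minContourArea),
    blurSigma = as.numeric(blurSigma)
  )
}

setMethod("show", "MotionParams", function(object) {
  sigma <- if (is.na(object@blurSigma)) {
    sprintf("auto (%.3f)", derivedSigma(object@blurKernel))
  } else {
    sprintf("%.3f", object@blurSigma)
  }
  cat("MotionParams\n",
    sprintf("  blur %dx%d (sigma %s), dilate %dx%d\n",
      object@blurKernel, object@blurKernel, sigma,
      object@dilateKernel, object@dilateKernel),
    sprintf("  diff threshold > %g, min contour area %g px\n",
      object@diffThreshold, object@minContourArea),
    sep = "")
})

#' Object--motion alignment parameters
#'
#' @slot maxDistancePx Euclidean radius in pixels within which a motion-region
#'   center must lie of a detection center for the detection to be
#'   motion-aligned (default 50; the boundary is inclusive).
#' @export
setClass("AlignmentParams", representation(maxDistancePx = "numeric"))

setValidity("AlignmentParams", function(object) {
  if (length(object@maxDistancePx) != 1L || is.na(object@maxDistancePx) ||
      object@maxDistancePx <= 0) {
    "maxDistancePx must be a single number > 0"
  } else TRUE
})

#' @param maxDistancePx see slot.
#' @rdname AlignmentParams-class
#' @export
AlignmentParams <- function(maxDistancePx = 50) {
  new("AlignmentParams", maxDistancePx = as.numeric(maxDistancePx))
}

setMethod("show", "AlignmentParams", function(object) {
  cat(sprintf("AlignmentParams: radius <= %g px\n", object@maxDistancePx))
})

#' Synthetic oracle detector configuration
#'
#' Configures the built-in detector that stands in for a trained object
#' detector: it perturbs ground-truth boxes instead of running inference, so
#' the pipeline can be exercised with controlled error rates.
#'
#' @slot missRate probability in [0, 1] that a true box is dropped (source of
#'   false negatives).
#' @slot spuriousRate expected number of spurious boxes per frame, Poisson
#'   distributed (source of false positives).
#' @slot jitterPx standard deviation in pixels of Gaussian perturbation
#'   applied independently to each box corner coordinate.
#' @slot scoreRange length-2 range from which confidence scores are drawn
#'   uniformly.
#' @slot spuriousSizePx length-2 range of spurious box side lengths.
#' @slot seed integer RNG seed; the per-frame stream is derived as
#'   \code{seed + frameIndex}, so output is reproducible and independent of
#'   call order.
#' @export
setClass("OracleDetectorConfig",
  representation(
    missRate = "numeric",
    spuriousRate = "numeric",
    jitterPx = "numeric",
    scoreRange = "numeric",
    spuriousSizePx = "numeric",
    seed = "integer"
  )
)

setValidity("OracleDetectorConfig", function(object) {
  msg <- character()
  if (object@missRate < 0 || object@missRate > 1) {
    msg <- c(msg, "missRate must be in [0, 1]")
  }
  if (object@spuriousRate < 0) msg <- c(msg, "spuriousRate must be >= 0")
  if (object@jitterPx < 0) msg <- c(msg, "jitterPx must be >= 0")
  if (length(object@scoreRange) != 2L ||
      any(object@scoreRange < 0 | object@scoreRange > 1) ||
      object@scoreRange[1] > object@scoreRange[2]) {
    msg <- c(msg, "scoreRange must be an increasing pair within [0, 1]")
  }
  if (length(object@spuriousSizePx) != 2L || any(object@spuriousSizePx <= 0) ||
      object@spuriousSizePx[1] > object@spuriousSizePx[2]) {
    msg <- c(msg, "spuriousSizePx must be an increasing positive pair")
  }
  if (length(msg)) msg else TRUE
})

#' @param missRate,spuriousRate,jitterPx,scoreRange,spuriousSizePx,seed see
#'   the corresponding slots.
#' @rdname OracleDetectorConfig-class
#' @export
OracleDetectorConfig <- function(missRate = 0, spuriousRate = 0, jitterPx = 0,
                                 scoreRange = c(0.7, 1),
                                 spuriousSizePx = c(10, 60), seed = 1L) {
  new("OracleDetectorConfig",
    missRate = as.numeric(missRate),
    spuriousRate = as.numeric(spuriousRate),
    jitterPx = as.numeric(jitterPx),
    scoreRange = as.numeric(scoreRange),
    spuriousSizePx = as.numeric(spuriousSizePx),
    seed = as.integer(seed)
  )
}

setMethod("show", "OracleDetectorConfig", function(object) {
  cat("OracleDetectorConfig\n",
    sprintf("  miss rate %g, spurious rate %g/frame, corner jitter sd %g px\n",
      object@missRate, object@spuriousRate, object@jitterPx),
    sprintf("  scores U(%g, %g), seed %d\n",
      object@scoreRange[1], object@scoreRange[2], object@seed),
    sep = "")
})

# ---------------------------------------------------------------------------
# Evaluation containers
# ---------------------------------------------------------------------------

#' Confusion counts for bee object inference
#'
#' Aggregated true positives, false negatives and false positives from the
#' seven-category event taxonomy (see [classifyEvent()]), plus the number of
#' frames and videos they were tallied over.
#'
#' @slot TP,FN,FP non-negative integer counts.
#' @slot NF number of frames (NA if unknown).
#' @slot NV number of videos (NA if unknown).
#' @export
setClass("ConfusionCounts",
  representation(TP = "integer", FN = "integer", FP = "integer",
                 NF = "integer", NV = "integer")
)

setValidity("ConfusionCounts", function(object) {
  counts <- c(object@TP, object@FN, object@FP)
  if (any(is.na(counts)) || any(counts < 0L)) {
    "TP, FN and FP must be non-negative integers"
  } else TRUE
})

#' @param TP,FN,FP,NF,NV see the corresponding slots.
#' @rdname ConfusionCounts-class
#' @export
ConfusionCounts <- function(TP, FN, FP, NF = NA_integer_, NV = NA_integer_) {
  new("ConfusionCounts", TP = as.integer(TP), FN = as.integer(FN),
      FP = as.integer(FP), NF = as.integer(NF), NV = as.integer(NV))
}

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d FN=%d FP=%d (NF=%s, NV=%s)\n",
    object@TP, object@FN, object@FP,
    ifelse(is.na(object@NF), "?", object@NF),
    ifelse(is.na(object@NV), "?", object@NV)))
})

#' Metric set derived from confusion counts
#'
#' Holds the four as-printed metrics. Note the deliberate, documented swap
#' relative to standard usage: here \code{precision = TP / (TP + FN)} and
#' \code{recall = TP / (TP + FP)}, exactly as the evaluation protocol defines
#' them (see [computeMetrics()]).
#'
#' @slot precision TP / (TP + FN), as printed.
#' @slot recall TP / (TP + FP), as printed.
#' @slot f1 harmonic mean of the two.
#' @slot iou TP / (TP + FP + FN).
#' @export
setClass("MetricSet",
  representation(precision = "numeric", recall = "numeric",
                 f1 = "numeric", iou = "numeric")
)

#' @param precision,recall,f1,iou see the corresponding slots.
#' @rdname MetricSet-class
#' @export
MetricSet <- function(precision, recall, f1, iou) {
  new("MetricSet", precision = precision, recall = recall, f1 = f1, iou = iou)
}

setMethod("show", "MetricSet", function(object) {
  cat(sprintf(
    "MetricSet (as printed): precision=%.4f recall=%.4f f1=%.4f iou=%.4f\n",
    object@precision, object@recall, object@f1, object@iou))
})

#' Per-frame object--motion alignment result
#'
#' @slot frameIndex 1-based index of the frame the result belongs to.
#' @slot regions data.frame of motion regions (columns x, y, w, h, area and a
#'   contour list-column), attributed to this frame.
#' @slot aligned data.frame of motion-aligned detections, with the matched
#'   region row index (\code{matchedRegion}) and center distance
#'   (\code{matchDistance}).
#' @slot unaligned data.frame of motion-unaligned detections.
#' @export
setClass("FrameAlignment",
  representation(frameIndex = "integer", regions = "data.frame",
                 aligned = "data.frame", unaligned = "data.frame")
)

setMethod("show", "FrameAlignment", function(object) {
  cat(sprintf("FrameAlignment [frame %d]: %d regions, %d aligned, %d unaligned\n",
    object@frameIndex, nrow(object@regions), nrow(object@aligned),
    nrow(object@unaligned)))
})

#' @describeIn FrameAlignment-class motion regions of the frame.
#' @param x a \code{FrameAlignment} or \code{BeeTrafficResult} object.
#' @export
setGeneric("motionRegions", function(x) standardGeneric("motionRegions"))
setMethod("motionRegions", "FrameAlignment", function(x) x@regions)

#' @describeIn FrameAlignment-class motion-aligned detections.
#' @export
setGeneric("alignedDetections",
           function(x) standardGeneric("alignedDetections"))
setMethod("alignedDetections", "FrameAlignment", function(x) x@aligned)

#' @describeIn FrameAlignment-class motion-unaligned detections.
#' @export
setGeneric("unalignedDetections",
           function(x) standardGeneric("unalignedDetections"))
setMethod("unalignedDetections", "FrameAlignment", function(x) x@unaligned)

#' Video-level pipeline result
#'
#' @slot alignments list of [FrameAlignment-class] objects for frames
#'   2..n (frame 1 has no preceding frame, hence no motion regions, and is
#'   not processed).
#' @slot trafficCount total number of motion-aligned detections across the
#'   processed frames: the omnidirectional traffic measurement. A bee visible
#'   and moving in k consecutive frames contributes k.
#' @export
setClass("BeeTrafficResult",
  representation(alignments = "list", trafficCount = "integer")
)

setMethod("show", "BeeTrafficResult", function(object) {
  cat(sprintf("BeeTrafficResult: %d processed frames, traffic count %d\n",
    length(object@alignments), object@trafficCount))
})

#' @describeIn BeeTrafficResult-class the video-level traffic count.
#' @param x a \code{BeeTrafficResult}.
#' @export
setGeneric("trafficCount", function(x) standardGeneric("trafficCount"))
setMethod("trafficCount", "BeeTrafficResult", function(x) x@trafficCount)

#' @describeIn BeeTrafficResult-class list of per-frame alignments.
#' @export
setGeneric("frameAlignments", function(x) standardGeneric("frameAlignments"))
setMethod("frameAlignments", "BeeTrafficResult", function(x) x@alignments)

#' Scene evaluation result
#'
#' @slot records data.frame with one row per classified event: columns
#'   frame, category, gtIndex, detIndex.
#' @slot counts [ConfusionCounts-class] aggregated over all records.
#' @slot metrics [MetricSet-class] computed from the counts.
#' @export
setClass("SceneEvaluation",
  representation(records = "data.frame", counts = "ConfusionCounts",
                 metrics = "MetricSet")
)

setMethod("show", "SceneEvaluation", function(object) {
  cat(sprintf("SceneEvaluation: %d events\n", nrow(object@records)))
  show(object@counts)
  show(object@metrics)
})

#' @describeIn SceneEvaluation-class per-event classification records.
#' @param x a \code{SceneEvaluation}.
#' @export
setGeneric("evalRecords", function(x) standardGeneric("evalRecords"))
setMethod("evalRecords", "SceneEvaluation", function(x) x@records)

#' @describeIn SceneEvaluation-class aggregated confusion counts.
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))
setMethod("confusionCounts", "SceneEvaluation", function(x) x@counts)

#' @describeIn SceneEvaluation-class as-printed metric set.
#' @export
setGeneric("metricSet", function(x) standardGeneric("metricSet"))
setMethod("metricSet", "SceneEvaluation", function(x) x@metrics)

# ---------------------------------------------------------------------------
# Energy accounting containers
# ---------------------------------------------------------------------------

#' Data-engineering energy ledger
#'
#' Cumulative power amounts (CPA, kW-h) of the four data-engineering
#' categories for one model: dataset curation, model training, running the
#' model over the evaluation videos, and manual evaluation of its output.
#'
#' @slot curationKwh,trainingKwh,evalRunKwh,evalManualKwh CPA entries, kW-h.
#' @slot label free-text provenance, e.g. the model name.
#' @export
setClass("EnergyLedger",
  representation(curationKwh = "numeric", trainingKwh = "numeric",
                 evalRunKwh = "numeric", evalManualKwh = "numeric",
                 label = "character")
)

setValidity("EnergyLedger", function(object) {
  entries <- c(object@curationKwh, object@trainingKwh, object@evalRunKwh,
               object@evalManualKwh)
  if (any(is.na(entries)) || any(entries < 0)) {
    "all ledger entries must be non-negative kW-h amounts"
  } else TRUE
})

#' @param curationKwh,trainingKwh,evalRunKwh,evalManualKwh,label see the
#'   corresponding slots.
#' @rdname EnergyLedger-class
#' @export
EnergyLedger <- function(curationKwh, trainingKwh, evalRunKwh, evalManualKwh,
                         label = "") {
  new("EnergyLedger", curationKwh = as.numeric(curationKwh),
      trainingKwh = as.numeric(trainingKwh),
      evalRunKwh = as.numeric(evalRunKwh),
      evalManualKwh = as.numeric(evalManualKwh), label = label)
}

setMethod("show", "EnergyLedger", function(object) {
  cat(sprintf(
    "EnergyLedger%s: curation %g + training %g + eval run %g + eval manual %g = %.2f kW-h\n",
    if (nzchar(object@label)) paste0(" (", object@label, ")") else "",
    object@curationKwh, object@trainingKwh, object@evalRunKwh,
    object@evalManualKwh, ledgerTotal(object)))
})

#' Operational power profile of a deployed monitoring pipeline
#'
#' @slot modelRateKwhPerH power use rate of the inference computer, kW-h/h.
#' @slot loggerRateKwhPerH power use rate of one on-hive logger, kW-h/h.
#' @slot nLoggers number of deployed loggers.
#' @slot hoursPerMonth accounting hours per month (default 24 x 7 x 4 = 672).
#' @slot monthsPerSeason months in a beekeeping season (default 5, May
#'   through September in northern Utah).
#' @export
setClass("PowerProfile",
  representation(modelRateKwhPerH = "numeric", loggerRateKwhPerH = "numeric",
                 nLoggers = "integer", hoursPerMonth = "numeric",
                 monthsPerSeason = "numeric")
)

setValidity("PowerProfile", function(object) {
  msg <- character()
  if (object@modelRateKwhPerH < 0 || object@loggerRateKwhPerH < 0) {
    msg <- c(msg, "power rates must be >= 0")
  }
  if (object@nLoggers < 0L) msg <- c(msg, "nLoggers must be >= 0")
  if (object@hoursPerMonth <= 0 || object@monthsPerSeason <= 0) {
    msg <- c(msg, "hoursPerMonth and monthsPerSeason must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' @param modelRateKwhPerH,loggerRateKwhPerH,nLoggers,hoursPerMonth,monthsPerSeason
#'   see the corresponding slots.
#' @rdname PowerProfile-class
#' @export
PowerProfile <- function(modelRateKwhPerH, loggerRateKwhPerH = 0.003,
                         nLoggers = 10L, hoursPerMonth = 24 * 7 * 4,
                         monthsPerSeason = 5) {
  new("PowerProfile", modelRateKwhPerH = as.numeric(modelRateKwhPerH),
      loggerRateKwhPerH = as.numeric(loggerRateKwhPerH),
      nLoggers = as.integer(nLoggers),
      hoursPerMonth = as.numeric(hoursPerMonth),
      monthsPerSeason = as.numeric(monthsPerSeason))
}

setMethod("show", "PowerProfile", function(object) {
  cat(sprintf(
    "PowerProfile: model %g kW-h/h, %d loggers @ %g kW-h/h, %g h/month, %g months/season\n",
    object@modelRateKwhPerH, object@nLoggers, object@loggerRateKwhPerH,
    object@hoursPerMonth, object@monthsPerSeason))
})
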