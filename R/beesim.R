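# Synthetic bee-flight scene generator.
#
# Renders moving bee-sized dark ellipses over a static procedural
# hive-entrance background (textured field with a light landing-pad band at
# the bottom), following five qualitative flight patterns observed at hive
# entrances: straight, inward zigzag, outward zigzag, land-and-crawl, and
# parallel. Emits per-frame ground truth (tight bounding boxes and motion
# states) so every pipeline stage can be tested without real recordings.
# Realism beyond what drives a differencing motion detector is a non-goal.

SIM_PATTERNS <- c("STRAIGHT", "INWARD_ZIGZAG", "OUTWARD_ZIGZAG",
                  "LAND_AND_CRAWL", "PARALLEL")

#' Simulation configuration
#'
#' @slot frameSize integer c(height, width) in pixels; the 240 x 320 default
#'   keeps test scenes fast while preserving the reference geometry's aspect.
#' @slot nFrames number of frames.
#' @slot cameraHeightClass 1 or 2; class 2 (camera one super higher) halves
#'   the apparent bee size.
#' @slot nBees number of bees.
#' @slot patternMix named probability vector over the five patterns.
#' @slot beeAxesPx mean ellipse semi-axes (along-track, cross-track) at
#'   camera height class 1.
#' @slot beeAxesSpread relative s.d. of per-bee size variation.
#' @slot speedRange named list of per-pattern c(min, max) flight speeds in
#'   px/frame; straight flight is the fastest pattern of the mix.
#' @slot pixelNoiseSigma s.d. of additive Gaussian intensity noise.
#' @slot trajectoryNoiseSd s.d. in pixels of per-frame heading / lateral
#'   perturbations of the flight paths (0 gives geometrically exact paths).
#' @slot flyingMinPx displacement at or above which a bee counts as FLYING.
#' @slot stationaryMaxPx displacement below which a bee counts as STATIONARY;
#'   in between is CRAWLING.
#' @slot seed RNG seed; a fixed seed makes frames and truth bit-identical.
#' @export
setClass("SimConfig",
  representation(
    frameSize = "integer", nFrames = "integer", cameraHeightClass = "integer",
    nBees = "integer", patternMix = "numeric", beeAxesPx = "numeric",
    beeAxesSpread = "numeric", speedRange = "list",
    pixelNoiseSigma = "numeric", trajectoryNoiseSd = "numeric",
    flyingMinPx = "numeric", stationaryMaxPx = "numeric", seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (length(object@frameSize) != 2L || any(object@frameSize < 32L)) {
    msg <- c(msg, "frameSize must be c(height, width), each >= 32")
  }
  if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
  if (!object@cameraHeightClass %in% c(1L, 2L)) {
    msg <- c(msg, "cameraHeightClass must be 1 or 2")
  }
  if (object@nBees < 0L) msg <- c(msg, "nBees must be >= 0")
  if (!setequal(names(object@patternMix), SIM_PATTERNS) ||
      any(object@patternMix < 0) ||
      abs(sum(object@patternMix) - 1) > 1e-8) {
    msg <- c(msg, "patternMix must be probabilities over the five patterns summing to 1")
  }
  if (length(object@beeAxesPx) != 2L || any(object@beeAxesPx <= 0)) {
    msg <- c(msg, "beeAxesPx must be two positive semi-axes")
  }
  ax <- beeAxesFor(object)
  if (any(2 * ax >= object@frameSize[2:1])) {
    msg <- c(msg, "bee size must be smaller than the frame")
  }
  if (!setequal(names(object@speedRange), SIM_PATTERNS)) {
    msg <- c(msg, "speedRange must name all five patterns")
  }
  if (object@pixelNoiseSigma < 0) msg <- c(msg, "pixelNoiseSigma must be >= 0")
  if (object@trajectoryNoiseSd < 0) {
    msg <- c(msg, "trajectoryNoiseSd must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

beeAxesFor <- function(config) {
  scale <- if (config@cameraHeightClass == 2L) 0.5 else 1
  config@beeAxesPx * scale
}

#' @param frameSize,nFrames,cameraHeightClass,nBees,patternMix,beeAxesPx,beeAxesSpread,speedRange,pixelNoiseSigma,trajectoryNoiseSd,flyingMinPx,stationaryMaxPx,seed
#'   see the corresponding slots.
#' @rdname SimConfig-class
#' @export
SimConfig <- function(frameSize = c(240L, 320L), nFrames = 30L,
                      cameraHeightClass = 1L, nBees = 3L,
                      patternMix = c(STRAIGHT = 0.35, INWARD_ZIGZAG = 0.15,
                                     OUTWARD_ZIGZAG = 0.15,
                                     LAND_AND_CRAWL = 0.20, PARALLEL = 0.15),
                      beeAxesPx = c(14, 9), beeAxesSpread = 0.15,
                      speedRange = list(STRAIGHT = c(8, 12),
                                        INWARD_ZIGZAG = c(4, 7),
                                        OUTWARD_ZIGZAG = c(4, 7),
                                        LAND_AND_CRAWL = c(4, 7),
                                        PARALLEL = c(4, 7)),
                      pixelNoiseSigma = 2, trajectoryNoiseSd = 0.3,
                      flyingMinPx = 3, stationaryMaxPx = 1, seed = 1L) {
  new("SimConfig", frameSize = as.integer(frameSize),
      nFrames = as.integer(nFrames),
      cameraHeightClass = as.integer(cameraHeightClass),
      nBees = as.integer(nBees), patternMix = patternMix,
      beeAxesPx = as.numeric(beeAxesPx),
      beeAxesSpread = as.numeric(beeAxesSpread), speedRange = speedRange,
      pixelNoiseSigma = as.numeric(pixelNoiseSigma),
      trajectoryNoiseSd = as.numeric(trajectoryNoiseSd),
      flyingMinPx = as.numeric(flyingMinPx),
      stationaryMaxPx = as.numeric(stationaryMaxPx), seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %dx%d px, %d frames, %d bees, CH=%d, noise sd %g, seed %d\n",
    object@frameSize[1], object@frameSize[2], object@nFrames, object@nBees,
    object@cameraHeightClass, object@pixelNoiseSigma, object@seed))
})

#' Motion parameters scaled to a simulated frame size
#'
#' The 1000 px minimum contour area is calibrated for 1080-row reference
#' frames; for smaller simulated frames it is rescaled proportionally to
#' frame area so a rendered bee still clears the filter.
#'
#' @param frameSize c(height, width) of the frames to process.
#' @param reference reference geometry the 1000 px area belongs to.
#' @param ... passed to [MotionParams()].
#' @return a [MotionParams-class] with rescaled \code{minContourArea}.
#' @export
scaledMotionParams <- function(frameSize, reference = c(1080, 1920), ...) {
  scale <- prod(as.numeric(frameSize)) / prod(as.numeric(reference))
  MotionParams(minContourArea = max(1, round(1000 * scale)), ...)
}

# motion states from per-frame displacements; state of frame 1 copies frame 2
motionStates <- function(waypoints, flyingMin, stationaryMax) {
  n <- nrow(waypoints)
  if (n == 1L) return("STATIONARY")
  d <- sqrt(rowSums((waypoints[-1L, , drop = FALSE] -
                     waypoints[-n, , drop = FALSE])^2))
  st <- ifelse(d >= flyingMin, "FLYING",
               ifelse(d < stationaryMax, "STATIONARY", "CRAWLING"))
  c(st[1L], st)
}

#' Generate waypoints for one flight pattern
#'
#' Uses the current RNG stream. Patterns: \code{STRAIGHT} is constant
#' velocity with small per-frame heading noise (the fastest pattern);
#' \code{INWARD_ZIGZAG} / \code{OUTWARD_ZIGZAG} are piecewise segments whose
#' approach (vertical) velocity component reverses sign 2-4 times, with net
#' motion toward / away from the landing pad; \code{LAND_AND_CRAWL} flies to
#' a point on the pad band then crawls (steps <= 2 px/frame) or sits still;
#' \code{PARALLEL} moves across the frame with approach component ~ 0.
#'
#' @param pattern one of the five pattern names.
#' @param start length-2 (x, y) start point, inside the frame.
#' @param nFrames number of waypoints to produce.
#' @param speed flight speed in px/frame.
#' @param frameSize c(height, width).
#' @param noiseSd s.d. of heading / lateral perturbations in pixels
#'   (0 gives exactly straight / exactly constant-row paths).
#' @param crawlMaxPx maximum crawl step for LAND_AND_CRAWL.
#' @return list with \code{waypoints} (nFrames x 2 matrix of (x, y)) and
#'   \code{pattern}.
#' @export
patternWaypoints <- function(pattern, start, nFrames, speed, frameSize,
                             noiseSd = 0.3, crawlMaxPx = 2) {
  pattern <- match.arg(pattern, SIM_PATTERNS)
  H <- frameSize[1]; W <- frameSize[2]
  wp <- matrix(NA_real_, nFrames, 2)
  wp[1L, ] <- start
  padTop <- H * 0.78  # landing-pad band occupies the bottom fifth
  if (pattern == "STRAIGHT") {
    theta <- stats::runif(1, 0, 2 * pi)
    for (i in seq_len(nFrames - 1L)) {
      theta <- theta + stats::rnorm(1, 0, noiseSd * 0.15)
      wp[i + 1L, ] <- wp[i, ] + speed * c(cos(theta), sin(theta))
    }
  } else if (pattern %in% c("INWARD_ZIGZAG", "OUTWARD_ZIGZAG")) {
    nRev <- min(sample(2:4, 1), max(2L, nFrames - 2L))
    nSeg <- nRev + 1L
    inwardSign <- if (pattern == "INWARD_ZIGZAG") 1 else -1
    # odd segments move with the pattern direction and are given roughly
    # double the length of the reversal legs, guaranteeing net drift toward
    # (inward) or away from (outward) the landing pad
    weights <- ifelse(seq_len(nSeg) %% 2L == 1L,
                      stats::runif(nSeg, 1.0, 1.5),
                      stats::runif(nSeg, 0.4, 0.6))
    segLen <- rep(1L, nSeg)
    extra <- (nFrames - 1L) - nSeg
    if (extra > 0L) {
      add <- floor(weights / sum(weights) * extra)
      segLen <- segLen + add
      rem <- extra - sum(add)
      if (rem > 0L) segLen[seq_len(rem)] <- segLen[seq_len(rem)] + 1L
    }
    segOfStep <- rep(seq_len(nSeg), times = segLen)[seq_len(nFrames - 1L)]
    vxSeg <- stats::runif(nSeg, -0.6, 0.6) * speed
    for (i in seq_len(nFrames - 1L)) {
      s <- segOfStep[i]
      vySign <- if (s %% 2L == 1L) inwardSign else -inwardSign
      v <- c(vxSeg[s], vySign * 0.8 * speed) + stats::rnorm(2, 0, noiseSd)
      v <- v / max(sqrt(sum(v^2)), 1e-9) * speed
      wp[i + 1L, ] <- wp[i, ] + v
    }
  } else if (pattern == "LAND_AND_CRAWL") {
    target <- c(stats::runif(1, W * 0.2, W * 0.8),
                stats::runif(1, padTop + 5, H - 10))
    # land within ~60% of the clip so a crawl/still phase is always observed
    if (nFrames > 2L) {
      dist0 <- sqrt(sum((target - start)^2))
      speed <- max(speed, dist0 / (0.6 * (nFrames - 1L)))
    }
    crawling <- stats::runif(1) < 0.5
    landed <- FALSE
    for (i in seq_len(nFrames - 1L)) {
      if (!landed) {
        delta <- target - wp[i, ]
        dist <- sqrt(sum(delta^2))
        if (dist <= speed) {
          # final approach step, kept at flying speed (>= 3 px) so the
          # state sequence is FLYING+ then (CRAWLING|STATIONARY)+
          step <- delta / max(dist, 1e-9) * max(dist, 3)
          wp[i + 1L, ] <- wp[i, ] + step
          landed <- TRUE
        } else {
          dir <- delta / dist
          wp[i + 1L, ] <- wp[i, ] + speed * dir + stats::rnorm(2, 0, noiseSd)
        }
      } else if (crawling) {
        ang <- stats::runif(1, 0, 2 * pi)
        stepLen <- stats::runif(1, 1, crawlMaxPx)
        wp[i + 1L, ] <- wp[i, ] + stepLen * c(cos(ang), sin(ang))
      } else {
        wp[i + 1L, ] <- wp[i, ] + stats::rnorm(2, 0, 0.1)
      }
    }
  } else {  # PARALLEL: approach component ~ 0, lateral crossing
    dir <- sample(c(-1, 1), 1)
    for (i in seq_len(nFrames - 1L)) {
      wp[i + 1L, ] <- wp[i, ] +
        c(dir * speed, 0) + c(0, stats::rnorm(1, 0, noiseSd))
    }
  }
  list(waypoints = wp, pattern = pattern)
}

# soft-edged dark ellipse composited onto a grayscale canvas
renderEllipse <- function(canvas, cx, cy, a, b, intensity = 40) {
  H <- nrow(canvas); W <- ncol(canvas)
  c1 <- max(1L, floor(cx - a)); c2 <- min(W, ceiling(cx + a) + 1L)
  r1 <- max(1L, floor(cy - b)); r2 <- min(H, ceiling(cy + b) + 1L)
  if (c1 > c2 || r1 > r2) return(canvas)
  cols <- seq(c1, c2); rows <- seq(r1, r2)
  # 0-based pixel centers
  fx <- ((cols - 1) - cx) / a
  fy <- ((rows - 1) - cy) / b
  f <- sqrt(outer(fy^2, fx^2, `+`))          # normalized radius
  alpha <- clamp((1 - f) * min(a, b) + 0.5, 0, 1)
  sub <- canvas[rows, cols, drop = FALSE]
  canvas[rows, cols] <- sub * (1 - alpha) + intensity * alpha
  canvas
}

proceduralBackground <- function(H, W) {
  base <- matrix(155 + stats::rnorm(H * W, 0, 10), H, W)
  bg <- gaussianBlur(base, 7L, 2)           # smooth field texture
  padTop <- floor(H * 0.8)
  bg[seq(padTop, H), ] <- 205 + bg[seq(padTop, H), ] * 0.02  # light pad band
  clamp(bg, 0, 255)
}

#' Simulate a bee-flight scene
#'
#' Renders bees as anti-aliased dark ellipses along pattern trajectories over
#' a static procedural background, adds Gaussian pixel noise, and emits
#' per-frame ground truth. Only fully visible bees (tight bounding box
#' entirely inside the frame) are emitted as truth, mirroring an annotation
#' protocol that labels only full-size unoccluded bees.
#'
#' @param config a [SimConfig-class].
#' @return list with \code{frames} (list of grayscale matrices in [0, 255])
#'   and \code{truth} (data.frame: frame, bee, x1, y1, x2, y2, state,
#'   pattern), plus \code{trajectories} (per-bee waypoint/state lists).
#' @export
simulateBeeScene <- function(config = SimConfig()) {
  validObject(config)
  H <- config@frameSize[1]; W <- config@frameSize[2]
  withSeed(config@seed, {
    bg <- proceduralBackground(H, W)
    axes <- beeAxesFor(config)
    bees <- lapply(seq_len(config@nBees), function(b) {
      pattern <- sample(SIM_PATTERNS, 1, prob = config@patternMix[SIM_PATTERNS])
      sizeMul <- exp(stats::rnorm(1, 0, config@beeAxesSpread))
      a <- axes[1] * sizeMul; bAx <- axes[2] * sizeMul
      speed <- stats::runif(1, config@speedRange[[pattern]][1],
                            config@speedRange[[pattern]][2])
      margin <- ceiling(max(a, bAx)) + 2
      start <- switch(pattern,
        STRAIGHT = c(stats::runif(1, margin, W - margin),
                     stats::runif(1, margin, H - margin)),
        INWARD_ZIGZAG = c(stats::runif(1, W * 0.2, W * 0.8),
                          stats::runif(1, margin, H * 0.3)),
        OUTWARD_ZIGZAG = c(stats::runif(1, W * 0.2, W * 0.8),
                           stats::runif(1, H * 0.55, H * 0.75)),
        LAND_AND_CRAWL = c(stats::runif(1, W * 0.2, W * 0.8),
                           stats::runif(1, margin, H * 0.3)),
        PARALLEL = c(stats::runif(1, margin, W - margin),
                     stats::runif(1, H * 0.2, H * 0.6))
      )
      tr <- patternWaypoints(pattern, start, config@nFrames, speed,
                             config@frameSize,
                             noiseSd = config@trajectoryNoiseSd)
      tr$states <- motionStates(tr$waypoints, config@flyingMinPx,
                                config@stationaryMaxPx)
      tr$axes <- c(a, bAx)
      tr
    })
    frames <- vector("list", config@nFrames)
    truthRows <- list()
    for (i in seq_len(config@nFrames)) {
      canvas <- bg
      for (b in seq_along(bees)) {
        tr <- bees[[b]]
        cx <- tr$waypoints[i, 1]; cy <- tr$waypoints[i, 2]
        a <- tr$axes[1]; bAx <- tr$axes[2]
        canvas <- renderEllipse(canvas, cx, cy, a, bAx)
        x1 <- cx - a; x2 <- cx + a; y1 <- cy - bAx; y2 <- cy + bAx
        if (x1 >= 0 && y1 >= 0 && x2 <= W - 1 && y2 <= H - 1) {
          truthRows[[length(truthRows) + 1L]] <- data.frame(
            frame = i, bee = b, x1 = x1, y1 = y1, x2 = x2, y2 = y2,
            state = tr$states[i], pattern = tr$pattern
          )
        }
      }
      if (config@pixelNoiseSigma > 0) {
        canvas <- canvas + stats::rnorm(H * W, 0, config@pixelNoiseSigma)
      }
      frame <- clamp(canvas, 0, 255)
      attr(frame, "frameIndex") <- i
      frames[[i]] <- frame
    }
    truth <- if (length(truthRows)) {
      do.call(rbind, truthRows)
    } else {
      data.frame(frame = integer(), bee = integer(), x1 = numeric(),
                 y1 = numeric(), x2 = numeric(), y2 = numeric(),
                 state = character(), pattern = character())
    }
    list(frames = frames, truth = truth, trajectories = bees)
  })
}

#' Write a simulated scene to disk
#'
#' Writes frame PNGs (\code{frame_\%06d.png}), one Darknet-style label file
#' per frame (\code{frame_\%06d.txt}), and \code{truth.csv} with pixel boxes
#' and motion states.
#'
#' @param scene result of [simulateBeeScene()].
#' @param path output directory.
#' @return invisibly, the output directory.
#' @export
writeScene <- function(scene, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  writeFrames(scene$frames, path)
  H <- nrow(scene$frames[[1]]); W <- ncol(scene$frames[[1]])
  for (i in seq_along(scene$frames)) {
    rows <- scene$truth[scene$truth$frame == i, , drop = FALSE]
    labels <- pixelBoxesToLabels(rows, W, H)
    writeLabels(labels, file.path(path, sprintf("frame_%06d.txt", i)))
  }
  utils::write.csv(scene$truth, file.path(path, "truth.csv"),
                   row.names = FALSE)
  invisible(path)
}
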