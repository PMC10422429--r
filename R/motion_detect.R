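# Frame-differencing motion detection.
#
# Operator chain between two consecutive frames: grayscale (luma weights
# 0.299/0.587/0.114), Gaussian blur (5x5), pixelwise absolute difference,
# grayscale dilation (5x5 rectangle, one iteration), binary threshold
# (foreground = value > 20), external contours of 8-connected foreground
# components with simplified chain approximation, discard contours of polygon
# area < 1000 px, and report each survivor's minimal enclosing axis-aligned
# rectangle. All convolution/dilation borders use replicate (clamped-index)
# padding.

derivedSigma <- function(k) 0.3 * ((k - 1) / 2 - 1) + 0.8

#' Convert a frame to grayscale intensities
#'
#' Applies the luma weights 0.299 R + 0.587 G + 0.114 B; grayscale input is
#' returned unchanged.
#'
#' @param frame H x W matrix or H x W x 3 array, intensities in [0, 255].
#' @return H x W numeric matrix.
#' @export
grayscaleFrame <- function(frame) {
  if (length(dim(frame)) == 2L) return(frame)
  0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
}

# normalized 1-d Gaussian kernel of odd length k
gaussianKernel1d <- function(k, sigma = NA_real_) {
  if (is.na(sigma)) sigma <- derivedSigma(k)
  r <- (k - 1) / 2
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  g / sum(g)
}

# replicate-pad a matrix by r rows/cols on every side
padReplicate <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  m[c(rep(1L, r), seq_len(H), rep(H, r)),
    c(rep(1L, r), seq_len(W), rep(W, r)), drop = FALSE]
}

# separable convolution with a 1-d kernel, replicate border
convolveSeparable <- function(m, g) {
  k <- length(g)
  r <- (k - 1L) / 2L
  H <- nrow(m); W <- ncol(m)
  p <- padReplicate(m, r)
  tmp <- matrix(0, H, W + 2L * r)  # vertical pass
  for (i in seq_len(k)) {
    tmp <- tmp + g[i] * p[seq_len(H) + i - 1L, , drop = FALSE]
  }
  out <- matrix(0, H, W)           # horizontal pass
  for (i in seq_len(k)) {
    out <- out + g[i] * tmp[, seq_len(W) + i - 1L, drop = FALSE]
  }
  out
}

gaussianBlur <- function(m, k, sigma = NA_real_) {
  convolveSeparable(m, gaussianKernel1d(k, sigma))
}

# grayscale dilation with a k x k rectangular structuring element (max
# filter), replicate border; separable as row then column max
dilateMax <- function(m, k) {
  r <- (k - 1L) / 2L
  H <- nrow(m); W <- ncol(m)
  p <- padReplicate(m, r)
  tmp <- matrix(-Inf, H, W + 2L * r)
  for (i in seq_len(k)) {
    tmp <- pmax(tmp, p[seq_len(H) + i - 1L, , drop = FALSE])
  }
  out <- matrix(-Inf, H, W)
  for (i in seq_len(k)) {
    out <- pmax(out, tmp[, seq_len(W) + i - 1L, drop = FALSE])
  }
  out
}

# label 8-connected components of a logical matrix; returns integer matrix
# (0 = background), labels numbered in row-major scan order of first pixel
labelComponents8 <- function(bin) {
  H <- nrow(bin); W <- ncol(bin)
  lab <- matrix(0L, H, W)
  nextLabel <- 0L
  stack <- integer(256L)
  # row-major scan so component numbering matches boundary-trace start order
  for (r0 in seq_len(H)) {
    for (c0 in seq_len(W)) {
      if (!bin[r0, c0] || lab[r0, c0] != 0L) next
      nextLabel <- nextLabel + 1L
      top <- 1L
      stack[1L] <- (c0 - 1L) * H + r0
      lab[r0, c0] <- nextLabel
      while (top > 0L) {
        idx <- stack[top]; top <- top - 1L
        r <- ((idx - 1L) %% H) + 1L
        cc <- ((idx - 1L) %/% H) + 1L
        for (dr in -1L:1L) {
          rr <- r + dr
          if (rr < 1L || rr > H) next
          for (dc in -1L:1L) {
            ccn <- cc + dc
            if (ccn < 1L || ccn > W) next
            if (bin[rr, ccn] && lab[rr, ccn] == 0L) {
              lab[rr, ccn] <- nextLabel
              top <- top + 1L
              if (top > length(stack)) stack <- c(stack, integer(length(stack)))
              stack[top] <- (ccn - 1L) * H + rr
            }
          }
        }
      }
    }
  }
  attr(lab, "nLabels") <- nextLabel
  lab
}

# Moore-neighbor tracing of the external boundary of component `id` in a
# label matrix; returns an n x 2 matrix of 0-based (x, y) boundary points in
# clockwise order (image coordinates, y down). Jacob's stopping criterion.
traceBoundary <- function(lab, id) {
  H <- nrow(lab); W <- ncol(lab)
  # clockwise neighbor order: E, SE, S, SW, W, NW, N, NE as (dx, dy), y down
  dx <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  dy <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  fg <- function(x, y) {  # 0-based query with out-of-frame = background
    x >= 0L && x < W && y >= 0L && y < H && lab[y + 1L, x + 1L] == id
  }
  # start at topmost-leftmost pixel of the component (row-major scan)
  hit <- which(t(lab) == id)[1L]  # t() makes which() scan row-major
  sy <- (hit - 1L) %/% W          # 0-based row
  sx <- (hit - 1L) %% W           # 0-based col
  pts <- matrix(c(sx, sy), ncol = 2)
  cx <- sx; cy <- sy
  d <- 6L  # came "from the west" conceptually: start searching at N... see below
  # For the topmost-leftmost start, searching clockwise from direction index
  # 6 (N) first re-checks the guaranteed-background north/west side, so the
  # first foreground neighbor found is the correct clockwise successor.
  first <- NULL
  maxSteps <- 4L * (H * W + 4L)
  for (step in seq_len(maxSteps)) {
    found <- FALSE
    for (i in 0:7) {
      nd <- (d + i) %% 8L
      nx <- cx + dx[nd + 1L]; ny <- cy + dy[nd + 1L]
      if (fg(nx, ny)) { found <- TRUE; break }
    }
    if (!found) break  # isolated single pixel
    if (is.null(first)) {
      first <- c(nx, ny)
    } else if (cx == sx && cy == sy && nx == first[1] && ny == first[2]) {
      break  # back at start, repeating the first move
    }
    pts <- rbind(pts, c(nx, ny))
    cx <- nx; cy <- ny
    d <- (nd + 6L) %% 8L  # backtrack direction + 1 step clockwise
  }
  if (nrow(pts) > 1L && all(pts[nrow(pts), ] == pts[1L, ])) {
    pts <- pts[-nrow(pts), , drop = FALSE]
  }
  colnames(pts) <- c("x", "y")
  pts
}

# collapse collinear runs of a closed polyline to segment endpoints
# (simplified chain approximation)
simplifyChain <- function(pts) {
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  prv <- pts[c(n, seq_len(n - 1L)), , drop = FALSE]
  nxt <- pts[c(seq_len(n - 1L) + 1L, 1L), , drop = FALSE]
  d1 <- pts - prv
  d2 <- nxt - pts
  # boundary steps are unit king moves, so a point is interior to a straight
  # run iff its incoming and outgoing step vectors are identical
  keep <- d1[, 1] != d2[, 1] | d1[, 2] != d2[, 2]
  if (!any(keep)) keep[1L] <- TRUE
  pts[keep, , drop = FALSE]
}

# shoelace polygon area of a closed polyline (n x 2)
polygonArea <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) return(0)
  x <- pts[, 1]; y <- pts[, 2]
  xn <- x[c(2:n, 1L)]; yn <- y[c(2:n, 1L)]
  abs(sum(x * yn - xn * y)) / 2
}

#' Detect motion regions between two consecutive frames
#'
#' Runs the full frame-differencing operator chain (see
#' [MotionParams-class]) and returns the surviving motion regions, attributed
#' to the later frame \code{frameB}. Regions are ordered by top-left corner
#' (y, then x), then by decreasing area.
#'
#' @param frameA,frameB consecutive frames of equal dimensions (grayscale
#'   matrices or H x W x 3 arrays, intensities in [0, 255]).
#' @param params a [MotionParams-class] object.
#' @return data.frame with one row per motion region: columns \code{x},
#'   \code{y} (0-based top-left corner), \code{w}, \code{h} (pixels),
#'   \code{area} (contour polygon area) and a list-column \code{contour}
#'   (n x 2 matrices of 0-based boundary points).
#' @examples
#' a <- matrix(0, 64, 64)
#' b <- a; b[20:50, 20:50] <- 255
#' detectMotionRegions(a, b, MotionParams(minContourArea = 100))
#' @export
detectMotionRegions <- function(frameA, frameB, params = MotionParams()) {
  regionsFromMask(motionMask(frameA, frameB, params), params@minContourArea)
}

#' Binary foreground mask of the differencing chain
#'
#' The intermediate result of [detectMotionRegions()] before contour
#' extraction: the thresholded, dilated absolute difference of the blurred
#' grayscale frames. Exposed for debugging and verification.
#'
#' @inheritParams detectMotionRegions
#' @return logical H x W matrix (TRUE = foreground).
#' @export
motionMask <- function(frameA, frameB, params = MotionParams()) {
  validObject(params)
  da <- dim(frameA); db <- dim(frameB)
  if (length(da) != length(db) || any(da != db)) {
    stopInput("frames have mismatched dimensions (%s vs %s)",
              paste(da, collapse = "x"), paste(db, collapse = "x"))
  }
  ga <- gaussianBlur(grayscaleFrame(frameA), params@blurKernel, params@blurSigma)
  gb <- gaussianBlur(grayscaleFrame(frameB), params@blurKernel, params@blurSigma)
  dd <- dilateMax(abs(ga - gb), params@dilateKernel)
  dd > params@diffThreshold
}

# contour extraction + area filter + enclosing rectangles from a binary mask
regionsFromMask <- function(bin, minContourArea) {
  empty <- data.frame(x = integer(), y = integer(), w = integer(),
                      h = integer(), area = numeric())
  empty$contour <- list()
  if (!any(bin)) return(empty)
  lab <- labelComponents8(bin)
  rows <- list()
  for (id in seq_len(attr(lab, "nLabels"))) {
    contour <- simplifyChain(traceBoundary(lab, id))
    area <- polygonArea(contour)
    if (area < minContourArea) next
    idx <- which(lab == id, arr.ind = TRUE)
    x <- min(idx[, 2]) - 1L
    y <- min(idx[, 1]) - 1L
    w <- max(idx[, 2]) - min(idx[, 2]) + 1L
    h <- max(idx[, 1]) - min(idx[, 1]) + 1L
    rows[[length(rows) + 1L]] <-
      list(x = x, y = y, w = w, h = h, area = area, contour = contour)
  }
  if (!length(rows)) return(empty)
  out <- data.frame(
    x = vapply(rows, `[[`, integer(1), "x"),
    y = vapply(rows, `[[`, integer(1), "y"),
    w = vapply(rows, `[[`, integer(1), "w"),
    h = vapply(rows, `[[`, integer(1), "h"),
    area = vapply(rows, `[[`, numeric(1), "area")
  )
  out$contour <- lapply(rows, `[[`, "contour")
  ord <- order(out$y, out$x, -out$area)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Motion-region centers
#'
#' The center of a region's enclosing rectangle, \code{(x + w/2, y + h/2)},
#' kept as real numbers (no integer truncation).
#'
#' @param regions motion-region data.frame (columns x, y, w, h).
#' @return n x 2 numeric matrix with columns \code{cx}, \code{cy}.
#' @examples
#' regionCenter(data.frame(x = 10, y = 20, w = 4, h = 6))  # 12, 23
#' @export
regionCenter <- function(regions) {
  m <- cbind(cx = regions$x + regions$w / 2, cy = regions$y + regions$h / 2)
  m
}
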