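# Frame-sequence and annotation I/O.
#
# Frames are numeric matrices (grayscale) or H x W x 3 arrays with intensity
# values in [0, 255] and a "frameIndex" attribute (1-based). Pixel
# coordinates throughout the package are 0-based with x = column, y = row and
# origin at the top-left corner.

frameIndexOf <- function(frame) attr(frame, "frameIndex")

frameDims <- function(frame) {
  d <- dim(frame)
  c(height = d[1], width = d[2])
}

#' Load a frame sequence
#'
#' Reads a contiguous range of frames from a directory of PNG images
#' (lexicographically ordered, e.g. \code{frame_000001.png} ...). Video
#' containers must be decoded to such a PNG sequence beforehand (e.g. with
#' ffmpeg); processing on the decoded sequence keeps results independent of
#' the container.
#'
#' @param path directory containing the PNG frames.
#' @param first,last 1-based inclusive frame range; \code{last = NULL} means
#'   the last available frame.
#' @return list of frames, each an H x W (grayscale) matrix or H x W x 3
#'   array of intensities in [0, 255] with attribute \code{frameIndex}.
#' @examples
#' dir <- tempfile()
#' writeFrames(list(matrix(0, 8, 8), matrix(255, 8, 8)), dir)
#' frames <- loadFrames(dir)
#' length(frames)
#' @export
loadFrames <- function(path, first = 1L, last = NULL) {
  if (!is.character(path) || length(path) != 1L) {
    stopInput("'path' must be a single path")
  }
  if (!file.exists(path)) stopInput("input path does not exist: %s", path)
  if (!dir.exists(path)) {
    stopInput(paste0(
      "'%s' is not a frame directory; video files are not decoded directly. ",
      "Extract frames to PNG first (e.g. ffmpeg -i video.mp4 ",
      "frame_%%06d.png) and pass the directory."), path)
  }
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  total <- length(files)
  if (total == 0L) stopInput("no PNG frames found in %s", path)
  if (is.null(last)) last <- total
  first <- as.integer(first)
  last <- as.integer(last)
  if (first < 1L || first > last) {
    stopInput("invalid frame range [%d, %d]", first, last)
  }
  if (last > total) {
    stopInput("frame range [%d, %d] exceeds the %d available frames",
              first, last, total)
  }
  lapply(seq(first, last), function(i) {
    px <- tryCatch(png::readPNG(files[i]), error = function(e) {
      stopInput("frame %d (%s) could not be decoded: %s",
                i, basename(files[i]), conditionMessage(e))
    })
    if (length(dim(px)) == 3L && dim(px)[3] >= 3L) px <- px[, , 1:3]
    frame <- px * 255
    attr(frame, "frameIndex") <- i
    frame
  })
}

#' Write a frame sequence as numbered PNGs
#'
#' @param frames list of frames (intensities in [0, 255]).
#' @param path output directory, created if needed.
#' @param startIndex index used for the first file name.
#' @return invisibly, the written file paths.
#' @export
writeFrames <- function(frames, path, startIndex = 1L) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  paths <- vapply(seq_along(frames), function(i) {
    fp <- file.path(path, sprintf("frame_%06d.png", startIndex + i - 1L))
    png::writePNG(clamp(frames[[i]] / 255, 0, 1), fp)
    fp
  }, character(1))
  invisible(paths)
}

#' Select the middle n frames of a video
#'
#' Returns the 1-based inclusive window of \code{n} contiguous frames
#' centered in a video of \code{totalFrames} frames, anchored so that a
#' 744-frame video yields frames 358 to 387 for n = 30.
#'
#' @param totalFrames total number of frames in the video.
#' @param n window length.
#' @return named integer vector \code{c(first, last)}.
#' @examples
#' selectMiddleFrames(744, 30)  # 358 387
#' @export
selectMiddleFrames <- function(totalFrames, n) {
  checkScalarNumber(totalFrames, "totalFrames", min = 1)
  checkScalarNumber(n, "n", min = 1)
  if (n > totalFrames) {
    stopInput("window length n = %d exceeds totalFrames = %d", n, totalFrames)
  }
  first <- floor((totalFrames - n) / 2) + 1L
  c(first = as.integer(first), last = as.integer(first + n - 1L))
}

#' Read and write ground-truth labels (Darknet dialect)
#'
#' One text file per frame, one box per line:
#' \code{class cx cy w h} with the box center and size normalized to [0, 1]
#' by frame width/height, written with 6 decimals. The single object class is
#' \code{0} ("BEE").
#'
#' @param path label file path.
#' @return \code{readLabels()}: data.frame with columns classId, cx, cy, w, h
#'   (normalized); zero rows for an empty file.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLabels(data.frame(classId = 0L, cx = 0.5, cy = 0.5, w = 0.1, h = 0.1), f)
#' readLabels(f)
#' @export
readLabels <- function(path) {
  if (!file.exists(path)) stopInput("label file does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(classId = integer(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric()))
  }
  parsed <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(fields) != 5L || anyNA(vals)) {
      stopInput("malformed label line %d in %s: '%s'", i, path, lines[i])
    }
    vals
  })
  m <- do.call(rbind, parsed)
  out <- data.frame(classId = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
                    w = m[, 4], h = m[, 5])
  bad <- which(out$cx < 0 | out$cx > 1 | out$cy < 0 | out$cy > 1 |
               out$w < 0 | out$w > 1 | out$h < 0 | out$h > 1)
  if (length(bad)) {
    stopInput("label line %d in %s has coordinates outside [0, 1]",
              bad[1], path)
  }
  out
}

#' @param boxes data.frame with columns classId, cx, cy, w, h (normalized).
#' @return \code{writeLabels()}: the path, invisibly.
#' @rdname readLabels
#' @export
writeLabels <- function(boxes, path) {
  lines <- sprintf("%d %.6f %.6f %.6f %.6f",
                   as.integer(boxes$classId), boxes$cx, boxes$cy,
                   boxes$w, boxes$h)
  writeLines(lines, path)
  invisible(path)
}

#' Convert between normalized labels and pixel boxes
#'
#' Pixel boxes use 0-based corner coordinates (x1, y1) top-left and (x2, y2)
#' bottom-right, x = column, y = row.
#'
#' @param labels data.frame as returned by [readLabels()].
#' @param width,height frame dimensions in pixels.
#' @return \code{labelsToPixelBoxes()}: data.frame x1, y1, x2, y2.
#' @export
labelsToPixelBoxes <- function(labels, width, height) {
  data.frame(
    x1 = labels$cx * width - labels$w * width / 2,
    y1 = labels$cy * height - labels$h * height / 2,
    x2 = labels$cx * width + labels$w * width / 2,
    y2 = labels$cy * height + labels$h * height / 2
  )
}

#' @param boxes data.frame with pixel columns x1, y1, x2, y2.
#' @param classId class index written to the label file.
#' @return \code{pixelBoxesToLabels()}: data.frame classId, cx, cy, w, h.
#' @rdname labelsToPixelBoxes
#' @export
pixelBoxesToLabels <- function(boxes, width, height, classId = 0L) {
  data.frame(
    classId = rep(as.integer(classId), nrow(boxes)),
    cx = (boxes$x1 + boxes$x2) / 2 / width,
    cy = (boxes$y1 + boxes$y2) / 2 / height,
    w = (boxes$x2 - boxes$x1) / width,
    h = (boxes$y2 - boxes$y1) / height
  )
}

# marking colors (RGB, 0-255)
MARK_COLORS <- list(
  aligned = c(255, 165, 0),    # orange
  unaligned = c(255, 0, 0),    # red
  region = c(0, 0, 255),       # blue
  contour = c(255, 255, 0)     # yellow
)

# paint a 1-px rectangle perimeter; coords are 0-based pixels, clamped
paintRect <- function(px, x1, y1, x2, y2, rgb) {
  H <- dim(px)[1]; W <- dim(px)[2]
  r1 <- clamp(round(y1) + 1, 1, H); r2 <- clamp(round(y2) + 1, 1, H)
  c1 <- clamp(round(x1) + 1, 1, W); c2 <- clamp(round(x2) + 1, 1, W)
  for (ch in 1:3) {
    px[r1, c1:c2, ch] <- rgb[ch]
    px[r2, c1:c2, ch] <- rgb[ch]
    px[r1:r2, c1, ch] <- rgb[ch]
    px[r1:r2, c2, ch] <- rgb[ch]
  }
  px
}

# paint contour points (n x 2 matrix of 0-based x, y)
paintContour <- function(px, contour, rgb) {
  H <- dim(px)[1]; W <- dim(px)[2]
  r <- clamp(round(contour[, 2]) + 1, 1, H)
  c <- clamp(round(contour[, 1]) + 1, 1, W)
  for (ch in 1:3) px[cbind(r, c, ch)] <- rgb[ch]
  px
}

#' Render an evaluation marking of a frame
#'
#' Returns a marked copy of the frame using the fixed color scheme: orange
#' rectangles around motion-aligned detections, red around motion-unaligned
#' detections, and blue rectangles with yellow contour polylines for motion
#' regions. Out-of-bounds boxes are clamped; the input frame is not modified.
#'
#' @param frame grayscale matrix or H x W x 3 array, intensities in [0, 255].
#' @param aligned,unaligned detection data.frames (columns x1, y1, x2, y2).
#' @param regions motion-region data.frame as returned by
#'   [detectMotionRegions()].
#' @return H x W x 3 array in [0, 255].
#' @export
renderMarkedFrame <- function(frame, aligned = NULL, unaligned = NULL,
                              regions = NULL) {
  px <- if (length(dim(frame)) == 2L) {
    array(rep(frame, 3), dim = c(dim(frame), 3))
  } else {
    frame[, , 1:3, drop = FALSE]
  }
  attr(px, "frameIndex") <- frameIndexOf(frame)
  if (!is.null(regions) && nrow(regions)) {
    for (i in seq_len(nrow(regions))) {
      px <- paintRect(px, regions$x[i], regions$y[i],
                      regions$x[i] + regions$w[i] - 1,
                      regions$y[i] + regions$h[i] - 1, MARK_COLORS$region)
      px <- paintContour(px, regions$contour[[i]], MARK_COLORS$contour)
    }
  }
  if (!is.null(unaligned) && nrow(unaligned)) {
    for (i in seq_len(nrow(unaligned))) {
      px <- paintRect(px, unaligned$x1[i], unaligned$y1[i], unaligned$x2[i],
                      unaligned$y2[i], MARK_COLORS$unaligned)
    }
  }
  if (!is.null(aligned) && nrow(aligned)) {
    for (i in seq_len(nrow(aligned))) {
      px <- paintRect(px, aligned$x1[i], aligned$y1[i], aligned$x2[i],
                      aligned$y2[i], MARK_COLORS$aligned)
    }
  }
  px
}
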