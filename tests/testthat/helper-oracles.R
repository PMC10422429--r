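# Independent brute-force oracles. Deliberately written as naive per-pixel /
# per-candidate computations, sharing no code path with the package
# implementation (which uses shifted-matrix passes, a BFS labeler, Moore
# tracing and a kd-tree).

bfSigma <- function(k) 0.3 * ((k - 1) / 2 - 1) + 0.8

bfGaussianKernel2d <- function(k, sigma = NA) {
  if (is.na(sigma)) sigma <- bfSigma(k)
  r <- (k - 1) / 2
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  g <- g / sum(g)
  outer(g, g)
}

# full 2-d convolution, explicit loops, replicate (clamped-index) border
bfConvolve <- function(m, ker) {
  H <- nrow(m); W <- ncol(m)
  k <- nrow(ker); r <- (k - 1) / 2
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      acc <- 0
      for (di in -r:r) {
        for (dj in -r:r) {
          ii <- min(max(i + di, 1), H)
          jj <- min(max(j + dj, 1), W)
          acc <- acc + m[ii, jj] * ker[di + r + 1, dj + r + 1]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# per-pixel grayscale dilation (max filter), replicate border
bfDilate <- function(m, k) {
  H <- nrow(m); W <- ncol(m)
  r <- (k - 1) / 2
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      best <- -Inf
      for (di in -r:r) {
        for (dj in -r:r) {
          ii <- min(max(i + di, 1), H)
          jj <- min(max(j + dj, 1), W)
          if (m[ii, jj] > best) best <- m[ii, jj]
        }
      }
      out[i, j] <- best
    }
  }
  out
}

bfGray <- function(frame) {
  if (length(dim(frame)) == 2L) return(frame)
  0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
}

# the full differencing chain up to the binary mask
bfMotionMask <- function(frameA, frameB, blurK = 5, dilateK = 5,
                         threshold = 20) {
  ker <- bfGaussianKernel2d(blurK)
  ga <- bfConvolve(bfGray(frameA), ker)
  gb <- bfConvolve(bfGray(frameB), ker)
  bfDilate(abs(ga - gb), dilateK) > threshold
}

# 8-connected labeling by iterative minimum-label propagation (fixpoint),
# algorithmically unrelated to the package's BFS labeler
bfLabel8 <- function(bin) {
  H <- nrow(bin); W <- ncol(bin)
  lab <- matrix(seq_len(H * W), H, W)
  lab[!bin] <- 0L
  repeat {
    new <- lab
    for (di in -1:1) {
      for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        rs <- max(1, 1 + di):min(H, H + di)
        rt <- rs - di
        cs <- max(1, 1 + dj):min(W, W + dj)
        ct <- cs - dj
        shifted <- matrix(0L, H, W)
        shifted[rt, ct] <- lab[rs, cs]
        upd <- bin & shifted > 0 & (new == 0 | shifted < new)
        new[upd] <- shifted[upd]
      }
    }
    if (all(new == lab)) break
    lab <- new
  }
  # renumber by first appearance in row-major order
  ids <- unique(as.vector(t(lab))[as.vector(t(lab)) > 0])
  out <- matrix(0L, H, W)
  for (i in seq_along(ids)) out[lab == ids[i]] <- i
  out
}

# brute-force radius search over region centers
bfRadiusHits <- function(centers, q, r) {
  if (nrow(centers) == 0L) return(integer())
  d <- sqrt((centers[, 1] - q[1])^2 + (centers[, 2] - q[2])^2)
  which(d <= r)
}

bfIoU <- function(a, b) {
  w <- min(a[3], b[3]) - max(a[1], b[1])
  h <- min(a[4], b[4]) - max(a[2], b[2])
  if (w <= 0 || h <= 0) return(0)
  inter <- w * h
  inter / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

# exhaustive optimal one-to-one assignment maximizing total IoU over pairs
# with IoU > 0; instances must be small (enumerates injective mappings)
bfOptimalMatching <- function(detections, truthBoxes) {
  nt <- nrow(truthBoxes); nd <- nrow(detections)
  iou <- matrix(0, nt, nd)
  for (i in seq_len(nt)) {
    for (j in seq_len(nd)) {
      iou[i, j] <- bfIoU(as.numeric(truthBoxes[i, c("x1", "y1", "x2", "y2")]),
                         as.numeric(detections[j, c("x1", "y1", "x2", "y2")]))
    }
  }
  best <- list(score = -1, pairs = NULL)
  assign_next <- function(i, used, pairs, score) {
    if (i > nt) {
      if (score > best$score) best <<- list(score = score, pairs = pairs)
      return(invisible())
    }
    assign_next(i + 1, used, pairs, score)  # leave truth i unmatched
    for (j in seq_len(nd)) {
      if (!used[j] && iou[i, j] > 0) {
        used[j] <- TRUE
        assign_next(i + 1, used, rbind(pairs, c(i, j)), score + iou[i, j])
        used[j] <- FALSE
      }
    }
  }
  assign_next(1L, rep(FALSE, nd), NULL, 0)
  best
}

# random sparse-blob frame pair for oracle-equivalence checks
randomBlobFrames <- function(H, W, nBlobs = 3) {
  mk <- function() {
    m <- matrix(0, H, W)
    for (b in seq_len(sample(0:nBlobs, 1))) {
      r0 <- sample(H, 1); c0 <- sample(W, 1)
      rh <- sample(2:12, 1); cw <- sample(2:12, 1)
      rows <- r0:min(H, r0 + rh)
      cols <- c0:min(W, c0 + cw)
      m[rows, cols] <- runif(1, 60, 255)
    }
    m
  }
  list(a = mk(), b = mk())
}
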