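# Scene builders shared by tests.

# all-flying configuration: straight/zigzag/parallel mix, no landings
flyingSimConfig <- function(seed = 7L, nBees = 3L, nFrames = 30L) {
  SimConfig(
    nBees = as.integer(nBees), nFrames = as.integer(nFrames),
    seed = as.integer(seed),
    patternMix = c(STRAIGHT = 0.5, INWARD_ZIGZAG = 0.2, OUTWARD_ZIGZAG = 0.2,
                   LAND_AND_CRAWL = 0, PARALLEL = 0.1)
  )
}

testMotionParams <- function() scaledMotionParams(c(240, 320))

# frames with one static dark square "bee" on a flat light background,
# plus matching stationary ground truth
stationaryScene <- function(nFrames = 10, H = 240, W = 320) {
  frame <- matrix(180, H, W)
  frame[100:130, 150:190] <- 40
  frames <- lapply(seq_len(nFrames), function(i) {
    f <- frame
    attr(f, "frameIndex") <- i
    f
  })
  truth <- data.frame(
    frame = seq_len(nFrames), bee = 1L,
    x1 = 149, y1 = 99, x2 = 189, y2 = 129,
    state = "STATIONARY", pattern = "NONE"
  )
  list(frames = frames, truth = truth)
}
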