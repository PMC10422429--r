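# internal helpers shared across modules

# round half away from zero; base round() is banker's and does not reproduce
# the printed tables (e.g. 2.016 -> 2.02)
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# evaluate expr with a fixed RNG seed, restoring global RNG state afterwards
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

stopInput <- function(...) stop(sprintf(...), call. = FALSE)

checkScalarNumber <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stopInput("'%s' must be a single non-missing number", name)
  }
  if (x < min || x > max) {
    stopInput("'%s' must be in [%s, %s], got %s", name, min, max, x)
  }
  invisible(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
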