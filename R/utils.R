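# Small shared internals.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic noise stream that neither reads nor disturbs the caller's
# RNG state; keeps synthesis bit-reproducible.
localNoise <- function(n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::rnorm(n)
}

# Short-term power (mean square) in sliding windows.
shortTermPower <- function(x, sampleRate, window = 0.010, hop = 0.005) {
  win <- max(1L, round(window * sampleRate))
  hp <- max(1L, round(hop * sampleRate))
  if (length(x) < win) return(list(power = mean(x^2), t = length(x) / 2 / sampleRate))
  starts <- seq(1L, length(x) - win + 1L, by = hp)
  p <- vapply(starts, function(s) mean(x[s:(s + win - 1L)]^2), numeric(1))
  list(power = p, t = (starts + win / 2) / sampleRate, hop = hp / sampleRate)
}

rmsDb <- function(x) {
  r <- sqrt(mean(x^2))
  if (r <= 0) -Inf else 20 * log10(r)
}

# Resample a numeric vector to a fixed length by linear interpolation.
resampleTo <- function(x, n) {
  if (length(x) == n) return(as.numeric(x))
  if (length(x) == 1L) return(rep(as.numeric(x), n))
  stats::approx(seq_along(x), x, xout = seq(1, length(x), length.out = n))$y
}

assertScalarNumeric <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}
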