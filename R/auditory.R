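# Perceptual front-end: gammatone filterbank, F0 estimation, salience,
# activity detection, DTW distance.

.fbCache <- new.env(parent = emptyenv())

erbScale <- function(f) 21.4 * log10(4.37 * f / 1000 + 1)
erbScaleInv <- function(e) (10^(e / 21.4) - 1) * 1000 / 4.37
erbBandwidth <- function(f) 24.7 * (4.37 * f / 1000 + 1)

# FFT spectra of truncated 4th-order gammatone impulse responses, cached per
# (sampleRate, nChannels, nfft). Each channel is normalized to unit peak
# magnitude response.
gammatoneBank <- function(sampleRate, nChannels, nfft, fmin = 80) {
  key <- sprintf("%d_%d_%d_%g", sampleRate, nChannels, nfft, fmin)
  if (!is.null(.fbCache[[key]])) return(.fbCache[[key]])
  fmax <- sampleRate / 2 * 0.9
  cf <- erbScaleInv(seq(erbScale(fmin), erbScale(fmax),
                        length.out = nChannels))
  irLen <- min(nfft, 2048L)
  t <- (seq_len(irLen) - 1) / sampleRate
  H <- matrix(0 + 0i, nfft, nChannels)
  for (c in seq_len(nChannels)) {
    b <- 1.019 * erbBandwidth(cf[c])
    ir <- t^3 * exp(-2 * pi * b * t) * cos(2 * pi * cf[c] * t)
    spec <- stats::fft(c(ir, numeric(nfft - irLen)))
    H[, c] <- spec / max(Mod(spec))
  }
  out <- list(cf = cf, H = H)
  .fbCache[[key]] <- out
  out
}

#' Gammatone auditory analysis
#'
#' Filters the waveform through a bank of 4th-order gammatone filters with
#' ERB-spaced center frequencies between `fmin` and 90% of the Nyquist
#' frequency, then frames each channel's power and applies power-law
#' compression (exponent `compression` on frame power, so scaling the
#' waveform by `a` scales every stored energy by `a^(2 * compression)`;
#' the default 0.2 is a strong root compression that keeps the weaker
#' formant channels discriminative).
#'
#' @param waveform numeric vector (non-empty).
#' @param sampleRate Hz.
#' @param nChannels number of filterbank channels.
#' @param frameRate output frames per second.
#' @param fmin lowest center frequency, Hz.
#' @param compression power-law exponent applied to frame power.
#' @return an [AuditoryRepresentation-class].
#' @examples
#' rep <- gammatoneAnalyze(sin(2 * pi * 1000 * (1:4800) / 24000), 24000)
#' rep
#' @export
gammatoneAnalyze <- function(waveform, sampleRate, nChannels = 64L,
                             frameRate = 100, fmin = 80,
                             compression = 0.2) {
  if (length(waveform) == 0) stop("empty waveform")
  n <- length(waveform)
  nfft <- stats::nextn(n + 2048L, 2)
  bank <- gammatoneBank(as.integer(sampleRate), as.integer(nChannels),
                        nfft, fmin)
  W <- stats::fft(c(waveform, numeric(nfft - n)))
  hop <- max(1L, round(sampleRate / frameRate))
  win <- 2L * hop
  starts <- seq(1L, max(1L, n - win + 1L), by = hop)
  ends <- pmin(n, starts + win - 1L)
  tf <- matrix(0, nChannels, length(starts))
  for (c in seq_len(nChannels)) {
    y <- Re(stats::fft(W * bank$H[, c], inverse = TRUE)) / nfft
    cs <- cumsum(c(0, y[seq_len(n)]^2))
    tf[c, ] <- (cs[ends + 1L] - cs[starts]) / (ends - starts + 1L)
  }
  tf[tf < 0] <- 0                      # numerical guard
  tf <- tf^compression
  new("AuditoryRepresentation", tfMatrix = tf, centerFreqs = bank$cf,
      frameRate = sampleRate / hop)
}

#' Autocorrelation F0 estimation
#'
#' Frame-wise normalized autocorrelation applied directly to the waveform;
#' a frame is voiced when its autocorrelation peak within the
#' \[fmin, fmax\] lag range exceeds `voicingThreshold` and the frame has
#' non-negligible energy. Unvoiced frames report 0.
#'
#' @param waveform numeric vector.
#' @param sampleRate Hz.
#' @param fmin,fmax F0 search range, Hz (fmin < fmax).
#' @param frameLength,hop analysis frame length and hop, s.
#' @param voicingThreshold normalized autocorrelation threshold.
#' @return numeric F0 track, Hz per frame (0 = unvoiced), with frame times
#'   (s) in attribute "t".
#' @examples
#' saw <- 2 * ((1:12000) * 200 / 24000 %% 1) - 1
#' f0 <- estimateF0(saw, 24000)
#' @export
estimateF0 <- function(waveform, sampleRate, fmin = 75, fmax = 600,
                       frameLength = 0.04, hop = 0.01,
                       voicingThreshold = 0.5) {
  if (fmin >= fmax) stop("fmin must be below fmax")
  win <- round(frameLength * sampleRate)
  hp <- max(1L, round(hop * sampleRate))
  n <- length(waveform)
  if (n < win) { waveform <- c(waveform, numeric(win - n)); n <- win }
  starts <- seq(1L, n - win + 1L, by = hp)
  lagMin <- max(2L, floor(sampleRate / fmax))
  lagMax <- min(win - 2L, ceiling(sampleRate / fmin))
  energyFloor <- 1e-8
  f0 <- vapply(starts, function(s) {
    fr <- waveform[s:(s + win - 1L)]
    fr <- fr - mean(fr)
    e0 <- sum(fr^2)
    if (e0 < energyFloor) return(0)
    ac <- acfFft(fr, lagMax)
    r <- ac[(lagMin:lagMax) + 1L] / ac[1L]
    k <- which.max(r)
    if (r[k] < voicingThreshold) return(0)
    lag <- lagMin + k - 1L
    # parabolic refinement around the peak
    if (k > 1L && k < length(r)) {
      num <- r[k - 1L] - r[k + 1L]
      den <- r[k - 1L] - 2 * r[k] + r[k + 1L]
      if (abs(den) > 1e-12) lag <- lag + 0.5 * num / den
    }
    sampleRate / lag
  }, numeric(1))
  attr(f0, "t") <- (starts + win / 2) / sampleRate
  f0
}

acfFft <- function(x, maxLag) {
  nfft <- stats::nextn(2L * length(x), 2)
  X <- stats::fft(c(x, numeric(nfft - length(x))))
  ac <- Re(stats::fft(X * Conj(X), inverse = TRUE)) / nfft
  ac[seq_len(maxLag + 1L)]
}

#' @rdname estimateSalience
#' @param wLow,wHigh,wTouch non-negative component weights.
#' @param lowHighBoundary Hz boundary between the bands.
#' @export
salienceWeights <- function(wLow = 1, wHigh = 1, wTouch = 1,
                            lowHighBoundary = 2500) {
  if (wLow < 0 || wHigh < 0 || wTouch < 0)
    stop("salience weights must be >= 0")
  new("SalienceWeights", wLow = wLow, wHigh = wHigh, wTouch = wTouch,
      lowHighBoundary = lowHighBoundary)
}

#' Sensory salience of an utterance
#'
#' Salience combines the averaged low-band acoustic power, the averaged
#' high-band acoustic power, and the averaged touch (tract contact) signal,
#' each weighted. Attending to the low band favors vowel discovery, the
#' high band fricatives, and touch consonantal closures.
#'
#' @param x a [SynthResult-class], or a numeric waveform.
#' @param weights a [SalienceWeights-class].
#' @param sampleRate required when `x` is a plain waveform.
#' @param touch optional logical/numeric contact signal when `x` is a plain
#'   waveform.
#' @return scalar salience >= 0.
#' @examples
#' estimateSalience(numeric(100), salienceWeights(), sampleRate = 24000)
#' @export
estimateSalience <- function(x, weights = salienceWeights(),
                             sampleRate = NULL, touch = NULL) {
  if (is(x, "SynthResult")) {
    wave <- x@waveform; sampleRate <- x@sampleRate
    touch <- as.numeric(x@touch)
  } else {
    wave <- x
    if (is.null(sampleRate)) stop("sampleRate is required for a raw waveform")
    if (is.null(touch)) touch <- 0
  }
  bp <- bandPowers(wave, sampleRate, weights@lowHighBoundary)
  unname(weights@wLow * bp["low"] + weights@wHigh * bp["high"] +
           weights@wTouch * mean(as.numeric(touch)))
}

bandPowers <- function(wave, sampleRate, boundary) {
  n <- length(wave)
  if (n == 0 || all(wave == 0)) return(c(low = 0, high = 0))
  spec <- Mod(stats::fft(wave))^2 / n^2
  half <- seq_len(floor(n / 2) + 1L)
  freqs <- (half - 1L) * sampleRate / n
  c(low = sum(spec[half][freqs <= boundary]),
    high = sum(spec[half][freqs > boundary]))
}

#' Detect active (supra-threshold) regions of a waveform
#'
#' Short-term power is compared against a noise floor; runs of
#' supra-threshold frames become segments, gaps shorter than `minGap` are
#' merged, and segments shorter than `minLen` are dropped. When
#' `noiseFloor` is NULL it is estimated as 4x the median short-term power
#' of the leading 200 ms (assumed silent), with a small absolute floor so
#' that digital silence yields no segments.
#'
#' @param waveform numeric vector.
#' @param sampleRate Hz.
#' @param noiseFloor power (mean-square) threshold, or NULL to estimate.
#' @param minGap merge gaps shorter than this, s.
#' @param minLen drop segments shorter than this, s.
#' @param pad widen each kept segment by this margin (s) on both sides
#'   (clamped to the recording, overlaps re-merged); protects low-energy
#'   onsets and offsets from being clipped.
#' @return data.frame with columns `start`, `end` (s), possibly 0 rows.
#' @examples
#' burst <- c(numeric(2400), sin(2 * pi * 440 * (1:4800) / 24000), numeric(2400))
#' detectActivity(burst, 24000)
#' @export
detectActivity <- function(waveform, sampleRate, noiseFloor = NULL,
                           minGap = 0.2, minLen = 0.05, pad = 0) {
  stp <- shortTermPower(waveform, sampleRate)
  p <- stp$power
  if (is.null(noiseFloor)) {
    lead <- p[stp$t <= 0.2]
    noiseFloor <- 4 * stats::median(if (length(lead)) lead else p)
  }
  if (noiseFloor < 0) stop("noiseFloor must be >= 0")
  thr <- max(noiseFloor, 1e-10)
  active <- p > thr
  if (!any(active)) return(data.frame(start = numeric(), end = numeric()))
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- data.frame(start = stp$t[starts[r$values]],
                     end = stp$t[ends[r$values]])
  # merge narrow gaps
  if (nrow(segs) > 1L) {
    keep <- list(segs[1L, ])
    for (i in 2L:nrow(segs)) {
      last <- keep[[length(keep)]]
      if (segs$start[i] - last$end < minGap) {
        keep[[length(keep)]]$end <- segs$end[i]
      } else keep[[length(keep) + 1L]] <- segs[i, ]
    }
    segs <- do.call(rbind, keep)
  }
  segs <- segs[segs$end - segs$start >= minLen, , drop = FALSE]
  if (pad > 0 && nrow(segs)) {
    segs$start <- pmax(0, segs$start - pad)
    segs$end <- pmin(length(waveform) / sampleRate, segs$end + pad)
    if (nrow(segs) > 1L) {
      keep <- list(segs[1L, ])
      for (i in 2L:nrow(segs)) {
        last <- keep[[length(keep)]]
        if (segs$start[i] <= last$end)
          keep[[length(keep)]]$end <- max(last$end, segs$end[i])
        else keep[[length(keep) + 1L]] <- segs[i, ]
      }
      segs <- do.call(rbind, keep)
    }
  }
  rownames(segs) <- NULL
  segs
}

#' Dynamic time warping distance between auditory representations
#'
#' Standard dynamic programming over the Euclidean frame-distance matrix
#' with the symmetric step set (1,0), (0,1), (1,1) (diagonal weight 2) and
#' normalization by the sum of the two lengths, which makes the distance
#' symmetric, zero exactly for frame-wise identical inputs, and equal to
#' the frame metric itself in the one-frame degenerate case.
#'
#' @param a,b [AuditoryRepresentation-class] objects or channels x frames
#'   matrices with equal channel counts.
#' @return scalar distance >= 0.
#' @examples
#' m <- matrix(runif(12), 3)
#' dtwDistance(m, m)
#' @export
dtwDistance <- function(a, b) {
  ma <- if (is(a, "AuditoryRepresentation")) a@tfMatrix else as.matrix(a)
  mb <- if (is(b, "AuditoryRepresentation")) b@tfMatrix else as.matrix(b)
  if (nrow(ma) != nrow(mb))
    stop("channel count mismatch: ", nrow(ma), " vs ", nrow(mb))
  .dtw_core(ma, mb)
}
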