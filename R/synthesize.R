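#' Synthesize audio from a sequence of control frames
#'
#' Runs the full articulatory synthesis chain: per-frame area functions
#' (with closure/touch detection), the voiced glottal source (amplitude and
#' F0 from p8 and p9), turbulence-noise injection at supra-threshold
#' constrictions plus a short burst at closure releases, and the
#' Kelly-Lochbaum reflection-line tract filter with a one-way nasal branch
#' opened by p10. Synthesis is deterministic: identical frames and
#' configuration give a bit-identical waveform (the turbulence noise comes
#' from a config-seeded stream that does not touch the session RNG).
#'
#' The source F0 maps linearly from p9: `f0 = f0Midrange * (1 + 0.5 p9)`,
#' i.e. 200--600 Hz around the 400 Hz infant mid-range at defaults. The
#' phonation amplitude follows the glottal area parameter as
#' `sin(pi (p8 + 1) / 2)`: zero at p8 = -1 (glottis sealed), maximal at
#' p8 = 0, zero again at p8 = +1 (glottis wide open, no vibration -- the
#' voiceless setting, which maximizes airflow for frication).
#'
#' @param frames control frames: a numeric vector of length 10, an
#'   nFrames x 10 matrix, or a list of frames.
#' @param config a [SynthConfig-class].
#' @return a [SynthResult-class].
#' @examples
#' cfg <- synthConfig()
#' res <- synthesizeFrames(matrix(0, nrow = 20, ncol = 10), cfg)
#' res
#' @export
synthesizeFrames <- function(frames, config) {
  frames <- asFrameMatrix(frames)
  for (i in seq_len(nrow(frames))) controlFrame(frames[i, ])
  at <- areaTouchTrack(frames, config)
  nFrames <- nrow(frames)
  sr <- config@sampleRate
  spf <- max(1L, round(config@framePeriod * sr))
  nSamples <- nFrames * spf

  # per-sample source tracks
  frameMid <- (seq_len(nFrames) - 0.5) * spf
  sampleAt <- seq_len(nSamples)
  f0Frame <- pmin(600, pmax(50, config@f0Midrange * (1 + 0.5 * frames[, 9])))
  ampFrame <- pmax(0, sin(pi * (frames[, 8] + 1) / 2))
  f0s <- interpTrack(frameMid, f0Frame, sampleAt)
  amps <- interpTrack(frameMid, ampFrame, sampleAt)
  src <- glottalSource(f0s, amps * config@sourceGain, config)

  # turbulence: constriction noise + release bursts
  ag <- (frames[, 8] + 1) / 2                       # glottal opening (flow proxy)
  minA <- apply(at$areas, 2, min)
  minAt <- apply(at$areas, 2, which.min)
  flow <- ag / (minA + 0.05)
  turb <- minA > 0 & minA < config@noiseAreaThreshold &
    flow > config@reynoldsThreshold
  nAmp <- ifelse(turb, config@noiseGain * ag, 0)
  nSec <- ifelse(turb, minAt, NA_integer_)
  release <- c(FALSE, at$touch[-nFrames] & !at$touch[-1])
  for (t in which(release)) {
    burst <- t:min(nFrames, t + 1L)
    nAmp[burst] <- nAmp[burst] + 0.25 * config@noiseGain * ag[burst]
    nSec[burst] <- at$touchIndex[t - 1L]
  }
  nSec[is.na(nSec)] <- 1L

  # digital reflection line
  ns <- nrow(at$areas)
  L <- config@tractLength * config@tractScale
  nDig <- max(10L, round(2 * sr * L / config@speedOfSound))
  digAreas <- matrix(0, nDig, nFrames)
  gridMid <- (seq_len(nDig) - 0.5) / nDig
  for (t in seq_len(nFrames)) {
    cum <- cumsum(at$lengths[, t])
    mid <- (cum - at$lengths[, t] / 2) / cum[ns]
    digAreas[, t] <- stats::approx(mid, at$areas[, t], xout = gridMid,
                                   rule = 2)$y
  }
  # preserve exact closures through the resampling
  for (t in seq_len(nFrames)) {
    z <- which(at$areas[, t] == 0)
    if (length(z)) digAreas[pmin(nDig, pmax(1L, round(z / ns * nDig))), t] <- 0
  }
  digNoiseSec <- as.integer(pmin(nDig, pmax(1L, round(nSec / ns * nDig))) - 1L)
  digNoiseSec[nAmp == 0] <- -1L

  noiseRaw <- localNoise(nSamples + 1L, config@noiseSeed)
  noiseHp <- diff(noiseRaw)                          # high-pass source spectrum
  noise <- noiseHp * interpTrack(frameMid, nAmp, sampleAt)

  velarArt <- round(0.45 * ns)
  nasalFrac <- 0.8 * at$port / (at$port + at$areas[velarArt, ] + 1e-6)
  nasalDelay <- max(1L, round(sr * 11.2 * config@tractScale /
                                config@speedOfSound))

  raw <- .kl_filter(src, noise, digNoiseSec, digAreas, nasalFrac,
                    as.integer(round(0.45 * nDig)) - 1L, spf,
                    config@glottalReflect, config@lipReflect,
                    nasalDelay, config@nostrilReflect)
  wave <- dcBlock(raw)

  new("SynthResult", waveform = wave, sampleRate = sr,
      framePeriod = config@framePeriod, touch = at$touch,
      touchIndex = at$touchIndex, areaMatrix = at$areas,
      lengthMatrix = at$lengths, portAreas = at$port)
}

interpTrack <- function(frameMid, values, sampleAt) {
  if (length(values) == 1L) return(rep(values, length(sampleAt)))
  stats::approx(frameMid, values, xout = sampleAt, rule = 2)$y
}

dcBlock <- function(x, r = 0.995) {
  v <- c(x[1], diff(x))
  as.numeric(stats::filter(v, r, method = "recursive"))
}
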