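#' Generate the voiced glottal source
#'
#' A simplified LF-type pulse train: each period consists of a raised-cosine
#' opening segment followed by an exponential return phase, with the shape
#' parameters fixed (open quotient and return-time constant) and only the
#' fundamental frequency and amplitude under external control, matching the
#' two source controls (glottal area and F0) exposed by the synthesizer.
#'
#' @param f0Track per-sample fundamental frequency, Hz, each value in
#'   \[50, 600\].
#' @param amplitudeTrack per-sample amplitude (>= 0); zero gives zero
#'   output.
#' @param config a [SynthConfig-class] (only the sample rate is used).
#' @param openQuotient fraction of the period in the opening segment.
#' @param returnTime return-phase time constant, as fraction of a period.
#' @return numeric vector of source samples, same length as the tracks.
#' @examples
#' cfg <- synthConfig()
#' src <- glottalSource(rep(400, 2400), rep(1, 2400), cfg)
#' @export
glottalSource <- function(f0Track, amplitudeTrack, config,
                          openQuotient = 0.4, returnTime = 0.08) {
  if (length(f0Track) != length(amplitudeTrack))
    stop("f0Track and amplitudeTrack must have the same length")
  if (any(f0Track <= 0)) stop("f0 must be positive")
  if (any(f0Track < 50 | f0Track > 600))
    stop("f0 must lie within [50, 600] Hz")
  sr <- config@sampleRate
  phase <- cumsum(f0Track / sr) %% 1
  g <- numeric(length(phase))
  open <- phase < openQuotient
  g[open] <- 0.5 * (1 - cos(pi * phase[open] / openQuotient))
  ret <- !open
  g[ret] <- exp(-(phase[ret] - openQuotient) / returnTime)
  amplitudeTrack * g
}
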