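#' Articulatory model coefficient table
#'
#' Loads the linear-component coefficient table of the articulatory model:
#' for each of the tract sections (glottis to lips) a neutral cross-sectional
#' area plus the additive contribution of each articulatory parameter (jaw,
#' tongue dorsum position and shape, tongue apex, lip aperture) and the
#' multiplicative length contributions of lip protrusion and larynx height.
#' The shipped table is a constructed, physiologically-motivated set of
#' coefficients (region layout after the classic seven-parameter
#' articulatory models); it is deliberately a plain CSV so alternative
#' coefficient sets can be swapped in via the `path` argument of
#' [synthConfig()].
#'
#' @param path CSV path; defaults to the table shipped with the package.
#' @param nSections resample the table to this many sections.
#' @return numeric matrix with columns `neutral_area`, `jaw`, `dorsum_pos`,
#'   `dorsum_shape`, `apex`, `lip_aperture`, `len_protrusion`,
#'   `len_larynx`.
#' @export
articulatoryCoefficients <- function(path = NULL, nSections = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "articulatory_model.csv",
                        package = "vocalearn", mustWork = TRUE)
  tab <- utils::read.csv(path)
  need <- c("neutral_area", "jaw", "dorsum_pos", "dorsum_shape", "apex",
            "lip_aperture", "len_protrusion", "len_larynx")
  if (!all(need %in% names(tab)))
    stop("coefficient table must provide columns: ", paste(need, collapse = ", "))
  m <- as.matrix(tab[, need])
  if (!is.null(nSections) && nSections != nrow(m)) {
    m <- apply(m, 2, resampleTo, n = nSections)
    colnames(m) <- need
  }
  m
}

#' Create a synthesizer configuration
#'
#' Defaults follow the study conditions: 24 kHz output, tract dimensions
#' scaled to 0.8 of the adult-female model to approximate an infant tract,
#' and the source F0 mid-range shifted to 400 Hz.
#'
#' @param sampleRate output sampling rate, Hz.
#' @param tractScale scaling of tract dimensions, in (0, 1].
#' @param f0Midrange F0 at source parameter p9 = 0, Hz.
#' @param nTubeSections articulatory tract sections (>= 8).
#' @param framePeriod control frame period, s.
#' @param noiseGain turbulence noise gain.
#' @param reynoldsThreshold flow-proxy threshold for turbulence onset.
#' @param noiseAreaThreshold constriction area below which turbulence can
#'   arise, cm^2.
#' @param maxPortArea maximum velopharyngeal port area, cm^2.
#' @param coefficientsPath optional CSV with an alternative articulatory
#'   coefficient table.
#' @param noiseSeed seed of the deterministic turbulence-noise stream.
#' @return a [SynthConfig-class] object.
#' @examples
#' cfg <- synthConfig()
#' cfg@sampleRate
#' @export
synthConfig <- function(sampleRate = 24000, tractScale = 0.8,
                        f0Midrange = 400, nTubeSections = 29L,
                        framePeriod = 0.005, noiseGain = 0.6,
                        reynoldsThreshold = 2.0, noiseAreaThreshold = 0.3,
                        maxPortArea = 0.8, coefficientsPath = NULL,
                        noiseSeed = 20141021L) {
  coefs <- articulatoryCoefficients(coefficientsPath,
                                    nSections = as.integer(nTubeSections))
  new("SynthConfig",
      sampleRate = sampleRate, tractScale = tractScale,
      f0Midrange = f0Midrange, nTubeSections = as.integer(nTubeSections),
      framePeriod = framePeriod, noiseGain = noiseGain,
      reynoldsThreshold = reynoldsThreshold,
      noiseAreaThreshold = noiseAreaThreshold, maxPortArea = maxPortArea,
      tractLength = 17.5, speedOfSound = 35000,
      glottalReflect = 0.75, lipReflect = -0.85, nostrilReflect = -0.85,
      sourceGain = 1.2, noiseSeed = as.integer(noiseSeed),
      coefficients = coefs)
}

#' Validate a vector of synthesizer control parameters
#'
#' A control frame holds the ten synthesizer parameters p1 (jaw), p2
#' (tongue dorsum position), p3 (dorsum shape), p4 (tongue apex), p5 (lip
#' aperture), p6 (lip protrusion), p7 (larynx height), p8 (glottal area),
#' p9 (fundamental frequency) and p10 (nasality), all dimensionless in
#' \[-1, 1\]. A frame with any non-finite or out-of-range value is
#' rejected with an error naming the offending parameter.
#'
#' @param p numeric vector of length 10 (optionally named p1..p10).
#' @return the validated frame as a named numeric vector.
#' @examples
#' controlFrame(rep(0, 10))
#' @export
controlFrame <- function(p) {
  if (!is.numeric(p) || length(p) != 10L)
    stop("a control frame must hold exactly 10 numeric parameters")
  bad <- which(!is.finite(p) | abs(p) > 1)
  if (length(bad))
    stop(sprintf("control parameter p%d = %s is outside [-1, 1]",
                 bad[1], format(p[bad[1]])), call. = FALSE)
  stats::setNames(as.numeric(p), paste0("p", 1:10))
}

paramNames <- c("p1_jaw", "p2_dorsum_pos", "p3_dorsum_shape", "p4_apex",
                "p5_lip_aperture", "p6_lip_protrusion", "p7_larynx_height",
                "p8_glottal_area", "p9_f0", "p10_nasality")
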