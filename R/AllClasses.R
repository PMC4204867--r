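# S4 class definitions for the whole package. Validity functions enforce the
# domain invariants; constructors live next to the module code.

#' Synthesizer configuration
#'
#' Holds the physical and numerical settings of the articulatory
#' synthesizer: output sampling rate (24 kHz), the infant scaling of the
#' vocal-tract dimensions (0.8 of the adult-female tract), the mid-range
#' fundamental frequency (400 Hz), the number of articulatory tube sections,
#' the control frame period, and the turbulence-noise settings.
#'
#' @slot sampleRate output sampling rate, Hz.
#' @slot tractScale dimensionless scaling of tract dimensions, in (0, 1].
#' @slot f0Midrange fundamental frequency at source parameter p9 = 0, Hz.
#' @slot nTubeSections number of articulatory tract sections (>= 8).
#' @slot framePeriod control frame period, seconds.
#' @slot noiseGain gain applied to injected turbulence noise.
#' @slot reynoldsThreshold flow-proxy threshold above which turbulence noise
#'   is injected at a constriction.
#' @slot noiseAreaThreshold constriction area (cm^2) below which turbulence
#'   can arise.
#' @slot maxPortArea maximum velopharyngeal port area, cm^2.
#' @slot tractLength unscaled (adult-female) tract length, cm.
#' @slot speedOfSound cm/s, used to size the digital reflection line.
#' @slot glottalReflect,lipReflect,nostrilReflect boundary reflection
#'   coefficients of the reflection-line filter.
#' @slot sourceGain amplitude of the voiced source.
#' @slot noiseSeed integer seed of the deterministic turbulence-noise
#'   stream (keeps synthesis bit-reproducible without touching the session
#'   RNG).
#' @slot coefficients articulatory linear-component coefficient table (one
#'   row per section; see [articulatoryCoefficients()]).
#' @exportClass SynthConfig
setClass("SynthConfig", representation(
  sampleRate = "numeric", tractScale = "numeric", f0Midrange = "numeric",
  nTubeSections = "integer", framePeriod = "numeric", noiseGain = "numeric",
  reynoldsThreshold = "numeric", noiseAreaThreshold = "numeric",
  maxPortArea = "numeric", tractLength = "numeric", speedOfSound = "numeric",
  glottalReflect = "numeric", lipReflect = "numeric",
  nostrilReflect = "numeric", sourceGain = "numeric", noiseSeed = "integer",
  coefficients = "matrix"))

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (object@sampleRate <= 0) msg <- c(msg, "sampleRate must be > 0")
  if (object@tractScale <= 0 || object@tractScale > 1)
    msg <- c(msg, "tractScale must be in (0, 1]")
  if (object@nTubeSections < 8L) msg <- c(msg, "nTubeSections must be >= 8")
  if (object@framePeriod <= 0) msg <- c(msg, "framePeriod must be > 0")
  if (length(msg)) msg else TRUE
})

#' Vocal tract area function
#'
#' Cross-sectional areas and section lengths from glottis to lips for one
#' control frame, plus the velopharyngeal port area.
#'
#' @slot sectionAreas areas in cm^2, glottis to lips; zero means closure.
#' @slot sectionLengths section lengths in cm, all positive.
#' @slot nasalPortArea velopharyngeal port area, cm^2.
#' @exportClass AreaFunction
setClass("AreaFunction", representation(
  sectionAreas = "numeric", sectionLengths = "numeric",
  nasalPortArea = "numeric"))

setValidity("AreaFunction", function(object) {
  msg <- character()
  if (length(object@sectionAreas) != length(object@sectionLengths))
    msg <- c(msg, "areas and lengths must have the same length")
  if (any(object@sectionAreas < 0)) msg <- c(msg, "areas must be >= 0")
  if (any(object@sectionLengths <= 0)) msg <- c(msg, "lengths must be > 0")
  if (object@nasalPortArea < 0) msg <- c(msg, "nasalPortArea must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Result of articulatory synthesis
#'
#' @slot waveform mono waveform at `sampleRate`.
#' @slot sampleRate Hz.
#' @slot framePeriod control frame period, s.
#' @slot touch logical per control frame: is any tract section fully closed?
#' @slot touchIndex integer per frame: section index of the closure
#'   (NA when no contact).
#' @slot areaMatrix nTubeSections x nFrames matrix of section areas.
#' @slot lengthMatrix matching section lengths.
#' @slot portAreas per-frame velopharyngeal port area.
#' @exportClass SynthResult
setClass("SynthResult", representation(
  waveform = "numeric", sampleRate = "numeric", framePeriod = "numeric",
  touch = "logical", touchIndex = "integer", areaMatrix = "matrix",
  lengthMatrix = "matrix", portAreas = "numeric"))

setValidity("SynthResult", function(object) {
  msg <- character()
  if (any(!is.finite(object@waveform))) msg <- c(msg, "waveform must be finite")
  if (length(object@touch) != ncol(object@areaMatrix))
    msg <- c(msg, "touch frame count must equal area frame count")
  if (length(msg)) msg else TRUE
})

#' A single gestural-score sub-pattern
#'
#' One sub-pattern holds a 10-element articulatory target vector, the time
#' each target activates, how long it is held, and one overall transition
#' speed scaling; it serializes to exactly 31 scalars.
#'
#' @slot targets 10 target values in \[-1, 1\].
#' @slot startTimes 10 activation times, s (>= 0).
#' @slot holdDurations 10 hold durations, s (>= 0).
#' @slot speedScaling dimensionless > 0; multiplies the transition rate.
#' @exportClass SubPattern
setClass("SubPattern", representation(
  targets = "numeric", startTimes = "numeric", holdDurations = "numeric",
  speedScaling = "numeric"))

setValidity("SubPattern", function(object) {
  msg <- character()
  if (length(object@targets) != 10L) msg <- c(msg, "targets must have length 10")
  if (length(object@startTimes) != 10L) msg <- c(msg, "startTimes must have length 10")
  if (length(object@holdDurations) != 10L) msg <- c(msg, "holdDurations must have length 10")
  if (length(object@speedScaling) != 1L || object@speedScaling <= 0)
    msg <- c(msg, "speedScaling must be a single value > 0")
  if (any(!is.finite(object@targets)) || any(abs(object@targets) > 1))
    msg <- c(msg, "targets must be finite and within [-1, 1]")
  if (any(object@startTimes < 0)) msg <- c(msg, "startTimes must be >= 0")
  if (any(object@holdDurations < 0)) msg <- c(msg, "holdDurations must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A motor pattern: one to three sub-patterns plus category flags
#'
#' @slot subPatterns list of 1--3 [SubPattern-class] objects.
#' @slot category one of "vowel", "plosive", "fricative", "nasal",
#'   "composite".
#' @slot voiced logical: is voicing enabled for this articulation?
#' @slot nasalPortOpen logical: is the velopharyngeal port opened?
#' @slot id opaque identifier.
#' @exportClass MotorPattern
setClass("MotorPattern", representation(
  subPatterns = "list", category = "character", voiced = "logical",
  nasalPortOpen = "logical", id = "character"))

setValidity("MotorPattern", function(object) {
  msg <- character()
  n <- length(object@subPatterns)
  if (n < 1L || n > 3L) msg <- c(msg, "a motor pattern holds 1 to 3 sub-patterns")
  if (!all(vapply(object@subPatterns, is, logical(1), "SubPattern")))
    msg <- c(msg, "subPatterns must all be SubPattern objects")
  if (!object@category %in% c("vowel", "plosive", "fricative", "nasal", "composite"))
    msg <- c(msg, "unknown category")
  if (length(msg)) msg else TRUE
})

#' Articulator dynamics configuration
#'
#' Transition rate constants of the critically damped second-order
#' articulator model: `omegaDefault` is used for vocalic, sonorant and
#' fricative movements; transitions immediately following a vocal tract
#' closure release use the faster `omegaPostClosure` (160 s^-1), which gives
#' more realistic plosive releases.
#'
#' @slot omegaDefault default transition rate, s^-1.
#' @slot omegaPostClosure rate after a closure release, s^-1
#'   (>= omegaDefault).
#' @slot postClosureWindow seconds after a release during which the fast
#'   rate applies.
#' @exportClass MotorDynamicsConfig
setClass("MotorDynamicsConfig", representation(
  omegaDefault = "numeric", omegaPostClosure = "numeric",
  postClosureWindow = "numeric"))

setValidity("MotorDynamicsConfig", function(object) {
  msg <- character()
  if (object@omegaDefault <= 0) msg <- c(msg, "omegaDefault must be > 0")
  if (object@omegaPostClosure < object@omegaDefault)
    msg <- c(msg, "omegaPostClosure must be >= omegaDefault")
  if (length(msg)) msg else TRUE
})

#' Gammatone time-frequency representation
#'
#' @slot tfMatrix channels x frames matrix of non-negative (compressed)
#'   band energies.
#' @slot centerFreqs strictly increasing channel center frequencies, Hz.
#' @slot frameRate frames per second.
#' @exportClass AuditoryRepresentation
setClass("AuditoryRepresentation", representation(
  tfMatrix = "matrix", centerFreqs = "numeric", frameRate = "numeric"))

setValidity("AuditoryRepresentation", function(object) {
  msg <- character()
  if (nrow(object@tfMatrix) != length(object@centerFreqs))
    msg <- c(msg, "one center frequency per channel is required")
  if (any(object@tfMatrix < 0)) msg <- c(msg, "band energies must be >= 0")
  if (is.unsorted(object@centerFreqs, strictly = TRUE))
    msg <- c(msg, "centerFreqs must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Salience weighting
#'
#' Weights of the components of sensory salience: averaged low-band power,
#' averaged high-band power and the averaged touch signal.
#'
#' @slot wLow,wHigh,wTouch non-negative weights.
#' @slot lowHighBoundary Hz boundary between the low and high bands.
#' @exportClass SalienceWeights
setClass("SalienceWeights", representation(
  wLow = "numeric", wHigh = "numeric", wTouch = "numeric",
  lowHighBoundary = "numeric"))

setValidity("SalienceWeights", function(object) {
  if (object@wLow < 0 || object@wHigh < 0 || object@wTouch < 0)
    "salience weights must be >= 0" else TRUE
})

#' Reward breakdown for one motor pattern
#'
#' @slot salience,diversity,effort,sensitivity the four reward terms.
#' @slot weights named numeric of the four active term weights.
#' @slot total weighted combination: salience and diversity add, effort and
#'   sensitivity subtract.
#' @exportClass RewardBreakdown
setClass("RewardBreakdown", representation(
  salience = "numeric", diversity = "numeric", effort = "numeric",
  sensitivity = "numeric", weights = "numeric", total = "numeric"))

setValidity("RewardBreakdown", function(object) {
  w <- object@weights
  if (!all(c("salience", "diversity", "effort", "sensitivity") %in% names(w)))
    return("weights must name salience, diversity, effort, sensitivity")
  expected <- w[["salience"]] * object@salience +
    w[["diversity"]] * object@diversity -
    w[["effort"]] * object@effort -
    w[["sensitivity"]] * object@sensitivity
  if (!isTRUE(all.equal(expected, object@total, tolerance = 1e-12)))
    return("total must equal the weighted combination of the four terms")
  TRUE
})

#' Discovery configuration
#'
#' Everything the unsupervised motor-pattern discovery stage needs: the
#' attention preset (which sensory channel salience emphasizes), the reward
#' term weights, the diversity space weights, the sensitivity perturbation
#' (0.1 = 5% of the parameter range), the optimizer iteration budget (3),
#' the per-category inventory caps (15 vowels / 15 plosives / 10
#' fricatives), and the embedded synthesis, dynamics and salience settings.
#'
#' @slot attentionPreset "vowel", "fricative" or "plosive".
#' @slot termWeights named weights of salience, diversity, effort,
#'   sensitivity.
#' @slot diversitySpaceWeights named weights of the acoustic, tactile and
#'   motor diversity components.
#' @slot perturbationDelta perturbation added to P1..P5 for the sensitivity
#'   term.
#' @slot optimizerIterations outer iterations of the bounded quasi-Newton
#'   ascent.
#' @slot caps named integer caps c(vowels, plosives, fricatives).
#' @slot seed integer RNG seed.
#' @slot diversityCeiling diversity value returned for an empty memory.
#' @slot patternDuration target hold duration of discovered single-target
#'   patterns, s.
#' @slot nChannels gammatone channels used during discovery.
#' @slot fluxThreshold artifact-filter threshold on relative spectral flux
#'   spikes.
#' @slot synth a [SynthConfig-class].
#' @slot dynamics a [MotorDynamicsConfig-class].
#' @slot salience a [SalienceWeights-class].
#' @exportClass DiscoveryConfig
setClass("DiscoveryConfig", representation(
  attentionPreset = "character", termWeights = "numeric",
  diversitySpaceWeights = "numeric", perturbationDelta = "numeric",
  optimizerIterations = "integer", caps = "integer", seed = "integer",
  diversityCeiling = "numeric", patternDuration = "numeric",
  nChannels = "integer", fluxThreshold = "numeric",
  synth = "SynthConfig", dynamics = "MotorDynamicsConfig",
  salience = "SalienceWeights"))

setValidity("DiscoveryConfig", function(object) {
  msg <- character()
  if (object@perturbationDelta <= 0) msg <- c(msg, "perturbationDelta must be > 0")
  if (any(object@caps <= 0L)) msg <- c(msg, "caps must be > 0")
  if (any(object@termWeights < 0)) msg <- c(msg, "term weights must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Motor-auditory association memory
#'
#' Maps motor-pattern ids to the caregiver response each provoked (audio,
#' auditory representation, optional label), keeps the motor patterns
#' themselves for later recall, and records the ids that were deselected
#' because no response came. An id is never both associated and deselected.
#'
#' @slot entries named list: id -> list(waveform, sampleRate, rep, label,
#'   timestamp).
#' @slot patterns named list: id -> [MotorPattern-class].
#' @slot deselected character vector of deselected ids.
#' @exportClass AssociationMemory
setClass("AssociationMemory", representation(
  entries = "list", patterns = "list", deselected = "character"))

setValidity("AssociationMemory", function(object) {
  msg <- character()
  both <- intersect(names(object@entries), object@deselected)
  if (length(both))
    msg <- c(msg, paste("ids both associated and deselected:",
                        paste(both, collapse = ", ")))
  empty <- vapply(object@entries, function(e) length(e$waveform) == 0, logical(1))
  if (any(empty)) msg <- c(msg, "every association must hold non-empty audio")
  if (length(msg)) msg else TRUE
})

#' A caregiver interface
#'
#' The contract a caregiver must satisfy: `respond(waveform, sampleRate)`
#' returns `NULL` (the utterance is ignored) or `list(waveform, label)`;
#' `speak(labels)` produces a spoken word for the word-teaching stage; and
#' `evaluate(recognizedLabels, targetLabels)` judges an imitation attempt.
#'
#' @slot respond function(waveform, sampleRate) -> NULL or
#'   list(waveform, label).
#' @slot speak function(labels) -> list(waveform, labels) or NULL.
#' @slot evaluate function(recognizedLabels, targetLabels) -> logical.
#' @slot description free-text description.
#' @exportClass Caregiver
setClass("Caregiver", representation(
  respond = "function", speak = "function", evaluate = "function",
  description = "character"))

#' Two-pass recognition template index
#'
#' Caregiver responses clustered (DTW k-medoids) into at most `nCenters`
#' clusters; the first recognition pass scores a segment against the cluster
#' exemplars, the second against all members of the best clusters.
#'
#' @slot exemplars response ids of the cluster exemplars (medoids).
#' @slot members list of member-id vectors, parallel to `exemplars`.
#' @slot ids all response ids the index covers.
#' @exportClass TemplateIndex
setClass("TemplateIndex", representation(
  exemplars = "character", members = "list", ids = "character"))

#' Intonation specification extracted from a caregiver segment
#'
#' @slot startF0,endF0 fitted F0 line evaluated at the segment ends, Hz.
#' @slot duration segment duration clamped to \[0.250, 0.600\] s.
#' @slot caregiverSex "male" or "female".
#' @slot flagged TRUE when no voiced frames were found and a flat default
#'   contour was substituted.
#' @exportClass IntonationSpec
setClass("IntonationSpec", representation(
  startF0 = "numeric", endF0 = "numeric", duration = "numeric",
  caregiverSex = "character", flagged = "logical"))

setValidity("IntonationSpec", function(object) {
  msg <- character()
  if (object@duration < 0.250 - 1e-9 || object@duration > 0.600 + 1e-9)
    msg <- c(msg, "duration must lie within [0.250, 0.600] s")
  if (object@startF0 <= 0 || object@endF0 <= 0)
    msg <- c(msg, "f0 values must be positive")
  if (length(msg)) msg else TRUE
})

#' Per-word recognition trace
#'
#' One element per segment, each holding the ranked pass-1 and pass-2
#' candidates with DTW scores, the chosen response id and its label.
#'
#' @slot segments list of per-segment traces.
#' @exportClass RecognitionTrace
setClass("RecognitionTrace", representation(segments = "list"))

#' A coded transcription record
#'
#' One caregiver response coded within a CVC/CVV frame; `#` codes a silent
#' response and `xxx` an untranscribable one.
#'
#' @slot tokenId token identifier.
#' @slot kind "coded", "silent" or "untranscribable".
#' @slot c1,v1,v2,c2 SAMPA phoneme strings; "" marks an empty slot.
#' @exportClass TranscriptionRecord
setClass("TranscriptionRecord", representation(
  tokenId = "character", kind = "character", c1 = "character",
  v1 = "character", v2 = "character", c2 = "character"))

#' Archiphoneme consolidation table
#'
#' Maps every phoneme of one language to exactly one archiphoneme category
#' (pipe notation, e.g. `|pb|` covering /p/ and /b/), enabling
#' cross-language comparison of transcriptions.
#'
#' @slot language "English", "German" or "French".
#' @slot mapping named character: phoneme -> archiphoneme.
#' @exportClass ArchiphonemeTable
setClass("ArchiphonemeTable", representation(
  language = "character", mapping = "character"))

setValidity("ArchiphonemeTable", function(object) {
  if (anyDuplicated(names(object@mapping)))
    "every phoneme must map to exactly one archiphoneme" else TRUE
})

#' Pairwise dataset comparison result
#'
#' @slot sameCounts named counts per archiphoneme given the same label in
#'   both datasets.
#' @slot diffCounts named counts per unordered archiphoneme pair (names
#'   "a|b" with the two labels sorted).
#' @slot totalSame,totalDifferent totals.
#' @slot skipped tokens missing a label in either dataset.
#' @slot slot which slot (C1/V1/...) was compared.
#' @exportClass ComparisonResult
setClass("ComparisonResult", representation(
  sameCounts = "numeric", diffCounts = "numeric", totalSame = "numeric",
  totalDifferent = "numeric", skipped = "numeric", slot = "character"))

setValidity("ComparisonResult", function(object) {
  msg <- character()
  if (!isTRUE(all.equal(object@totalSame, sum(object@sameCounts))))
    msg <- c(msg, "totalSame must equal the sum of sameCounts")
  if (!isTRUE(all.equal(object@totalDifferent, sum(object@diffCounts))))
    msg <- c(msg, "totalDifferent must equal the sum of diffCounts")
  if (length(msg)) msg else TRUE
})

#' Two-proportion z-test result
#'
#' @slot x1,n1,x2,n2 success and total counts.
#' @slot pHat1,pHat2,pPooled sample and pooled proportions.
#' @slot z the test statistic under the pooled-variance normal
#'   approximation.
#' @slot significantAt subset of c(0.05, 0.01, 0.001) at which the
#'   two-sided test rejects.
#' @exportClass ProportionTest
setClass("ProportionTest", representation(
  x1 = "numeric", n1 = "numeric", x2 = "numeric", n2 = "numeric",
  pHat1 = "numeric", pHat2 = "numeric", pPooled = "numeric", z = "numeric",
  significantAt = "numeric"))

setValidity("ProportionTest", function(object) {
  msg <- character()
  if (object@x1 < 0 || object@x1 > object@n1 ||
      object@x2 < 0 || object@x2 > object@n2)
    msg <- c(msg, "counts must satisfy 0 <= x <= n")
  pp <- (object@x1 + object@x2) / (object@n1 + object@n2)
  if (!isTRUE(all.equal(pp, object@pPooled)))
    msg <- c(msg, "pPooled must equal (x1+x2)/(n1+n2)")
  if (length(msg)) msg else TRUE
})

#' Synthetic caregiver language specification
#'
#' Defines the simulated caregiver's category inventory: labelled vowel
#' formant targets (F1 < F2 < F3), consonant classes given by a burst
#' spectral centroid and voicing flag, and the caregiver F0 range.
#'
#' @slot vowelPrototypes named list: label -> c(F1, F2, F3) in Hz.
#' @slot consonantClasses named list: label -> list(centroid, voiced).
#' @slot f0Range length-2 Hz range.
#' @slot sampleRate Hz of generated audio.
#' @exportClass CaregiverLanguageSpec
setClass("CaregiverLanguageSpec", representation(
  vowelPrototypes = "list", consonantClasses = "list", f0Range = "numeric",
  sampleRate = "numeric"))

setValidity("CaregiverLanguageSpec", function(object) {
  msg <- character()
  if (length(object@vowelPrototypes) < 2L)
    msg <- c(msg, "at least 2 vowel prototypes are required")
  bad <- vapply(object@vowelPrototypes,
                function(f) length(f) != 3L || is.unsorted(f, strictly = TRUE),
                logical(1))
  if (any(bad)) msg <- c(msg, "each vowel needs increasing F1 < F2 < F3")
  if (length(msg)) msg else TRUE
})
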