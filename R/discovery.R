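#' Create a discovery configuration
#'
#' The attention preset picks which sensory channel salience emphasizes and
#' which diversity space dominates: `"vowel"` attends to low-frequency
#' power and acoustic diversity, `"fricative"` to high-frequency power and
#' acoustic diversity, `"plosive"` to touch and tactile diversity. The
#' reward term weights are presets of this implementation (the study never
#' published its values) and are deliberately config-exposed.
#'
#' @param attentionPreset "vowel", "fricative" or "plosive".
#' @param termWeights named weights for salience, diversity, effort,
#'   sensitivity.
#' @param diversitySpaceWeights named weights for the acoustic, tactile and
#'   motor diversity components (preset-dependent default).
#' @param perturbationDelta sensitivity perturbation on P1..P5 (0.1 = 5% of
#'   the full parameter range).
#' @param optimizerIterations outer quasi-Newton iterations per candidate.
#' @param caps named per-category inventory caps.
#' @param seed RNG seed for discovery.
#' @param diversityCeiling diversity returned against an empty memory.
#' @param patternDuration hold duration of discovered single-target
#'   patterns, s.
#' @param nChannels gammatone channels used for acoustic distances during
#'   discovery.
#' @param fluxThreshold artifact filter: reject outputs whose peak
#'   frame-to-frame spectral flux exceeds this multiple of their median
#'   flux.
#' @param synth,dynamics,salience embedded configurations; salience
#'   defaults depend on the preset.
#' @return a [DiscoveryConfig-class].
#' @examples
#' discoveryConfig("vowel", seed = 1)
#' @export
discoveryConfig <- function(attentionPreset = c("vowel", "fricative", "plosive"),
                            termWeights = c(salience = 1, diversity = 1,
                                            effort = 0.05, sensitivity = 0.02),
                            diversitySpaceWeights = NULL,
                            perturbationDelta = 0.1,
                            optimizerIterations = 3L,
                            caps = c(vowels = 15L, plosives = 15L,
                                     fricatives = 10L),
                            seed = 1L, diversityCeiling = 1.0,
                            patternDuration = 0.25, nChannels = 32L,
                            fluxThreshold = 0.15,
                            synth = synthConfig(),
                            dynamics = motorDynamicsConfig(),
                            salience = NULL) {
  attentionPreset <- match.arg(attentionPreset)
  if (is.null(salience)) {
    salience <- switch(attentionPreset,
      vowel     = salienceWeights(wLow = 1,    wHigh = 0.05, wTouch = 0),
      fricative = salienceWeights(wLow = 0.05, wHigh = 1,    wTouch = 0),
      plosive   = salienceWeights(wLow = 0.1,  wHigh = 0.1,  wTouch = 1))
  }
  if (is.null(diversitySpaceWeights)) {
    diversitySpaceWeights <- switch(attentionPreset,
      vowel     = c(acoustic = 1, tactile = 0.1, motor = 0.2),
      fricative = c(acoustic = 1, tactile = 0.1, motor = 0.2),
      plosive   = c(acoustic = 0.2, tactile = 1, motor = 0.2))
  }
  new("DiscoveryConfig", attentionPreset = attentionPreset,
      termWeights = termWeights,
      diversitySpaceWeights = diversitySpaceWeights,
      perturbationDelta = perturbationDelta,
      optimizerIterations = as.integer(optimizerIterations),
      caps = vapply(caps, as.integer, integer(1)), seed = as.integer(seed),
      diversityCeiling = diversityCeiling, patternDuration = patternDuration,
      nChannels = as.integer(nChannels), fluxThreshold = fluxThreshold,
      synth = synth, dynamics = dynamics, salience = salience)
}

#' Motor effort of a trajectory
#'
#' Effort combines the cost of movement -- the time-integral of weighted
#' squared articulator speeds over the pattern's duration, which grows with
#' transition speed -- and the loudness of voicing, the summed phonation
#' contribution of the glottal-area parameter p8. Without the voicing
#' penalty the optimizer would always push voicing to maximum, since that
#' maximizes salience. A static, voiceless posture costs nothing.
#'
#' @param frames nFrames x 10 control-frame matrix (e.g. from
#'   [interpolateTrajectory()]).
#' @param framePeriod frame period, s.
#' @param paramWeights weights of the 7 articulatory parameters' movement
#'   cost.
#' @param voiceWeight weight of the voicing-loudness term.
#' @return scalar effort >= 0.
#' @export
computeEffort <- function(frames, framePeriod = 0.005,
                          paramWeights = rep(1, 7), voiceWeight = 1) {
  frames <- asFrameMatrix(frames)
  move <- 0
  if (nrow(frames) > 1L) {
    v <- diff(frames[, 1:7, drop = FALSE]) / framePeriod
    move <- sum(sweep(v^2, 2, paramWeights, "*")) * framePeriod
  }
  voicing <- pmax(0, sin(pi * (frames[, 8] + 1) / 2))
  move + voiceWeight * sum(voicing) * framePeriod
}

# Sensory/motor features of a pattern, cached for diversity computations:
# auditory representation, fixed-length touch profile, zero-padded motor
# vector, and the synthesis result itself.
patternFeatures <- function(pattern, config) {
  res <- synthesizePattern(pattern, config@synth, config@dynamics)
  rep <- gammatoneAnalyze(res@waveform, res@sampleRate,
                          nChannels = config@nChannels)
  touch <- resampleTo(as.numeric(res@touch), 20L)
  motor <- serializePattern(pattern)
  list(pattern = pattern, synth = res, rep = rep, touch = touch,
       motor = motor)
}

# Fixed-length (93) motor vector: up to 3 serialized sub-patterns,
# zero-padded.
serializePattern <- function(pattern) {
  v <- unlist(lapply(pattern@subPatterns, serializeSubPattern))
  c(v, numeric(93L - length(v)))
}

#' Diversity of a pattern relative to previously kept patterns
#'
#' The weighted sum of the minimum distances from the candidate to all
#' memory patterns in three spaces: acoustic (DTW between gammatone
#' representations), tactile (Euclidean between fixed-length touch
#' profiles, scaled by profile length) and motor (Euclidean between
#' zero-padded serialized vectors, scaled by vector length). Against an
#' empty memory the configured ceiling is returned so the very first
#' pattern is maximally novel.
#'
#' @param features candidate features from `patternFeatures()` (or a
#'   [MotorPattern-class], which is featurized first).
#' @param memory list of feature sets of previously kept patterns.
#' @param config a [DiscoveryConfig-class].
#' @return scalar diversity >= 0.
#' @export
computeDiversity <- function(features, memory, config) {
  if (is(features, "MotorPattern"))
    features <- patternFeatures(features, config)
  if (length(memory) == 0L) return(config@diversityCeiling)
  dA <- min(vapply(memory, function(m) dtwDistance(features$rep, m$rep),
                   numeric(1)))
  dT <- min(vapply(memory, function(m)
    sqrt(mean((features$touch - m$touch)^2)), numeric(1)))
  dM <- min(vapply(memory, function(m)
    sqrt(mean((features$motor - m$motor)^2)), numeric(1)))
  w <- config@diversitySpaceWeights
  unname(w["acoustic"] * dA + w["tactile"] * dT + w["motor"] * dM)
}

#' Articulatory sensitivity of a pattern
#'
#' How much the acoustic output changes under small articulatory
#' perturbation: each of the five parameters P1..P5 of the pattern's (first)
#' target vector is individually increased by `delta` (clipped to +1, all
#' other parameters held), the perturbed posture is re-synthesized and its
#' auditory representation compared to the unperturbed one; the sensitivity
#' is the square root of the sum of squares of the five distances.
#' Perturbed patterns are evaluated and discarded, never stored. Sensitive
#' articulations are penalized during discovery because they only produce
#' their sound under very accurate articulation.
#'
#' @param pattern a [MotorPattern-class].
#' @param delta perturbation size (default 0.1 = 5% of the full range).
#' @param config a [DiscoveryConfig-class].
#' @param distanceFun optional function(patternIndex) -> distance, replacing
#'   the synthesize-and-compare route (used for stubbing in tests).
#' @return scalar sensitivity >= 0.
#' @export
computeSensitivity <- function(pattern, delta = 0.1,
                               config = discoveryConfig(),
                               distanceFun = NULL) {
  if (delta == 0) return(0)
  if (is.null(distanceFun)) {
    # static evaluation posture: the (first) target vector held constant
    posture <- pattern@subPatterns[[1L]]@targets
    if (!pattern@voiced) posture[8] <- 1
    posture[10] <- if (pattern@nasalPortOpen) 1 else -1
    holdFrames <- max(2L, round(0.08 / config@synth@framePeriod))
    analyzeStatic <- function(p) {
      res <- synthesizeFrames(matrix(p, holdFrames, 10L, byrow = TRUE),
                              config@synth)
      gammatoneAnalyze(res@waveform, res@sampleRate,
                       nChannels = config@nChannels)
    }
    baseRep <- analyzeStatic(posture)
    distanceFun <- function(i) {
      pert <- posture
      pert[i] <- min(1, pert[i] + delta)
      dtwDistance(baseRep, analyzeStatic(pert))
    }
  }
  d <- vapply(1:5, distanceFun, numeric(1))
  sqrt(sum(d^2))
}

#' Evaluate the discovery reward for a motor pattern
#'
#' Synthesizes the pattern once and returns the full reward breakdown:
#' `total = w_sal * salience + w_div * diversity - w_eff * effort -
#' w_sens * sensitivity`.
#'
#' @param pattern a [MotorPattern-class].
#' @param memory list of feature sets of previously kept patterns.
#' @param config a [DiscoveryConfig-class].
#' @param features optional precomputed features (skips re-synthesis).
#' @return a [RewardBreakdown-class].
#' @export
evaluateReward <- function(pattern, memory = list(),
                           config = discoveryConfig(), features = NULL) {
  if (is.null(features)) {
    features <- tryCatch(patternFeatures(pattern, config), error = function(e)
      stop("synthesis failed for pattern '", pattern@id, "': ",
           conditionMessage(e), call. = FALSE))
  }
  w <- config@termWeights
  sal <- as.numeric(estimateSalience(features$synth, config@salience))
  div <- computeDiversity(features, memory, config)
  traj <- interpolateTrajectory(pattern, config@dynamics,
                                config@synth@framePeriod)
  eff <- computeEffort(traj, config@synth@framePeriod)
  sens <- if (w[["sensitivity"]] > 0)
    computeSensitivity(pattern, config@perturbationDelta, config) else 0
  total <- w[["salience"]] * sal + w[["diversity"]] * div -
    w[["effort"]] * eff - w[["sensitivity"]] * sens
  new("RewardBreakdown", salience = sal, diversity = div, effort = eff,
      sensitivity = sens, weights = w, total = total)
}

#' Automated artifact filter
#'
#' Replaces the by-hand removal of implausible sounds (synthesizer
#' artifacts such as clicks): an output is rejected when it clips, when
#' more than half of its frames carry essentially no energy, or when its
#' peak frame-to-frame spectral flux exceeds `fluxThreshold` times its
#' median flux (a click signature). The criteria are documented and
#' tunable.
#'
#' @param waveform numeric vector.
#' @param sampleRate Hz.
#' @param fluxThreshold absolute spectral-flux spike threshold (flux of
#'   L1-normalized spectra lies in \[0, 2\]; sustained and transient speech
#'   sounds stay well below ~0.1 while clicks exceed ~0.25).
#' @param checkSilence reject mostly-silent outputs; disabled for
#'   touch-attended (plosive) discovery, where a silent closure is the
#'   desired articulation and only becomes audible in composites.
#' @return list(ok = logical, reasons = character vector).
#' @export
artifactFilter <- function(waveform, sampleRate, fluxThreshold = 0.15,
                           checkSilence = TRUE) {
  reasons <- character()
  if (max(abs(waveform)) >= 0.999) reasons <- c(reasons, "clipping")
  stp <- shortTermPower(waveform, sampleRate)
  if (checkSilence && mean(stp$power < 1e-9) > 0.5)
    reasons <- c(reasons, "mostly silent")
  flux <- spectralFlux(waveform, sampleRate)
  if (length(flux) && max(flux) > fluxThreshold)
    reasons <- c(reasons, "spectral flux spike")
  list(ok = length(reasons) == 0L, reasons = reasons)
}

# Spectral flux between consecutive energetic frames (L1-normalized
# magnitude spectra, squared-difference sum). Frames bordering silence are
# excluded: onsets and offsets are not clicks.
spectralFlux <- function(x, sampleRate, window = 0.02, energyFloor = 1e-6) {
  win <- max(16L, round(window * sampleRate))
  starts <- seq(1L, max(1L, length(x) - win + 1L), by = win %/% 2L)
  if (length(starts) < 2L) return(numeric())
  specs <- vapply(starts, function(s) {
    fr <- x[s:min(length(x), s + win - 1L)]
    m <- Mod(stats::fft(c(fr, numeric(win - length(fr)))))[1:(win %/% 2L)]
    c(mean(fr^2), m / (sum(m) + 1e-12))
  }, numeric(win %/% 2L + 1L))
  energy <- specs[1L, ]
  specs <- specs[-1L, , drop = FALSE]
  ok <- energy > energyFloor
  pairOk <- ok[-length(ok)] & ok[-1L]
  flux <- colSums((specs[, -1L, drop = FALSE] -
                     specs[, -ncol(specs), drop = FALSE])^2)
  flux[pairOk]
}

#' Discover motor patterns by reward optimization
#'
#' Each candidate starts from a uniform random draw over \[-1, 1\] of the
#' seven articulatory targets of a single-target pattern (voicing and the
#' nasal port are explicitly set per preset, not optimized), then runs a
#' bounded quasi-Newton ascent (L-BFGS-B, finite-difference gradients) on
#' the total reward for `optimizerIterations` outer iterations. Candidates
#' whose output fails the automated artifact filter are dropped; kept
#' candidates enter the diversity memory, so later candidates are pushed
#' towards novel articulations.
#'
#' @param config a [DiscoveryConfig-class]; `config@seed` seeds the run.
#' @param nCandidates number of random initializations.
#' @param voiced voicing flag of the generated patterns (preset families
#'   enumerate both settings for plosives and fricatives).
#' @param nasalPort velopharyngeal port flag (TRUE with the plosive preset
#'   gives nasals).
#' @return list with elements `patterns` (kept [MotorPattern-class]
#'   objects), `rewards` (their [RewardBreakdown-class]s), and `log`
#'   (per-candidate data.frame with initial and final reward and the filter
#'   outcome).
#' @export
discoverPatterns <- function(config, nCandidates, voiced = TRUE,
                             nasalPort = FALSE) {
  if (nCandidates == 0L)
    return(list(patterns = list(), rewards = list(),
                log = data.frame()))
  set.seed(config@seed)
  category <- switch(config@attentionPreset,
                     vowel = "vowel", fricative = "fricative",
                     plosive = if (nasalPort) "nasal" else "plosive")
  memory <- list()
  patterns <- list(); rewards <- list(); logRows <- list()

  makePattern <- function(free, id) {
    tg <- c(pmin(1, pmax(-1, free)), voicedP8(voiced), 0,
            if (nasalPort) 1 else -1)
    motorPattern(subPattern(tg, 0, config@patternDuration),
                 category = category, voiced = voiced,
                 nasalPortOpen = nasalPort, id = id)
  }

  for (i in seq_len(nCandidates)) {
    id <- sprintf("%s%s_%03d", substr(category, 1, 1),
                  if (voiced) "v" else "u", i)
    init <- stats::runif(7, -1, 1)
    lastPar <- NULL; lastVal <- NULL
    objective <- function(free) {
      if (!is.null(lastPar) && identical(free, lastPar)) return(lastVal)
      v <- -rewardTotal(evaluateReward(makePattern(free, id), memory, config))
      lastPar <<- free; lastVal <<- v
      v
    }
    # forward-difference gradient (cheaper than optim's central differences;
    # each reward evaluation costs several syntheses)
    gradient <- function(free) {
      f0 <- objective(free)
      h <- 0.02
      vapply(1:7, function(j) {
        fj <- free; fj[j] <- min(1, fj[j] + h)
        (objective(fj) - f0) / (fj[j] - free[j])
      }, numeric(1))
    }
    initVal <- objective(init)
    opt <- stats::optim(init, objective, gradient, method = "L-BFGS-B",
                        lower = rep(-1, 7), upper = rep(1, 7),
                        control = list(maxit = config@optimizerIterations))
    pat <- makePattern(opt$par, id)
    feats <- patternFeatures(pat, config)
    filt <- artifactFilter(feats$synth@waveform, config@synth@sampleRate,
                           config@fluxThreshold,
                           checkSilence = config@attentionPreset != "plosive")
    kept <- filt$ok
    if (kept) {
      rew <- evaluateReward(pat, memory, config, features = feats)
      memory[[length(memory) + 1L]] <- feats
      patterns[[length(patterns) + 1L]] <- pat
      rewards[[length(rewards) + 1L]] <- rew
    }
    logRows[[i]] <- data.frame(
      id = id, initialReward = -initVal, finalReward = -opt$value,
      kept = kept,
      reason = if (kept) "" else paste(filt$reasons, collapse = ";"))
  }
  list(patterns = patterns, rewards = rewards, log = do.call(rbind, logRows))
}

# p8 setting for a voiced vs voiceless articulation: maximal phonation vs
# wide-open silent glottis.
voicedP8 <- function(voiced) if (voiced) 0 else 1
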