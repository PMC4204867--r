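#' Construct a sub-pattern
#'
#' @param targets 10 articulatory targets in \[-1, 1\].
#' @param startTimes 10 activation times (s); scalar recycled.
#' @param holdDurations 10 hold durations (s); scalar recycled.
#' @param speedScaling single transition speed multiplier (> 0).
#' @return a [SubPattern-class].
#' @examples
#' sp <- subPattern(rep(0.2, 10), 0, 0.3)
#' length(serializeSubPattern(sp))
#' @export
subPattern <- function(targets, startTimes = 0, holdDurations = 0.3,
                       speedScaling = 1) {
  if (length(startTimes) == 1L) startTimes <- rep(startTimes, 10L)
  if (length(holdDurations) == 1L) holdDurations <- rep(holdDurations, 10L)
  new("SubPattern", targets = as.numeric(targets),
      startTimes = as.numeric(startTimes),
      holdDurations = as.numeric(holdDurations),
      speedScaling = as.numeric(speedScaling))
}

#' Construct a motor pattern
#'
#' @param subPatterns a [SubPattern-class] or list of 1--3 of them.
#' @param category "vowel", "plosive", "fricative", "nasal" or "composite".
#' @param voiced logical voicing flag.
#' @param nasalPortOpen logical velopharyngeal port flag.
#' @param id opaque identifier.
#' @return a [MotorPattern-class].
#' @export
motorPattern <- function(subPatterns, category = "vowel", voiced = TRUE,
                         nasalPortOpen = FALSE, id = "mp") {
  if (is(subPatterns, "SubPattern")) subPatterns <- list(subPatterns)
  new("MotorPattern", subPatterns = subPatterns, category = category,
      voiced = voiced, nasalPortOpen = nasalPortOpen, id = id)
}

#' Create an articulator dynamics configuration
#'
#' The default transition rate (40 s^-1) matches typical human articulation
#' speeds; transitions immediately after a closure release use 160 s^-1,
#' reflecting the rapid release of air pressure in plosives.
#'
#' @param omegaDefault default transition rate, s^-1.
#' @param omegaPostClosure post-release transition rate, s^-1.
#' @param postClosureWindow window after a release during which the fast
#'   rate applies, s.
#' @return a [MotorDynamicsConfig-class].
#' @export
motorDynamicsConfig <- function(omegaDefault = 40, omegaPostClosure = 160,
                                postClosureWindow = 0.05) {
  new("MotorDynamicsConfig", omegaDefault = omegaDefault,
      omegaPostClosure = omegaPostClosure,
      postClosureWindow = postClosureWindow)
}

#' Critically damped step response
#'
#' The closed-form trajectory of a critically damped second-order system
#' released at rest from `x0` towards target `x1`:
#' `x(t) = x1 + (x0 - x1) (1 + omega t) exp(-omega t)`. It approaches the
#' target monotonically with no overshoot; `omega = sqrt(k/m)` is the
#' natural rate of the underlying spring-mass system.
#'
#' @param x0 starting value.
#' @param x1 target value.
#' @param omega rate constant, s^-1.
#' @param t time (vector), s.
#' @return x(t), same length as `t`.
#' @examples
#' criticallyDampedStep(0, 1, 40, 0.025)  # 1 - 2/e
#' @export
criticallyDampedStep <- function(x0, x1, omega, t) {
  x1 + (x0 - x1) * (1 + omega * t) * exp(-omega * t)
}

#' Interpolate a motor pattern into control-frame trajectories
#'
#' Each articulatory parameter starts from the neutral resting state (0),
#' holds its value until its target activates, then follows the critically
#' damped closed form towards the target at rate
#' `omegaDefault * speedScaling`. Within `postClosureWindow` seconds after
#' any time listed in `releaseTimes` (detected closure releases), the rate
#' switches to `omegaPostClosure`, which produces the faster transitions of
#' plosive releases; at each rate switch the trajectory is re-anchored at
#' its current value so it stays continuous and overshoot-free.
#'
#' @param pattern a [MotorPattern-class].
#' @param dynamics a [MotorDynamicsConfig-class].
#' @param framePeriod control frame period, s.
#' @param releaseTimes times (s) of detected closure releases.
#' @return an nFrames x 10 matrix of control frames, with the frame period
#'   stored in attribute "framePeriod".
#' @examples
#' tr <- interpolateTrajectory(motorPattern(subPattern(rep(0.5, 10))),
#'                             motorDynamicsConfig(), 0.005)
#' dim(tr)
#' @export
interpolateTrajectory <- function(pattern, dynamics = motorDynamicsConfig(),
                                  framePeriod = 0.005,
                                  releaseTimes = numeric()) {
  stopifnot(is(pattern, "MotorPattern"), framePeriod > 0)
  validObject(pattern)
  extent <- patternExtent(pattern)
  nFrames <- max(2L, ceiling(extent / framePeriod))
  times <- (seq_len(nFrames) - 1L) * framePeriod

  # per-parameter event lists: (time, target, omega)
  events <- lapply(1:10, function(j) {
    ev <- do.call(rbind, lapply(pattern@subPatterns, function(sp) {
      c(time = sp@startTimes[j], target = sp@targets[j],
        omega = dynamics@omegaDefault * sp@speedScaling)
    }))
    ev[order(ev[, "time"]), , drop = FALSE]
  })

  out <- matrix(0, nFrames, 10L)
  colnames(out) <- paste0("p", 1:10)
  cur <- numeric(10L); x0 <- numeric(10L); t0 <- numeric(10L)
  tgt <- numeric(10L); om <- rep(dynamics@omegaDefault, 10L)
  nextEv <- rep(1L, 10L)
  releaseTimes <- sort(releaseTimes)

  for (k in seq_len(nFrames)) {
    tk <- times[k]
    fastNow <- length(releaseTimes) &&
      any(releaseTimes <= tk & tk < releaseTimes + dynamics@postClosureWindow)
    for (j in 1:10) {
      ev <- events[[j]]
      while (nextEv[j] <= nrow(ev) && ev[nextEv[j], "time"] <= tk) {
        x0[j] <- cur[j]; t0[j] <- ev[nextEv[j], "time"]
        tgt[j] <- ev[nextEv[j], "target"]
        om[j] <- if (fastNow) dynamics@omegaPostClosure else ev[nextEv[j], "omega"]
        nextEv[j] <- nextEv[j] + 1L
      }
      wantOm <- if (fastNow) dynamics@omegaPostClosure
                else if (nextEv[j] > 1L) events[[j]][nextEv[j] - 1L, "omega"]
                else dynamics@omegaDefault
      if (wantOm != om[j]) {               # rate switch: re-anchor, stay continuous
        x0[j] <- cur[j]; t0[j] <- tk; om[j] <- wantOm
      }
      cur[j] <- if (nextEv[j] > 1L)
        criticallyDampedStep(x0[j], tgt[j], om[j], tk - t0[j])
      else 0
      out[k, j] <- cur[j]
    }
  }
  attr(out, "framePeriod") <- framePeriod
  out
}

#' Total temporal extent of a motor pattern
#'
#' The latest `startTime + holdDuration` over all parameters of all
#' sub-patterns, in seconds.
#'
#' @param pattern a [MotorPattern-class].
#' @export
patternExtent <- function(pattern) {
  max(vapply(pattern@subPatterns,
             function(sp) max(sp@startTimes + sp@holdDurations), numeric(1)))
}

#' Serialize a sub-pattern to a flat 31-element vector
#'
#' The layout is 10 targets, 10 start times, 10 hold durations, then the
#' speed scaling -- 31 scalars in all; `deserializeSubPattern()` inverts it
#' losslessly and rejects vectors of any other length.
#'
#' @param sp a [SubPattern-class].
#' @return numeric vector of length 31.
#' @export
serializeSubPattern <- function(sp) {
  stopifnot(is(sp, "SubPattern"))
  validObject(sp)
  c(sp@targets, sp@startTimes, sp@holdDurations, sp@speedScaling)
}

#' @rdname serializeSubPattern
#' @param v numeric vector of length 31.
#' @export
deserializeSubPattern <- function(v) {
  if (!is.numeric(v) || length(v) != 31L)
    stop("a serialized sub-pattern has exactly 31 elements, got ", length(v))
  subPattern(targets = v[1:10], startTimes = v[11:20],
             holdDurations = v[21:30], speedScaling = v[31])
}

#' Concatenate two motor patterns into a composite
#'
#' The second pattern's start times are offset by the first pattern's
#' extent plus `gap`, so the composite's trajectory is the first pattern's
#' followed by the second's. The combined sub-pattern count may not exceed
#' three (longer sequences are not used).
#'
#' @param a,b [MotorPattern-class] objects.
#' @param gap silence gap between them, s.
#' @return a composite [MotorPattern-class].
#' @export
concatenatePatterns <- function(a, b, gap = 0) {
  nTot <- length(a@subPatterns) + length(b@subPatterns)
  if (nTot > 3L)
    stop("a motor pattern may hold at most 3 sub-patterns (got ", nTot, ")")
  offset <- patternExtent(a) + gap
  shifted <- lapply(b@subPatterns, function(sp) {
    subPattern(sp@targets, sp@startTimes + offset, sp@holdDurations,
               sp@speedScaling)
  })
  motorPattern(c(a@subPatterns, shifted), category = "composite",
               voiced = a@voiced || b@voiced,
               nasalPortOpen = a@nasalPortOpen || b@nasalPortOpen,
               id = paste(a@id, b@id, sep = "+"))
}

#' Synthesize a motor pattern
#'
#' Two-pass synthesis: the pattern is first interpolated with the default
#' articulator rate and its area track inspected for closure releases
#' (touch present at one frame, absent at the next); if any are found the
#' trajectory is recomputed with the faster post-closure rate around each
#' release, and the final trajectory is rendered through
#' [synthesizeFrames()]. The pattern's voicing and nasal-port flags
#' override p8 and p10: voiceless patterns get a wide-open glottis
#' (p8 = +1) and an open port sets p10 = +1.
#'
#' @param pattern a [MotorPattern-class].
#' @param config a [SynthConfig-class].
#' @param dynamics a [MotorDynamicsConfig-class].
#' @return a [SynthResult-class].
#' @export
synthesizePattern <- function(pattern, config = synthConfig(),
                              dynamics = motorDynamicsConfig()) {
  traj <- interpolateTrajectory(pattern, dynamics, config@framePeriod)
  traj <- applyPatternFlags(traj, pattern)
  at <- areaTouchTrack(traj, config)
  rel <- which(c(FALSE, at$touch[-length(at$touch)] & !at$touch[-1]))
  if (length(rel)) {
    traj <- interpolateTrajectory(pattern, dynamics, config@framePeriod,
                                  releaseTimes = (rel - 1L) * config@framePeriod)
    traj <- applyPatternFlags(traj, pattern)
  }
  synthesizeFrames(traj, config)
}

applyPatternFlags <- function(traj, pattern) {
  if (!pattern@voiced) traj[, 8] <- 1          # glottis wide open: no phonation
  traj[, 10] <- if (pattern@nasalPortOpen) 1 else -1
  traj
}
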