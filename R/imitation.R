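#' Segment a spoken word into syllable-sized chunks
#'
#' Words are spoken with pauses between syllables, so segmentation reduces
#' to activity detection: regions whose short-term power exceeds the
#' background noise level, in temporal order.
#'
#' @param waveform word audio.
#' @param sampleRate Hz.
#' @param noiseFloor power threshold; the default absolute floor suits
#'   normalized digital audio, and NULL estimates it from a leading
#'   assumed-silent region (see [detectActivity()]).
#' @param minGap,minLen,pad segmentation settings, s (see
#'   [detectActivity()]; the default padding keeps syllable onsets and
#'   offsets intact).
#' @return data.frame of segments (start/end, s); zero rows means nothing
#'   was heard.
#' @export
segmentWord <- function(waveform, sampleRate, noiseFloor = 1e-6,
                        minGap = 0.15, minLen = 0.05, pad = 0.03) {
  detectActivity(waveform, sampleRate, noiseFloor = noiseFloor,
                 minGap = minGap, minLen = minLen, pad = pad)
}

#' Build the two-pass recognition template index
#'
#' Clusters all stored caregiver responses (DTW K-medoids) into at most
#' `nCenters` clusters -- the default 100 cluster centers are the pass-1
#' templates; the members of the best pass-1 clusters become the pass-2
#' templates. With fewer responses than `nCenters` every response is its
#' own cluster.
#'
#' @param memory an [AssociationMemory-class] (non-empty).
#' @param nCenters maximum number of pass-1 templates.
#' @param seed RNG seed for the clustering.
#' @return a [TemplateIndex-class].
#' @export
buildTemplateIndex <- function(memory, nCenters = 100L, seed = 1L) {
  ids <- names(memory@entries)
  n <- length(ids)
  if (n == 0L) stop("association memory is empty")
  k <- min(nCenters, n)
  if (k == n) {
    return(new("TemplateIndex", exemplars = ids,
               members = as.list(ids), ids = ids))
  }
  set.seed(seed)
  reps <- lapply(memory@entries, `[[`, "rep")
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    D[i, j] <- D[j, i] <- dtwDistance(reps[[i]], reps[[j]])
  pm <- cluster::pam(stats::as.dist(D), k = k, diss = TRUE)
  members <- split(ids, pm$clustering)
  exemplars <- ids[pm$id.med]
  # order members list to parallel exemplars
  members <- members[as.character(seq_len(k))]
  new("TemplateIndex", exemplars = exemplars, members = members, ids = ids)
}

#' Two-pass DTW recognition of one segment
#'
#' Pass 1 scores the segment against the cluster exemplars; pass 2 scores
#' it against every member of the best `nBestClusters` clusters. The
#' global pass-2 best wins and its associated motor pattern becomes the
#' chosen candidate; the remaining pass-2 candidates are retained in score
#' order for retry attempts.
#'
#' @param segmentAudio waveform of one segment.
#' @param sampleRate Hz.
#' @param memory an [AssociationMemory-class].
#' @param index a [TemplateIndex-class] built from `memory`.
#' @param nBestClusters clusters whose members enter pass 2.
#' @param nChannels gammatone channels (must match those used for the
#'   stored representations).
#' @return list(pass1, pass2) data.frames of (id, score) plus `chosenId`
#'   and `label`.
#' @export
recognizeTwoPass <- function(segmentAudio, sampleRate, memory, index,
                             nBestClusters = 5L, nChannels = 32L) {
  if (length(index@exemplars) == 0L) stop("empty template index")
  rep <- gammatoneAnalyze(segmentAudio, sampleRate, nChannels = nChannels)
  score <- function(id) dtwDistance(rep, memory@entries[[id]]$rep)
  p1 <- data.frame(id = index@exemplars,
                   score = vapply(index@exemplars, score, numeric(1)))
  p1 <- p1[order(p1$score), , drop = FALSE]
  bestClusters <- match(p1$id[seq_len(min(nBestClusters, nrow(p1)))],
                        index@exemplars)
  pool <- unique(unlist(index@members[bestClusters]))
  p2 <- data.frame(id = pool, score = vapply(pool, score, numeric(1)))
  p2 <- p2[order(p2$score), , drop = FALSE]
  rownames(p1) <- rownames(p2) <- NULL
  chosen <- p2$id[1L]
  list(pass1 = p1, pass2 = p2, chosenId = chosen,
       label = memory@entries[[chosen]]$label %||% NA_character_)
}

#' Extract an intonation specification from a segment
#'
#' The F0 track over voiced frames is fitted with a least-squares straight
#' line; the line evaluated at the segment ends gives the start and end
#' frequencies, and the segment duration is clamped to \[250, 600\] ms.
#' When no voiced frames are found, a flat contour at the caregiver
#' mapping midpoint is substituted and flagged.
#'
#' @param segmentAudio waveform of one segment.
#' @param sampleRate Hz.
#' @param caregiverSex "male" or "female" (selects the F0 mapping range).
#' @return an [IntonationSpec-class].
#' @export
extractIntonation <- function(segmentAudio, sampleRate,
                              caregiverSex = c("female", "male")) {
  caregiverSex <- match.arg(caregiverSex)
  dur <- min(0.600, max(0.250, length(segmentAudio) / sampleRate))
  f0 <- estimateF0(segmentAudio, sampleRate)
  t <- attr(f0, "t")
  voiced <- f0 > 0
  if (sum(voiced) < 2L) {
    mid <- mean(f0MapRange(caregiverSex))
    return(new("IntonationSpec", startF0 = mid, endF0 = mid,
               duration = dur, caregiverSex = caregiverSex, flagged = TRUE))
  }
  fit <- stats::lm(f0[voiced] ~ t[voiced])
  b <- stats::coef(fit)
  tEnd <- length(segmentAudio) / sampleRate
  rng <- f0MapRange(caregiverSex)
  clampF0 <- function(x) min(max(x, rng[1] * 0.5), rng[2] * 2)
  new("IntonationSpec",
      startF0 = clampF0(unname(b[1])), endF0 = clampF0(unname(b[1] + b[2] * tEnd)),
      duration = dur, caregiverSex = caregiverSex, flagged = FALSE)
}

f0MapRange <- function(caregiverSex) {
  switch(caregiverSex, male = c(100, 300), female = c(150, 400),
         stop("caregiverSex must be 'male' or 'female'"))
}

#' Map a caregiver F0 to the source parameter (and back)
#'
#' Linear scaling between the (-0.9, 0.9) source-parameter range and the
#' caregiver F0 range: 100--300 Hz for a male caregiver, 150--400 Hz for a
#' female one. Out-of-range frequencies clip to the parameter bounds; the
#' inverse map round-trips exactly within bounds. This is the
#' normalization step of intonation transfer: the caregiver's relative
#' pitch is re-expressed in the infant's own F0 range.
#'
#' @param f0 frequency, Hz (> 0).
#' @param caregiverSex "male" or "female".
#' @return parameter value in \[-0.9, 0.9\].
#' @examples
#' frequencyToParam(200, "male")     # 0
#' paramToFrequency(0.9, "female")   # 400
#' @export
frequencyToParam <- function(f0, caregiverSex) {
  if (any(f0 <= 0)) stop("f0 must be positive")
  rng <- f0MapRange(caregiverSex)
  p <- -0.9 + (f0 - rng[1]) / (rng[2] - rng[1]) * 1.8
  pmin(0.9, pmax(-0.9, p))
}

#' @rdname frequencyToParam
#' @param p source parameter value.
#' @export
paramToFrequency <- function(p, caregiverSex) {
  rng <- f0MapRange(caregiverSex)
  rng[1] + (p + 0.9) / 1.8 * (rng[2] - rng[1])
}

#' Imitate a spoken word
#'
#' Segments the word, recognizes each segment against the stored caregiver
#' responses (two-pass DTW), recalls each chosen segment's associated
#' motor pattern, transfers the caregiver's intonation (the fitted F0 line
#' is mapped through [frequencyToParam()] and written linearly across the
#' pattern's p9 trajectory) and duration (hold times rescaled so the
#' pattern extent matches the clamped segment duration), concatenates the
#' per-segment trajectories with short silent gaps, and synthesizes once.
#'
#' @param wordAudio caregiver word audio.
#' @param sampleRate Hz.
#' @param memory an [AssociationMemory-class].
#' @param index a [TemplateIndex-class].
#' @param caregiverSex "male" or "female".
#' @param config a [SynthConfig-class].
#' @param dynamics a [MotorDynamicsConfig-class].
#' @param rank use the rank-th best pass-2 candidate per segment (retry
#'   attempts walk down the ranking).
#' @param noiseFloor segmentation power threshold.
#' @param nChannels gammatone channels for recognition.
#' @return list(waveform, sampleRate, trace ([RecognitionTrace-class]),
#'   labels).
#' @export
imitateWord <- function(wordAudio, sampleRate, memory, index,
                        caregiverSex = "female", config = synthConfig(),
                        dynamics = motorDynamicsConfig(), rank = 1L,
                        nChannels = 32L, noiseFloor = 1e-6) {
  segs <- segmentWord(wordAudio, sampleRate, noiseFloor = noiseFloor)
  if (nrow(segs) == 0L)
    stop(errorCondition("nothing heard: no supra-threshold segments",
                        class = c("vlNothingHeard", "error", "condition")))
  traces <- list()
  trajs <- list()
  gapFrames <- max(1L, round(0.1 / config@framePeriod))
  for (s in seq_len(nrow(segs))) {
    seg <- wordAudio[round(segs$start[s] * sampleRate):
                       min(length(wordAudio), round(segs$end[s] * sampleRate))]
    trace <- recognizeTwoPass(seg, sampleRate, memory, index,
                              nChannels = nChannels)
    useRank <- min(rank, nrow(trace$pass2))
    chosen <- trace$pass2$id[useRank]
    trace$chosenId <- chosen
    trace$label <- memory@entries[[chosen]]$label %||% NA_character_
    inton <- extractIntonation(seg, sampleRate, caregiverSex)
    trace$intonation <- inton
    traces[[s]] <- trace
    pat <- memory@patterns[[chosen]]
    if (is.null(pat)) {
      warning("no motor pattern associated with response '", chosen,
              "'; segment skipped")
      next
    }
    pat <- rescalePatternDuration(pat, inton@duration)
    traj <- interpolateTrajectory(pat, dynamics, config@framePeriod)
    traj <- applyPatternFlags(traj, pat)
    nf <- nrow(traj)
    traj[, 9] <- seq(frequencyToParam(inton@startF0, caregiverSex),
                     frequencyToParam(inton@endF0, caregiverSex),
                     length.out = nf)
    trajs[[length(trajs) + 1L]] <- traj
  }
  if (length(trajs) == 0L)
    stop("no segment could be rendered: all associations missing")
  gap <- matrix(rep(c(rep(0, 7), -1, 0, -1), each = gapFrames),
                gapFrames, 10L)
  full <- trajs[[1L]]
  for (tr in trajs[-1L]) full <- rbind(full, gap, tr)
  res <- synthesizeFrames(full, config)
  list(waveform = res@waveform, sampleRate = res@sampleRate,
       trace = new("RecognitionTrace", segments = traces),
       labels = vapply(traces, function(tr) tr$label %||% NA_character_,
                       character(1)))
}

# Rescale start and hold times so the pattern extent equals `duration`.
rescalePatternDuration <- function(pattern, duration) {
  ext <- patternExtent(pattern)
  if (ext <= 0) return(pattern)
  f <- duration / ext
  sps <- lapply(pattern@subPatterns, function(sp)
    subPattern(sp@targets, sp@startTimes * f, sp@holdDurations * f,
               sp@speedScaling))
  motorPattern(sps, pattern@category, pattern@voiced, pattern@nasalPortOpen,
               pattern@id)
}

#' Run a word-teaching session
#'
#' For each word the caregiver speaks it, the learner imitates, and the
#' caregiver accepts or rejects the attempt; rejected attempts walk down
#' the next-ranked recognition candidates, up to `maxAttempts` per spoken
#' prompt, after which the caregiver gives up on the word.
#'
#' @param wordList list of words, each a character vector of the
#'   caregiver's prototype labels (e.g. `c("b", "a")`).
#' @param caregiverObj a [Caregiver-class] with speak/evaluate behavior.
#' @param memory an [AssociationMemory-class].
#' @param index a [TemplateIndex-class].
#' @param maxAttempts imitation attempts per prompt.
#' @param caregiverSex "male" or "female".
#' @param config,dynamics synthesis settings.
#' @param nChannels gammatone channels for recognition.
#' @return data.frame log: word, attempts, outcome ("learned" /
#'   "given_up" / "nothing_heard").
#' @export
runWordSession <- function(wordList, caregiverObj, memory, index,
                           maxAttempts = 4L, caregiverSex = "female",
                           config = synthConfig(),
                           dynamics = motorDynamicsConfig(),
                           nChannels = 32L) {
  rows <- lapply(wordList, function(word) {
    spoken <- caregiverObj@speak(word)
    if (is.null(spoken))
      return(data.frame(word = paste(word, collapse = "+"), attempts = 0L,
                        outcome = "nothing_heard"))
    for (attempt in seq_len(maxAttempts)) {
      imit <- tryCatch(
        imitateWord(spoken$waveform, config@sampleRate, memory, index,
                    caregiverSex, config, dynamics, rank = attempt,
                    nChannels = nChannels),
        vlNothingHeard = function(e) NULL)
      if (is.null(imit))
        return(data.frame(word = paste(word, collapse = "+"), attempts = attempt,
                          outcome = "nothing_heard"))
      if (isTRUE(caregiverObj@evaluate(imit$labels, spoken$labels)))
        return(data.frame(word = paste(word, collapse = "+"),
                          attempts = attempt, outcome = "learned"))
    }
    data.frame(word = paste(word, collapse = "+"), attempts = maxAttempts,
               outcome = "given_up")
  })
  do.call(rbind, rows)
}
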