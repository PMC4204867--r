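#' Create an empty association memory
#'
#' @return an [AssociationMemory-class] with no entries.
#' @export
associationMemory <- function() {
  new("AssociationMemory", entries = list(), patterns = list(),
      deselected = character())
}

#' Add a motor-pattern/response association
#'
#' Stores the caregiver's response audio, its auditory representation and
#' optional label against the motor pattern id. Re-associating an id
#' replaces the stored response (latest response wins); the id is removed
#' from the deselected set if present.
#'
#' @param memory an [AssociationMemory-class].
#' @param pattern the [MotorPattern-class] that provoked the response.
#' @param responseWave caregiver response waveform (non-empty).
#' @param sampleRate Hz.
#' @param label optional caregiver-provided label.
#' @param rep optional precomputed [AuditoryRepresentation-class].
#' @param nChannels gammatone channels when `rep` must be computed.
#' @return the updated memory.
#' @export
addAssociation <- function(memory, pattern, responseWave, sampleRate,
                           label = NULL, rep = NULL, nChannels = 32L) {
  if (length(responseWave) == 0) stop("response audio must be non-empty")
  if (is.null(rep))
    rep <- gammatoneAnalyze(responseWave, sampleRate, nChannels = nChannels)
  id <- pattern@id
  memory@entries[[id]] <- list(waveform = responseWave,
                               sampleRate = sampleRate, rep = rep,
                               label = label,
                               timestamp = length(memory@entries) + 1L)
  memory@patterns[[id]] <- pattern
  memory@deselected <- setdiff(memory@deselected, id)
  validObject(memory)
  memory
}

#' Detect a caregiver response in a listening-window recording
#'
#' Scans the recording for the first region whose short-term power exceeds
#' the background noise level; returns that segment (start/end in seconds)
#' or NULL when the window stayed quiet. Recordings shorter than the
#' nominal window are processed as-is with a warning.
#'
#' @param recording waveform of the listening window.
#' @param sampleRate Hz.
#' @param noiseFloor power threshold (NULL = estimate, see
#'   [detectActivity()]).
#' @param window nominal listening window, s.
#' @return named numeric c(start, end) or NULL.
#' @export
detectResponse <- function(recording, sampleRate, noiseFloor = NULL,
                           window = 3) {
  if (length(recording) < window * sampleRate)
    warning("recording shorter than the ", window,
            " s listening window; processing as-is")
  segs <- detectActivity(recording, sampleRate, noiseFloor = noiseFloor)
  if (nrow(segs) == 0L) return(NULL)
  c(start = segs$start[1L], end = segs$end[1L])
}

#' Run a caregiver response session
#'
#' For each inventory pattern: synthesize it, present the audio to the
#' caregiver, and listen for a response within the listening window. A
#' detected response is stored as an association (audio, auditory
#' representation and label); silence deselects the pattern. A caregiver
#' error skips the pattern (logged, not deselected), so after the session
#' every inventory id is associated, deselected or skipped.
#'
#' @param inventory list of [MotorPattern-class] objects.
#' @param caregiver a [Caregiver-class].
#' @param memory an [AssociationMemory-class] to extend.
#' @param config a [SynthConfig-class].
#' @param dynamics a [MotorDynamicsConfig-class].
#' @param listenWindow listening window, s.
#' @param latency position of the response within the window, s.
#' @param noiseFloor power threshold for response detection.
#' @return list(memory, log) where log is a per-pattern data.frame with
#'   columns id, outcome ("associated"/"deselected"/"skipped") and label.
#' @export
runResponseSession <- function(inventory, caregiver, memory = associationMemory(),
                               config = synthConfig(),
                               dynamics = motorDynamicsConfig(),
                               listenWindow = 3, latency = 0.25,
                               noiseFloor = 1e-6) {
  if (length(inventory) == 0L) stop("inventory must be non-empty")
  sr <- config@sampleRate
  logRows <- vector("list", length(inventory))
  for (i in seq_along(inventory)) {
    pat <- inventory[[i]]
    res <- synthesizePattern(pat, config, dynamics)
    resp <- tryCatch(caregiver@respond(res@waveform, sr),
                     error = function(e) structure(list(), class = "vlCaregiverError",
                                                   message = conditionMessage(e)))
    if (inherits(resp, "vlCaregiverError")) {
      logRows[[i]] <- data.frame(id = pat@id, outcome = "skipped",
                                 label = NA_character_)
      next
    }
    seg <- NULL
    if (!is.null(resp)) {
      win <- numeric(round(listenWindow * sr))
      at <- round(latency * sr)
      ins <- seq_along(resp$waveform) + at
      ins <- ins[ins <= length(win)]
      win[ins] <- resp$waveform[seq_along(ins)]
      seg <- detectResponse(win, sr, noiseFloor = noiseFloor,
                            window = listenWindow)
    }
    if (is.null(seg)) {
      if (!pat@id %in% names(memory@entries))
        memory@deselected <- union(memory@deselected, pat@id)
      logRows[[i]] <- data.frame(id = pat@id, outcome = "deselected",
                                 label = NA_character_)
    } else {
      memory <- addAssociation(memory, pat, resp$waveform, sr,
                               label = resp$label)
      logRows[[i]] <- data.frame(id = pat@id, outcome = "associated",
                                 label = resp$label %||% NA_character_)
    }
  }
  list(memory = memory, log = do.call(rbind, logRows))
}

#' Construct a caregiver from behavior functions
#'
#' @param respond function(waveform, sampleRate) returning NULL (ignore)
#'   or list(waveform, label).
#' @param speak function(labels) returning list(waveform, labels), used in
#'   word teaching.
#' @param evaluate function(recognizedLabels, targetLabels) -> logical
#'   acceptance judgment.
#' @param description free text.
#' @return a [Caregiver-class].
#' @export
caregiver <- function(respond,
                      speak = function(labels) NULL,
                      evaluate = function(recognized, target) FALSE,
                      description = "custom caregiver") {
  new("Caregiver", respond = respond, speak = speak, evaluate = evaluate,
      description = description)
}

#' A fully synthetic caregiver
#'
#' Emulates the caregiver role with no human in the loop. The caregiver
#' owns a labelled inventory of formant-synthesized prototype tokens (from
#' [generateCaregiverTemplates()]). On hearing an utterance she classifies
#' it against her prototypes by DTW over gammatone representations; if the
#' best distance is within `acceptanceRadius` and a Bernoulli draw passes
#' `responseProbability`, she answers with that prototype's stored
#' reformulation audio and label -- i.e. she renders the infant's sound as
#' a well-formed token of her own inventory rather than copying its
#' acoustics. She speaks words by concatenating her prototype tokens with
#' pauses, and accepts an imitation when its recognized labels match the
#' target word's labels.
#'
#' @param templates labelled token inventory from
#'   [generateCaregiverTemplates()].
#' @param responseProbability probability of responding to a
#'   within-radius utterance.
#' @param acceptanceRadius DTW distance threshold (Inf = respond to
#'   everything).
#' @param nChannels gammatone channels for classification.
#' @param pauseDuration pause between spoken word constituents, s.
#' @return a [Caregiver-class]. Randomness (the response Bernoulli draw)
#'   uses the session RNG; seed the session for reproducibility.
#' @export
simulatedCaregiver <- function(templates, responseProbability = 1,
                               acceptanceRadius = Inf, nChannels = 32L,
                               pauseDuration = 0.3) {
  if (length(templates$tokens) == 0L) stop("empty prototype set")
  if (responseProbability < 0 || responseProbability > 1)
    stop("responseProbability must lie in [0, 1]")
  sr <- templates$sampleRate
  protoLabels <- vapply(templates$tokens, `[[`, character(1), "label")
  protoReps <- lapply(templates$tokens, function(tok)
    gammatoneAnalyze(tok$waveform, sr, nChannels = nChannels))

  classify <- function(wave, inRate) {
    rep <- gammatoneAnalyze(wave, inRate, nChannels = nChannels)
    d <- vapply(protoReps, dtwDistance, numeric(1), a = rep)
    list(best = which.min(d), dist = min(d))
  }

  respond <- function(wave, inRate) {
    cl <- classify(wave, inRate)
    if (cl$dist > acceptanceRadius) return(NULL)
    if (stats::runif(1) >= responseProbability) return(NULL)
    tok <- templates$tokens[[cl$best]]
    list(waveform = tok$waveform, label = tok$label)
  }

  speak <- function(labels) {
    idx <- vapply(labels, function(l) {
      hit <- which(protoLabels == l)
      if (!length(hit)) stop("caregiver has no prototype labelled '", l, "'")
      hit[1L]
    }, integer(1))
    pause <- numeric(round(pauseDuration * sr))
    wave <- numeric(0)
    for (i in idx) wave <- c(wave, templates$tokens[[i]]$waveform, pause)
    list(waveform = c(pause, wave), labels = labels)
  }

  evaluate <- function(recognized, target) {
    length(recognized) == length(target) && all(recognized == target)
  }

  caregiver(respond, speak, evaluate,
            description = sprintf("simulated caregiver (%d prototypes, p=%.2f)",
                                  length(templates$tokens),
                                  responseProbability))
}

#' @rdname simulatedCaregiver
#' @param waveform an utterance to classify and respond to.
#' @param sampleRate its sampling rate.
#' @param caregiverObj a [Caregiver-class] built by `simulatedCaregiver()`.
#' @export
simulateCaregiverResponse <- function(waveform, sampleRate, caregiverObj) {
  caregiverObj@respond(waveform, sampleRate)
}
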