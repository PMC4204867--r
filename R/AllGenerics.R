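# Generics and accessors. Slot access from user code should go through
# these, never through @.

#' @export
setGeneric("waveform", function(x) standardGeneric("waveform"))
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @export
setGeneric("touchSignal", function(x) standardGeneric("touchSignal"))
#' @export
setGeneric("tfMatrix", function(x) standardGeneric("tfMatrix"))
#' @export
setGeneric("centerFreqs", function(x) standardGeneric("centerFreqs"))
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @export
setGeneric("subPatterns", function(x) standardGeneric("subPatterns"))
#' @export
setGeneric("patternId", function(x) standardGeneric("patternId"))
#' @export
setGeneric("patternCategory", function(x) standardGeneric("patternCategory"))
#' @export
setGeneric("isVoiced", function(x) standardGeneric("isVoiced"))
#' @export
setGeneric("associations", function(x) standardGeneric("associations"))
#' @export
setGeneric("associatedPatterns", function(x) standardGeneric("associatedPatterns"))
#' @export
setGeneric("deselectedIds", function(x) standardGeneric("deselectedIds"))
#' @export
setGeneric("rewardTotal", function(x) standardGeneric("rewardTotal"))
#' @export
setGeneric("zStatistic", function(x) standardGeneric("zStatistic"))
#' @export
setGeneric("significantAt", function(x) standardGeneric("significantAt"))
#' @export
setGeneric("sectionAreas", function(x) standardGeneric("sectionAreas"))
#' @export
setGeneric("sectionLengths", function(x) standardGeneric("sectionLengths"))
#' @export
setGeneric("nasalPortArea", function(x) standardGeneric("nasalPortArea"))

#' @describeIn SynthResult-class the synthesized waveform
#' @param x object
#' @export
setMethod("waveform", "SynthResult", function(x) x@waveform)
#' @describeIn SynthResult-class output sampling rate (Hz)
#' @export
setMethod("sampleRate", "SynthResult", function(x) x@sampleRate)
#' @describeIn SynthResult-class per-frame logical closure (touch) signal
#' @export
setMethod("touchSignal", "SynthResult", function(x) x@touch)

#' @describeIn AreaFunction-class section areas, glottis to lips (cm^2)
#' @param x object
#' @export
setMethod("sectionAreas", "AreaFunction", function(x) x@sectionAreas)
#' @describeIn AreaFunction-class section lengths (cm)
#' @export
setMethod("sectionLengths", "AreaFunction", function(x) x@sectionLengths)
#' @describeIn AreaFunction-class velopharyngeal port area (cm^2)
#' @export
setMethod("nasalPortArea", "AreaFunction", function(x) x@nasalPortArea)

#' @describeIn AuditoryRepresentation-class channels x frames energy matrix
#' @param x object
#' @export
setMethod("tfMatrix", "AuditoryRepresentation", function(x) x@tfMatrix)
#' @describeIn AuditoryRepresentation-class channel center frequencies (Hz)
#' @export
setMethod("centerFreqs", "AuditoryRepresentation", function(x) x@centerFreqs)
#' @describeIn AuditoryRepresentation-class frames per second
#' @export
setMethod("frameRate", "AuditoryRepresentation", function(x) x@frameRate)

#' @describeIn MotorPattern-class list of sub-patterns
#' @param x object
#' @export
setMethod("subPatterns", "MotorPattern", function(x) x@subPatterns)
#' @describeIn MotorPattern-class pattern identifier
#' @export
setMethod("patternId", "MotorPattern", function(x) x@id)
#' @describeIn MotorPattern-class pattern category
#' @export
setMethod("patternCategory", "MotorPattern", function(x) x@category)
#' @describeIn MotorPattern-class voicing flag
#' @export
setMethod("isVoiced", "MotorPattern", function(x) x@voiced)

#' @describeIn AssociationMemory-class named list of stored responses
#' @param x object
#' @export
setMethod("associations", "AssociationMemory", function(x) x@entries)
#' @describeIn AssociationMemory-class named list of associated motor patterns
#' @export
setMethod("associatedPatterns", "AssociationMemory", function(x) x@patterns)
#' @describeIn AssociationMemory-class ids deselected for lack of response
#' @export
setMethod("deselectedIds", "AssociationMemory", function(x) x@deselected)

#' @describeIn RewardBreakdown-class the combined reward value
#' @param x object
#' @export
setMethod("rewardTotal", "RewardBreakdown", function(x) x@total)

#' @describeIn ProportionTest-class the z statistic
#' @param x object
#' @export
setMethod("zStatistic", "ProportionTest", function(x) x@z)
#' @describeIn ProportionTest-class significance levels at which H0 is rejected
#' @export
setMethod("significantAt", "ProportionTest", function(x) x@significantAt)

setMethod("show", "MotorPattern", function(object) {
  cat(sprintf("MotorPattern '%s' (%s, %svoiced, port %s): %d sub-pattern(s), %.0f ms\n",
              object@id, object@category,
              if (object@voiced) "" else "un",
              if (object@nasalPortOpen) "open" else "closed",
              length(object@subPatterns), 1000 * patternExtent(object)))
})

setMethod("show", "SynthResult", function(object) {
  cat(sprintf("SynthResult: %.0f ms at %.0f Hz, %d frames, %d with tract contact\n",
              1000 * length(object@waveform) / object@sampleRate,
              object@sampleRate, length(object@touch), sum(object@touch)))
})

setMethod("show", "AuditoryRepresentation", function(object) {
  cat(sprintf("AuditoryRepresentation: %d channels (%.0f-%.0f Hz) x %d frames at %.0f frames/s\n",
              nrow(object@tfMatrix), min(object@centerFreqs),
              max(object@centerFreqs), ncol(object@tfMatrix),
              object@frameRate))
})

setMethod("show", "AssociationMemory", function(object) {
  cat(sprintf("AssociationMemory: %d association(s), %d deselected\n",
              length(object@entries), length(object@deselected)))
  labs <- unlist(lapply(object@entries, function(e) e$label %||% NA_character_))
  if (length(labs) && any(!is.na(labs))) {
    tab <- table(labs, useNA = "no")
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
})

setMethod("show", "RewardBreakdown", function(object) {
  cat(sprintf("Reward %.4f = sal %.4f + div %.4f - eff %.4f - sens %.4f (weighted)\n",
              object@total, object@salience, object@diversity,
              object@effort, object@sensitivity))
})

setMethod("show", "ProportionTest", function(object) {
  sig <- if (length(object@significantAt))
    paste(object@significantAt, collapse = ", ") else "none"
  cat(sprintf("Two-proportion z-test: %d/%d vs %d/%d, z = %.5f, significant at: %s\n",
              object@x1, object@n1, object@x2, object@n2, object@z, sig))
})

setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf("Comparison (%s): %d same, %d different, %d skipped\n",
              object@slot, object@totalSame, object@totalDifferent,
              object@skipped))
})

setMethod("show", "DiscoveryConfig", function(object) {
  cat(sprintf("DiscoveryConfig: preset '%s', delta %.2f, %d optimizer iteration(s), caps %s\n",
              object@attentionPreset, object@perturbationDelta,
              object@optimizerIterations,
              paste(sprintf("%s=%d", names(object@caps), object@caps),
                    collapse = "/")))
})
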