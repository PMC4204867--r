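sr <- 24000
cfg <- synthConfig()

tinyInventory <- function() {
  list(staticPattern(c(0.2, 0, 0, 0, 0.3, 0, 0, 0, 0, -1), 0.2, id = "v1"),
       staticPattern(c(-0.3, 0.1, 0, 0, 0.2, 0, 0, 0, 0, -1), 0.2, id = "v2"),
       staticPattern(c(0, 0, 0, 1, 0, 0, 0, 0, 0, -1), 0.2,
                     category = "fricative", voiced = FALSE, id = "f1"))
}

test_that("response detection finds the first supra-threshold segment", {
  expect_null(detectResponse(numeric(3 * sr), sr, noiseFloor = 1e-6))

  win <- numeric(3 * sr)
  burst <- toneWave(600, 0.5)
  win[seq_along(burst) + sr] <- burst
  seg <- detectResponse(win, sr, noiseFloor = 1e-6)
  expect_equal(unname(seg["start"]), 1.0, tolerance = 0.05)
  expect_equal(unname(seg["end"]), 1.5, tolerance = 0.05)

  hiss <- rnorm(3 * sr) * 1e-5
  expect_null(detectResponse(hiss, sr, noiseFloor = 1e-6))
  expect_warning(detectResponse(numeric(sr), sr, noiseFloor = 1e-6),
                 "shorter")
})

test_that("a session partitions the inventory into associated and deselected", {
  inv <- tinyInventory()
  always <- caregiver(function(w, r) list(waveform = toneWave(300, 0.4),
                                          label = "x"))
  out <- runResponseSession(inv, always, config = cfg)
  expect_length(associations(out$memory), length(inv))
  expect_length(deselectedIds(out$memory), 0)

  never <- caregiver(function(w, r) NULL)
  out2 <- runResponseSession(inv, never, config = cfg)
  expect_length(associations(out2$memory), 0)
  expect_setequal(deselectedIds(out2$memory),
                  vapply(inv, patternId, character(1)))

  # every id ends in exactly one bucket
  expect_identical(sort(c(names(associations(out$memory)),
                          deselectedIds(out$memory))),
                   sort(vapply(inv, patternId, character(1))))
})

test_that("a selective caregiver reinforces exactly the voiced patterns", {
  inv <- tinyInventory()
  voicedOnly <- caregiver(function(w, r) {
    f0 <- estimateF0(w, r)
    if (sum(f0 > 0) > 3) list(waveform = toneWave(300, 0.4), label = "v")
    else NULL
  })
  out <- runResponseSession(inv, voicedOnly, config = cfg)
  voicedIds <- vapply(Filter(isVoiced, inv), patternId, character(1))
  expect_setequal(names(associations(out$memory)), voicedIds)
})

test_that("a caregiver error skips the pattern without deselecting it", {
  inv <- tinyInventory()
  flaky <- caregiver(function(w, r) stop("microphone fell over"))
  out <- runResponseSession(inv, flaky, config = cfg)
  expect_true(all(out$log$outcome == "skipped"))
  expect_length(deselectedIds(out$memory), 0)
})

test_that("an association is never both stored and deselected", {
  mem <- associationMemory()
  p <- tinyInventory()[[1]]
  mem <- addAssociation(mem, p, toneWave(300, 0.2), sr, label = "a")
  expect_error(
    methods::validObject(methods::new("AssociationMemory",
                                      entries = mem@entries,
                                      patterns = mem@patterns,
                                      deselected = patternId(p))),
    "both")
  expect_error(addAssociation(mem, p, numeric(0), sr), "non-empty")
})

test_that("the simulated caregiver classifies, reformulates, and respects probability", {
  tpl <- tinyCaregiverTemplates()
  expect_error(simulatedCaregiver(list(tokens = list(), sampleRate = sr)),
               "empty")

  mute <- simulatedCaregiver(tpl, responseProbability = 0)
  set.seed(1)
  expect_null(simulateCaregiverResponse(tpl$tokens[[1]]$waveform, sr, mute))

  cg <- simulatedCaregiver(tpl, responseProbability = 1)
  set.seed(1)
  r <- simulateCaregiverResponse(tpl$tokens[[1]]$waveform, sr, cg)
  expect_identical(r$label, tpl$tokens[[1]]$label)

  # constructed /a/-like formants resolve to the /a/ prototype, not /i/
  # (vowel-only caregiver: the discrimination under test is between the
  # two vowel prototypes)
  vg <- simulatedCaregiver(generateCaregiverTemplates(
    caregiverLanguageSpec(consonantClasses = list()), 2L, 11L))
  aLike <- formantSynthesize(c(830, 1250, 2750), 220)
  set.seed(2)
  expect_identical(simulateCaregiverResponse(aLike, sr, vg)$label, "a")
  iLike <- formantSynthesize(c(300, 2450, 3050), 220)
  set.seed(2)
  expect_identical(simulateCaregiverResponse(iLike, sr, vg)$label, "i")
})

test_that("sessions with a seeded simulated caregiver are reproducible", {
  tpl <- tinyCaregiverTemplates()
  cg <- simulatedCaregiver(tpl, responseProbability = 0.7)
  inv <- tinyInventory()[1:2]
  set.seed(99)
  out1 <- runResponseSession(inv, cg, config = cfg)
  set.seed(99)
  out2 <- runResponseSession(inv, cg, config = cfg)
  expect_identical(out1$log, out2$log)
})

test_that("vowel-preset patterns recover the caregiver's own vowel categories", {
  # closing the loop: the caregiver's label for the infant's utterance
  # agrees with her classifier applied to the same audio, by construction;
  # check the association labels all come from her vowel inventory
  tpl <- tinyCaregiverTemplates()
  cg <- simulatedCaregiver(tpl, responseProbability = 1)
  inv <- list(staticPattern(c(0.4, 0, 0, 0, 0.4, 0, 0, 0, 0, -1), 0.25, id = "open"),
              staticPattern(c(-0.2, 0.5, 0, 0, 0.3, 0, 0, 0, 0, -1), 0.25, id = "front"))
  set.seed(5)
  out <- runResponseSession(inv, cg, config = cfg)
  labs <- unlist(lapply(associations(out$memory), `[[`, "label"))
  expect_length(labs, 2)
  expect_true(all(labs %in% tpl$labels))
})
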