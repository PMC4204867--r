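sr <- 24000
cfg <- synthConfig()

test_that("word segmentation yields syllable-sized chunks in order", {
  burst <- toneWave(500, 0.3)
  two <- c(numeric(4800), burst, numeric(round(0.4 * sr)), burst,
           numeric(2400))
  segs <- segmentWord(two, sr, noiseFloor = 1e-4)
  expect_identical(nrow(segs), 2L)
  expect_true(all(diff(segs$start) > 0))
  expect_identical(nrow(segmentWord(numeric(sr), sr, noiseFloor = 1e-4)), 0L)
  expect_identical(nrow(segmentWord(toneWave(500, 0.5), sr,
                                    noiseFloor = 1e-4)), 1L)
})

test_that("the template index caps at nCenters with singletons below the cap", {
  tpl <- tinyCaregiverTemplates()              # 16 tokens
  set.seed(8)
  mem <- memoryFromTemplates(tpl)
  idx <- buildTemplateIndex(mem, nCenters = 100L)
  expect_length(idx@exemplars, length(associations(mem)))   # cap inactive

  idx5 <- buildTemplateIndex(mem, nCenters = 5L, seed = 4L)
  expect_length(idx5@exemplars, 5)
  expect_setequal(unlist(idx5@members), names(associations(mem)))
  idx5b <- buildTemplateIndex(mem, nCenters = 5L, seed = 4L)
  expect_identical(idx5@members, idx5b@members)

  expect_error(buildTemplateIndex(associationMemory()), "empty")
})

test_that("a stored response recognizes itself with zero distance", {
  tpl <- tinyCaregiverTemplates()
  set.seed(8)
  mem <- memoryFromTemplates(tpl)
  idx <- buildTemplateIndex(mem)
  id <- names(associations(mem))[3]
  wave <- associations(mem)[[id]]$waveform
  out <- recognizeTwoPass(wave, sr, mem, idx)
  expect_identical(out$chosenId, id)
  expect_equal(out$pass2$score[1], 0, tolerance = 1e-10)
})

test_that("pass 2 pools the members of exactly the best five clusters", {
  tpl <- tinyCaregiverTemplates()
  set.seed(8)
  mem0 <- memoryFromTemplates(tpl)
  # six singleton clusters -> pass-2 pool of five
  keep <- names(associations(mem0))[1:6]
  mem <- associationMemory()
  for (id in keep) {
    mem <- addAssociation(mem, associatedPatterns(mem0)[[id]],
                          associations(mem0)[[id]]$waveform, sr,
                          label = associations(mem0)[[id]]$label)
  }
  idx <- buildTemplateIndex(mem)
  expect_length(idx@exemplars, 6)
  out <- recognizeTwoPass(associations(mem)[[keep[1]]]$waveform, sr, mem, idx)
  expect_identical(nrow(out$pass2), 5L)
})

test_that("intonation extraction fits the F0 line and clamps duration", {
  glide <- formantSynthesize(c(600, 1400, 2700), f0 = 300, f0End = 200,
                             duration = 0.5)
  spec <- extractIntonation(glide, sr, "female")
  expect_equal(spec@startF0, 300, tolerance = 0.05)
  expect_equal(spec@endF0, 200, tolerance = 0.05)
  expect_false(spec@flagged)

  long <- formantSynthesize(c(600, 1400, 2700), 250, duration = 0.7)
  expect_equal(extractIntonation(long, sr, "female")@duration, 0.600)
  shrt <- formantSynthesize(c(600, 1400, 2700), 250, duration = 0.1)
  expect_equal(extractIntonation(shrt, sr, "female")@duration, 0.250)

  hiss <- localNoise <- rep(0, 2400)
  flat <- extractIntonation(hiss, sr, "male")
  expect_true(flat@flagged)
  expect_equal(flat@startF0, 200)     # male mapping midpoint
})

test_that("the F0 parameter map is the stated affine scaling with clipping", {
  expect_equal(paramToFrequency(-0.9, "male"), 100)
  expect_equal(paramToFrequency(0.9, "male"), 300)
  expect_equal(paramToFrequency(-0.9, "female"), 150)
  expect_equal(paramToFrequency(0.9, "female"), 400)
  expect_equal(frequencyToParam(200, "male"), 0)
  expect_equal(frequencyToParam(50, "male"), -0.9)     # clipped
  expect_equal(frequencyToParam(1000, "female"), 0.9)  # clipped
  expect_error(frequencyToParam(-5, "male"), "positive")
  for (f in c(120, 250, 280)) {
    expect_equal(paramToFrequency(frequencyToParam(f, "male"), "male"), f)
  }
})

test_that("imitating a stored response selects its own association", {
  tpl <- tinyCaregiverTemplates()
  set.seed(8)
  mem <- memoryFromTemplates(tpl)
  idx <- buildTemplateIndex(mem)
  for (id in names(associations(mem))[c(1, 5, 11)]) {
    out <- imitateWord(associations(mem)[[id]]$waveform, sr, mem, idx,
                       "female", cfg)
    expect_identical(out$trace@segments[[1]]$chosenId, id)
  }
})

test_that("imitation transfers a rising intonation contour", {
  tpl <- tinyCaregiverTemplates()
  set.seed(8)
  mem <- memoryFromTemplates(tpl)
  idx <- buildTemplateIndex(mem)
  rising <- formantSynthesize(c(700, 1300, 2700), f0 = 180, f0End = 320,
                              duration = 0.45)
  out <- imitateWord(rising, sr, mem, idx, "female", cfg)
  f0 <- estimateF0(out$waveform, sr)
  t <- attr(f0, "t")[f0 > 0]
  v <- f0[f0 > 0]
  expect_gt(length(v), 5)
  expect_gt(unname(coef(lm(v ~ t))[2]), 0)    # rising output pitch
  expect_error(imitateWord(numeric(sr), sr, mem, idx, "female", cfg),
               class = "vlNothingHeard")
})

test_that("a two-segment word recalls two motor patterns in sequence", {
  tpl <- tinyCaregiverTemplates()
  set.seed(8)
  mem <- memoryFromTemplates(tpl)
  idx <- buildTemplateIndex(mem)
  ids <- names(associations(mem))[c(2, 9)]
  word <- c(numeric(2400), associations(mem)[[ids[1]]]$waveform,
            numeric(round(0.3 * sr)), associations(mem)[[ids[2]]]$waveform,
            numeric(2400))
  out <- imitateWord(word, sr, mem, idx, "female", cfg)
  expect_length(out$trace@segments, 2)
  expect_identical(vapply(out$trace@segments, `[[`, character(1), "chosenId"),
                   ids)
  expect_gt(length(out$waveform), 0)
})

test_that("word sessions respect caregiver judgment and the attempt cap", {
  tpl <- tinyCaregiverTemplates()
  set.seed(8)
  mem <- memoryFromTemplates(tpl)
  idx <- buildTemplateIndex(mem)

  accepting <- caregiver(
    respond = function(w, r) NULL,
    speak = simulatedCaregiver(tpl)@speak,
    evaluate = function(rec, tgt) TRUE)
  log1 <- runWordSession(list(c("a"), c("b", "a")), accepting, mem, idx,
                         config = cfg)
  expect_true(all(log1$outcome == "learned"))

  rejecting <- caregiver(
    respond = function(w, r) NULL,
    speak = simulatedCaregiver(tpl)@speak,
    evaluate = function(rec, tgt) FALSE)
  log2 <- runWordSession(list(c("a")), rejecting, mem, idx, config = cfg)
  expect_identical(log2$outcome, "given_up")
  expect_lte(max(log2$attempts), 4)
})
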