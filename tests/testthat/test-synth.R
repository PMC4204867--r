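cfg <- synthConfig()

test_that("control frames are validated with the offending parameter named", {
  expect_silent(controlFrame(rep(0, 10)))
  expect_error(controlFrame(c(1.5, rep(0, 9))), "p1")
  expect_error(controlFrame(c(rep(0, 8), NaN, 0)), "p9")
  expect_error(controlFrame(rep(0, 9)), "10")
})

test_that("neutral posture gives an open tract, extreme lip closure reports touch", {
  af <- computeAreaFunction(rep(0, 10), cfg)
  expect_true(all(sectionAreas(af) > 0))
  expect_equal(length(sectionAreas(af)), length(sectionLengths(af)))

  lips <- rep(0, 10); lips[5] <- -1
  af2 <- computeAreaFunction(lips, cfg)
  n <- length(sectionAreas(af2))
  expect_identical(sectionAreas(af2)[n], 0)
  at <- vocalearn:::areaTouchTrack(matrix(lips, 1), cfg)
  expect_true(at$touch[1])
  expect_gte(at$touchIndex[1], n - 2L)   # touch located at the lip end
})

test_that("areas scale with tractScale and closures survive scaling exactly", {
  lips <- rep(0, 10); lips[5] <- -1
  for (sc in c(0.4, 0.8, 1)) {
    cfgS <- synthConfig(tractScale = sc)
    af <- computeAreaFunction(rep(0, 10), cfgS)
    af0 <- computeAreaFunction(rep(0, 10), synthConfig(tractScale = 1))
    expect_equal(sectionAreas(af), sectionAreas(af0) * sc)
    expect_identical(min(sectionAreas(computeAreaFunction(lips, cfgS))), 0)
  }
})

test_that("nasal port area maps affinely from p10", {
  p <- rep(0, 10)
  p[10] <- -1
  expect_equal(nasalPortArea(computeAreaFunction(p, cfg)), 0)
  p[10] <- 1
  expect_equal(nasalPortArea(computeAreaFunction(p, cfg)), cfg@maxPortArea)
})

test_that("a sustained neutral vowel is voiced at the 400 Hz mid-range", {
  res <- synthesizeFrames(matrix(0, 100, 10), cfg)   # 500 ms
  expect_length(waveform(res), 100 * round(cfg@framePeriod * cfg@sampleRate))
  f0 <- estimateF0(waveform(res), sampleRate(res))
  voiced <- f0[f0 > 0]
  expect_gt(length(voiced), 10)
  expect_lt(abs(median(voiced) - cfg@f0Midrange) / cfg@f0Midrange, 0.10)
})

test_that("narrow voiceless constriction produces frication above 2 kHz", {
  fr <- rep(0, 10); fr[4] <- 1; fr[8] <- 1     # apex raised, glottis open
  res <- synthesizeFrames(matrix(rep(fr, each = 60), 60, 10), cfg)
  w <- waveform(res)
  expect_gt(sqrt(mean(w^2)), 1e-4)
  spec <- Mod(stats::fft(w))^2
  half <- seq_len(length(w) %/% 2)
  freqs <- (half - 1) * cfg@sampleRate / length(w)
  centroid <- sum(freqs * spec[half]) / sum(spec[half])
  expect_gt(centroid, 2000)
})

test_that("sealed glottis with no constriction yields near-silence", {
  fr <- rep(0, 10); fr[8] <- -1
  res <- synthesizeFrames(matrix(rep(fr, each = 60), 60, 10), cfg)
  expect_lt(vocalearn:::rmsDb(waveform(res)), -40)
})

test_that("synthesis is bit-deterministic and rejects empty input", {
  frames <- matrix(rep(c(0.2, 0, 0, 0, 0.3, 0, 0, 0, 0.1, -1), each = 30),
                   30, 10)
  r1 <- synthesizeFrames(frames, cfg)
  r2 <- synthesizeFrames(frames, cfg)
  expect_identical(waveform(r1), waveform(r2))
  expect_error(synthesizeFrames(matrix(0, 0, 10), cfg), "at least one")
  expect_identical(length(touchSignal(r1)), nrow(frames))
})

test_that("halving the tract scale shifts the vowel spectral envelope up", {
  r1 <- synthesizeFrames(matrix(0, 100, 10), synthConfig(tractScale = 0.8))
  r2 <- synthesizeFrames(matrix(0, 100, 10), synthConfig(tractScale = 0.4))
  expect_gt(spectralEnvelopePeak(waveform(r2)),
            spectralEnvelopePeak(waveform(r1)))
})

test_that("glottal source is periodic at the requested frequency", {
  n <- 24000
  src <- glottalSource(rep(400, n), rep(1, n), cfg)
  # peak picking: one flow maximum per period
  peaks <- which(diff(sign(diff(src))) == -2) + 1L
  peaks <- peaks[src[peaks] > 0.5 * max(src)]
  expect_equal(mean(diff(peaks)) / cfg@sampleRate, 1 / 400,
               tolerance = 0.01)

  expect_identical(glottalSource(rep(400, 100), rep(0, 100), cfg),
                   rep(0, 100))
  p100 <- glottalSource(rep(100, n), rep(1, n), cfg)
  p200 <- glottalSource(rep(200, n), rep(1, n), cfg)
  per <- function(x) {
    pk <- which(diff(sign(diff(x))) == -2) + 1L
    pk <- pk[x[pk] > 0.5 * max(x)]
    mean(diff(pk))
  }
  expect_equal(per(p100) / per(p200), 2, tolerance = 0.01)
  expect_error(glottalSource(rep(-10, 5), rep(1, 5), cfg), "positive")
  expect_error(glottalSource(rep(700, 5), rep(1, 5), cfg), "within")
  expect_error(glottalSource(rep(400, 5), rep(1, 4), cfg), "same length")
})

test_that("no source and no noise means silence out", {
  fr <- rep(0, 10); fr[8] <- -1        # sealed glottis, open tract
  res <- synthesizeFrames(matrix(rep(fr, each = 40), 40, 10), cfg)
  expect_lt(max(abs(waveform(res))), 1e-6)
})

test_that("touch is reported exactly when some section area is zero", {
  set.seed(5)
  for (i in 1:20) {
    p <- runif(10, -1, 1)
    at <- vocalearn:::areaTouchTrack(matrix(p, 1), cfg)
    expect_identical(at$touch[1], min(at$areas[, 1]) == 0)
  }
})
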