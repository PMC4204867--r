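# Small problem sizes throughout: every reward evaluation involves real
# synthesis, so candidate counts are kept low.

fastConfig <- function(preset = "vowel", seed = 1L)
  discoveryConfig(preset, seed = seed, patternDuration = 0.2,
                  nChannels = 24L)

test_that("effort is zero for a static voiceless posture and grows with speed", {
  still <- matrix(rep(c(rep(0.3, 7), 1, 0, -1), each = 20), 20, 10)
  expect_equal(computeEffort(still, 0.005), 0)

  # hand-computed oracle on a 3-frame trajectory
  fr <- rbind(c(rep(0, 7), -1, 0, 0),
              c(0.1, rep(0, 6), -1, 0, 0),
              c(0.3, 0.2, rep(0, 5), -1, 0, 0))
  dt <- 0.005
  byHand <- ((0.1 / dt)^2 + (0.2 / dt)^2 + (0.2 / dt)^2) * dt
  expect_equal(computeEffort(fr, dt), byHand)

  slow <- interpolateTrajectory(
    motorPattern(subPattern(c(0.8, rep(0, 9)), 0, 0.3, speedScaling = 1)),
    motorDynamicsConfig(), 0.005)
  fast <- interpolateTrajectory(
    motorPattern(subPattern(c(0.8, rep(0, 9)), 0, 0.3, speedScaling = 2)),
    motorDynamicsConfig(), 0.005)
  slow[, 8] <- fast[, 8] <- 1          # voiceless: isolate the movement term
  expect_gt(computeEffort(fast, 0.005), computeEffort(slow, 0.005))
})

test_that("voicing loudness contributes to effort", {
  voiced <- matrix(rep(c(rep(0, 7), 0, 0, -1), each = 20), 20, 10)
  expect_gt(computeEffort(voiced, 0.005), 0)
})

test_that("diversity is zero for a memorized pattern and the ceiling for empty memory", {
  cfg <- fastConfig()
  p <- staticPattern(c(0.3, -0.2, 0.1, 0, 0.2, 0, 0, 0, 0, -1),
                     duration = 0.2, id = "p1")
  f <- vocalearn:::patternFeatures(p, cfg)
  expect_equal(computeDiversity(f, list(), cfg), cfg@diversityCeiling)
  expect_equal(computeDiversity(f, list(f), cfg), 0)
})

test_that("diversity equals the brute-force minimum over a toy memory", {
  cfg <- fastConfig()
  ps <- lapply(1:3, function(i)
    staticPattern(c(runif(7, -0.5, 0.5), 0, 0, -1), duration = 0.2,
                  id = paste0("m", i)))
  set.seed(21)
  fs <- lapply(ps, vocalearn:::patternFeatures, config = cfg)
  cand <- fs[[1]]
  mem <- fs[2:3]
  w <- cfg@diversitySpaceWeights
  manual <- w[["acoustic"]] * min(dtwDistance(cand$rep, mem[[1]]$rep),
                                  dtwDistance(cand$rep, mem[[2]]$rep)) +
    w[["tactile"]] * min(sqrt(mean((cand$touch - mem[[1]]$touch)^2)),
                         sqrt(mean((cand$touch - mem[[2]]$touch)^2))) +
    w[["motor"]] * min(sqrt(mean((cand$motor - mem[[1]]$motor)^2)),
                       sqrt(mean((cand$motor - mem[[2]]$motor)^2)))
  expect_equal(computeDiversity(cand, mem, cfg), unname(manual))
})

test_that("sensitivity follows the Pythagorean identity and vanishes at delta 0", {
  p <- neutralVowelPattern()
  stub <- function(i) c(3, 4, 0, 0, 0)[i]
  expect_equal(computeSensitivity(p, 0.1, fastConfig(), distanceFun = stub), 5)
  expect_equal(computeSensitivity(p, 0.1, fastConfig(),
                                  distanceFun = function(i) 0), 0)
  expect_equal(computeSensitivity(p, 0, fastConfig()), 0)
})

test_that("sensitivity from the real synthesis route is positive for a vowel", {
  cfg <- fastConfig()
  s <- computeSensitivity(neutralVowelPattern(), 0.1, cfg)
  expect_gt(s, 0)
})

test_that("the reward decomposition reconstructs its total exactly", {
  cfg <- fastConfig()
  p <- staticPattern(c(0.2, 0, 0, 0, 0.3, 0, 0, 0, 0, -1), duration = 0.2)
  rb <- evaluateReward(p, list(), cfg)
  w <- rb@weights
  expect_identical(rb@total,
                   w[["salience"]] * rb@salience +
                     w[["diversity"]] * rb@diversity -
                     w[["effort"]] * rb@effort -
                     w[["sensitivity"]] * rb@sensitivity)

  cfg0 <- cfg; cfg0@termWeights[] <- 0
  expect_equal(rewardTotal(evaluateReward(p, list(), cfg0)), 0)
})

test_that("a silent static pattern with no diversity credit cannot score positive", {
  cfg <- fastConfig()
  cfg@termWeights[["diversity"]] <- 0
  silent <- staticPattern(c(rep(0, 7), -1, 0, -1), duration = 0.2,
                          voiced = FALSE)
  # voiceless flag + sealed-glottis-equivalent: posture makes no sound
  silent@subPatterns[[1]]@targets[8] <- -1
  rb <- evaluateReward(motorPattern(subPattern(c(rep(0, 7), -1, 0, -1), 0, 0.2),
                                    voiced = FALSE, id = "sil"),
                       list(), cfg)
  expect_lte(rewardTotal(rb), 1e-6)
})

test_that("the artifact filter passes speech-like outputs and catches clicks", {
  cfg <- synthConfig()
  vw <- synthesizePattern(staticPattern(c(0.3, 0.2, -0.1, 0, 0.4, 0, 0, 0, 0, -1)),
                          cfg)
  expect_true(artifactFilter(waveform(vw), 24000)$ok)
  clicky <- waveform(vw)
  clicky[6000] <- clicky[6000] + 0.9
  f <- artifactFilter(clicky, 24000)
  expect_false(f$ok)
  expect_true("spectral flux spike" %in% f$reasons)
  expect_false(artifactFilter(rep(1, 4800), 24000)$ok)   # clipping
})

test_that("seeded discovery is reproducible and the optimizer never loses reward", {
  cfg <- fastConfig(seed = 7L)
  out1 <- discoverPatterns(cfg, 2)
  out2 <- discoverPatterns(cfg, 2)
  expect_identical(out1$log, out2$log)
  expect_true(all(out1$log$finalReward >= out1$log$initialReward - 1e-9))
  expect_identical(discoverPatterns(cfg, 0)$patterns, list())
})

test_that("vowel-preset discoveries are voiced with low-band dominant energy", {
  cfg <- fastConfig(seed = 3L)
  out <- discoverPatterns(cfg, 2)
  for (p in out$patterns) {
    res <- synthesizePattern(p, cfg@synth, cfg@dynamics)
    bp <- vocalearn:::bandPowers(waveform(res), 24000, 2500)
    expect_gt(bp[["low"]], bp[["high"]])
    f0 <- estimateF0(waveform(res), 24000)
    expect_gt(sum(f0 > 0), 3)
  }
})

test_that("k = n clustering gives singletons and k > n errors", {
  ps <- lapply(1:4, function(i)
    staticPattern(c(runif(7, -1, 1), 0, 0, -1), id = paste0("p", i)))
  set.seed(1)
  cl <- clusterPatterns(ps, "motor_kmeans", k = 4)
  expect_identical(cl$assignments, 1:4)
  expect_error(clusterPatterns(ps, "motor_kmeans", k = 5), "exceeds")
})

test_that("motor K-means separates two articulation blobs", {
  set.seed(33)
  blobA <- lapply(1:4, function(i)
    staticPattern(c(0.8, 0.8, 0.8, runif(4, -0.05, 0.05), 0, 0, -1) *
                    c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1), id = paste0("a", i)))
  blobB <- lapply(1:4, function(i)
    staticPattern(c(-0.8, -0.8, -0.8, runif(4, -0.05, 0.05), 0, 0, -1),
                  id = paste0("b", i)))
  cl <- clusterPatterns(c(blobA, blobB), "motor_kmeans", k = 2, seed = 5)
  expect_length(unique(cl$assignments[1:4]), 1)
  expect_length(unique(cl$assignments[5:8]), 1)
  expect_false(cl$assignments[1] == cl$assignments[5])
  cl2 <- clusterPatterns(c(blobA, blobB), "motor_kmeans", k = 2, seed = 5)
  expect_identical(cl$assignments, cl2$assignments)
})

test_that("acoustic DTW clustering separates a vowel from a fricative", {
  cfg <- fastConfig()
  vowels <- lapply(1:2, function(i)
    staticPattern(c(0.2 + 0.05 * i, 0, 0, 0, 0.3, 0, 0, 0, 0, -1),
                  duration = 0.2, id = paste0("v", i)))
  frics <- lapply(1:2, function(i)
    staticPattern(c(0, 0, 0, 1, 0.05 * i, 0, 0, 0, 0, -1),
                  duration = 0.2, category = "fricative", voiced = FALSE,
                  id = paste0("f", i)))
  cl <- clusterPatterns(c(vowels, frics), "acoustic_dtw", k = 2, seed = 2,
                        config = cfg)
  expect_false(cl$assignments[1] == cl$assignments[3])
  expect_identical(cl$assignments[1], cl$assignments[2])
  expect_identical(cl$assignments[3], cl$assignments[4])
})

test_that("composite generation enumerates the stated template families", {
  v1 <- staticPattern(rep(0.1, 10), id = "v1")
  v2 <- staticPattern(rep(-0.1, 10), id = "v2")
  cv <- staticPattern(c(rep(0, 4), -1, rep(0, 5)), category = "plosive",
                      voiced = TRUE, id = "b")
  out <- suppressWarnings(generateComposites(list(v1, v2, cv)))
  ids <- vapply(out, patternId, character(1))
  # CvV: plosive+vowel in order, one per vowel
  expect_length(grep("^b\\+v", ids), 2)
  # VCv mirrored
  expect_length(grep("^v[12]\\+b$", ids), 2)
  # VV ordered pairs excluding self-pairs
  expect_setequal(grep("^v[12]\\+v[12]$", ids, value = TRUE),
                  c("v1+v2", "v2+v1"))
  expect_true(all(vapply(out, function(p) length(subPatterns(p)) <= 3,
                         logical(1))))

  # missing fricative class skips its families with a warning
  ws <- capture_warnings(generateComposites(list(v1, v2, cv)))
  expect_true(any(grepl("Fv", ws)))
  expect_false(any(grepl("\\+f", vapply(out, patternId, character(1)))))
})
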