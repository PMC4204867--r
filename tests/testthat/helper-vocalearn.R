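# Shared fixtures: tiny signals, toy patterns, and independent oracles.

toneWave <- function(freq, duration, sr = 24000, amp = 0.5) {
  amp * sin(2 * pi * freq * seq_len(round(duration * sr)) / sr)
}

sawtoothWave <- function(freq, duration, sr = 24000, amp = 0.5) {
  t <- seq_len(round(duration * sr)) / sr
  amp * (2 * ((t * freq) %% 1) - 1)
}

# single-target static pattern helper
staticPattern <- function(targets, duration = 0.25, category = "vowel",
                          voiced = TRUE, nasalPort = FALSE, id = "test") {
  motorPattern(subPattern(targets, 0, duration), category = category,
               voiced = voiced, nasalPortOpen = nasalPort, id = id)
}

neutralVowelPattern <- function(duration = 0.25, id = "nv")
  staticPattern(rep(0, 10), duration, id = id)

# Brute-force DTW oracle: enumerate every monotone alignment path from
# (1,1) to (n,m) with steps (1,0), (0,1), (1,1); cost = sum of Euclidean
# frame distances weighted 2 for the start cell and diagonal arrivals, 1
# otherwise; result = min path cost / (n + m). Shares no code with the DP.
bruteForceDtw <- function(a, b) {
  n <- ncol(a); m <- ncol(b)
  d <- function(i, j) sqrt(sum((a[, i] - b[, j])^2))
  best <- Inf
  walk <- function(i, j, acc) {
    if (i == n && j == m) {
      best <<- min(best, acc)
      return(invisible())
    }
    if (i < n) walk(i + 1, j, acc + d(i + 1, j))
    if (j < m) walk(i, j + 1, acc + d(i, j + 1))
    if (i < n && j < m) walk(i + 1, j + 1, acc + 2 * d(i + 1, j + 1))
  }
  walk(1, 1, 2 * d(1, 1))
  best / (n + m)
}

# spectral envelope peak (pre-emphasized cepstral smoothing); used to
# compare formant positions across tract scalings
spectralEnvelopePeak <- function(w, sr = 24000, lo = 300, hi = 5000,
                                 fcut = 800) {
  w <- diff(w)
  n <- length(w)
  ls <- log(Mod(stats::fft(w))^2 + 1e-12)
  cep <- Re(stats::fft(ls, inverse = TRUE)) / n
  q <- round(sr / fcut)
  cep[(q + 2):(n - q)] <- 0
  env <- Re(stats::fft(cep))
  half <- seq_len(n %/% 2)
  fr <- (half - 1) * sr / n
  sel <- fr >= lo & fr <= hi
  fr[sel][which.max(env[half][sel])]
}

# small caregiver inventory shared by interaction/imitation tests
tinyCaregiverTemplates <- function(nPerCategory = 2L, seed = 11L) {
  generateCaregiverTemplates(caregiverLanguageSpec(), nPerCategory, seed)
}

# association memory whose responses are caregiver tokens attached to
# dummy single-target motor patterns
memoryFromTemplates <- function(templates, nChannels = 32L) {
  mem <- associationMemory()
  for (i in seq_along(templates$tokens)) {
    tok <- templates$tokens[[i]]
    pat <- staticPattern(c(stats::runif(7, -0.3, 0.3), 0, 0, -1),
                         id = sprintf("resp_%02d", i))
    mem <- addAssociation(mem, pat, tok$waveform, templates$sampleRate,
                          label = tok$label, nChannels = nChannels)
  }
  mem
}
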