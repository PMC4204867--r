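# Synthetic caregiver-language fixtures: formant-synthesized vowel and CV
# tokens, and synthetic transcription datasets with controllable agreement.

#' Define a synthetic caregiver language
#'
#' The default inventory holds five point-ish vowels (formant targets in
#' the adult female range) and three consonant place classes distinguished
#' by burst spectral centroid, giving eight categories in all.
#'
#' @param vowelPrototypes named list: label -> c(F1, F2, F3) Hz.
#' @param consonantClasses named list: label -> list(centroid = Hz,
#'   voiced = logical).
#' @param f0Range caregiver F0 range, Hz.
#' @param sampleRate Hz of generated audio.
#' @return a [CaregiverLanguageSpec-class].
#' @examples
#' caregiverLanguageSpec()
#' @export
caregiverLanguageSpec <- function(
    vowelPrototypes = list(
      a = c(850, 1220, 2800), e = c(500, 2100, 2900),
      i = c(310, 2500, 3100), o = c(450, 850, 2700),
      u = c(350, 700, 2600)),
    consonantClasses = list(
      b = list(centroid = 600, voiced = TRUE),
      d = list(centroid = 2500, voiced = TRUE),
      g = list(centroid = 1500, voiced = TRUE)),
    f0Range = c(180, 260), sampleRate = 24000) {
  new("CaregiverLanguageSpec", vowelPrototypes = vowelPrototypes,
      consonantClasses = consonantClasses, f0Range = f0Range,
      sampleRate = sampleRate)
}

#' Formant-synthesize a vowel token
#'
#' Source-filter synthesis: the LF-type glottal source filtered through a
#' cascade of three second-order resonators, with onset/offset amplitude
#' ramps.
#'
#' @param formants c(F1, F2, F3), Hz.
#' @param f0 start fundamental frequency, Hz.
#' @param f0End end F0 (default = `f0`, i.e. flat).
#' @param duration s.
#' @param sampleRate Hz.
#' @param bandwidths resonator bandwidths, Hz.
#' @param gain output peak normalization.
#' @return numeric waveform.
#' @export
formantSynthesize <- function(formants, f0, f0End = f0, duration = 0.3,
                              sampleRate = 24000,
                              bandwidths = c(80, 100, 140), gain = 0.3) {
  n <- round(duration * sampleRate)
  f0Track <- seq(f0, f0End, length.out = n)
  ramp <- pmin(1, seq_len(n) / (0.02 * sampleRate),
               rev(seq_len(n)) / (0.02 * sampleRate))
  cfg <- synthConfig(sampleRate = sampleRate)
  src <- glottalSource(f0Track, ramp, cfg)
  y <- src
  for (k in seq_along(formants)) y <- resonate(y, formants[k], bandwidths[k],
                                               sampleRate)
  y <- y - mean(y)
  y / max(abs(y)) * gain
}

# Two-pole resonator section.
resonate <- function(x, freq, bw, sampleRate) {
  r <- exp(-pi * bw / sampleRate)
  th <- 2 * pi * freq / sampleRate
  a <- c(2 * r * cos(th), -r^2)
  g <- 1 - 2 * r * cos(th) + r^2      # unit gain at DC-ish normalization
  as.numeric(stats::filter(x * g, a, method = "recursive"))
}

# A CV consonant token: a shaped noise burst at the class centroid
# (voiced classes add a low murmur) followed by the /a/-like vowel.
consonantToken <- function(class, vowelFormants, f0, sampleRate,
                           burstDur = 0.10, vowelDur = 0.14) {
  nb <- round(burstDur * sampleRate)
  burst <- localNoise(nb, seed = 77L)    # deterministic; shaped below
  burst <- resonate(burst, class$centroid, 400, sampleRate)
  burst <- burst / max(abs(burst)) * 0.4 *
    exp(-seq_len(nb) / (0.45 * nb))
  if (isTRUE(class$voiced)) {
    cfg <- synthConfig(sampleRate = sampleRate)
    murmur <- glottalSource(rep(f0, nb), rep(0.2, nb), cfg)
    burst <- burst + resonate(murmur, 250, 100, sampleRate) * 0.1
  }
  vowel <- formantSynthesize(vowelFormants, f0, f0 * 0.9, vowelDur,
                             sampleRate)
  c(burst, vowel)
}

#' Generate a labelled caregiver token inventory
#'
#' Formant-synthesizes `nPerCategory` tokens per vowel and consonant
#' category with per-token jitter of formants (+/- 3%) and F0 (drawn from
#' the caregiver range). Deterministic given the seed. The first token of
#' each category carries no jitter and serves as the category prototype.
#'
#' @param spec a [CaregiverLanguageSpec-class].
#' @param nPerCategory tokens per category.
#' @param seed RNG seed.
#' @return list(tokens, sampleRate, labels): `tokens` is a list of
#'   list(waveform, label, category) entries.
#' @export
generateCaregiverTemplates <- function(spec, nPerCategory = 3L, seed = 1L) {
  set.seed(seed)
  sr <- spec@sampleRate
  tokens <- list()
  for (lab in names(spec@vowelPrototypes)) {
    ff <- spec@vowelPrototypes[[lab]]
    if (any(diff(ff) <= 0)) stop("invalid formants for vowel ", lab)
    for (i in seq_len(nPerCategory)) {
      jit <- if (i == 1L) rep(1, 3) else 1 + stats::runif(3, -0.03, 0.03)
      f0 <- stats::runif(1, spec@f0Range[1], spec@f0Range[2])
      tokens[[length(tokens) + 1L]] <- list(
        waveform = formantSynthesize(ff * jit, f0, f0 * 0.92,
                                     sampleRate = sr),
        label = lab, category = "vowel")
    }
  }
  for (lab in names(spec@consonantClasses)) {
    cl <- spec@consonantClasses[[lab]]
    for (i in seq_len(nPerCategory)) {
      jitC <- if (i == 1L) 1 else 1 + stats::runif(1, -0.05, 0.05)
      f0 <- stats::runif(1, spec@f0Range[1], spec@f0Range[2])
      cl2 <- list(centroid = cl$centroid * jitC, voiced = cl$voiced)
      tokens[[length(tokens) + 1L]] <- list(
        waveform = consonantToken(cl2, spec@vowelPrototypes[[1L]], f0, sr),
        label = lab, category = "consonant")
    }
  }
  list(tokens = tokens, sampleRate = sr,
       labels = vapply(tokens, `[[`, character(1), "label"))
}

#' Generate a pair of synthetic transcription datasets
#'
#' Produces two labelled datasets over the same tokens in which a fraction
#' of about `agreement` of the tokens carry the same archiphoneme label in
#' both (each token agrees independently with probability `agreement`;
#' disagreeing tokens get a different label drawn uniformly). Used to
#' exercise the comparison and z-test machinery with known ground truth.
#'
#' @param nTokens number of tokens.
#' @param agreement target same-label probability in \[0, 1\].
#' @param table an [ArchiphonemeTable-class] supplying the label
#'   inventory.
#' @param seed RNG seed.
#' @param slot "V1" (vowel labels) or "C1" (consonant labels).
#' @return list(a, b): two data.frames with tokenId and the slot column.
#' @export
generateTranscriptionDataset <- function(nTokens, agreement, table,
                                         seed = 1L, slot = c("V1", "C1")) {
  slot <- match.arg(slot)
  if (agreement < 0 || agreement > 1)
    stop("agreement must lie in [0, 1]")
  set.seed(seed)
  labels <- unique(unname(table@mapping))
  vowels <- intersect(labels, vowelArchiphonemes())
  pool <- if (slot == "V1") vowels else setdiff(labels, vowels)
  ids <- sprintf("tok%04d", seq_len(nTokens))
  la <- sample(pool, nTokens, replace = TRUE)
  agree <- stats::runif(nTokens) < agreement
  lb <- la
  for (i in which(!agree)) lb[i] <- sample(setdiff(pool, la[i]), 1L)
  a <- data.frame(tokenId = ids, val = la)
  b <- data.frame(tokenId = ids, val = lb)
  names(a)[2] <- names(b)[2] <- slot
  list(a = a, b = b)
}
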