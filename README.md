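# vocalearn

An R package modeling how an infant can learn to pronounce first words
**without ever matching his own acoustics to adult speech**. The agent
discovers sound-producing motor patterns for an articulatory synthesizer
by reward-driven babbling; a caregiver selectively responds to the sounds
she can interpret, almost always *reformulating* them into well-formed
tokens of her language; the agent keeps the patterns that were responded
to and associates each with the response it provoked. Word learning is
then serial imitation: segment the caregiver's word, recognize each
syllable against the *stored caregiver responses* (caregiver speech is
only ever compared with caregiver speech, so there is no
speaker-normalization problem), and replay the associated motor patterns
with the caregiver's intonation and duration transferred. A fully
synthetic, formant-synthesized caregiver closes the loop, so everything
runs from a seed with no human subjects and no external data.

For whom: researchers in speech development, developmental robotics and
intrinsically motivated learning who want a reproducible, inspectable
implementation of the caregiver-reformulation account of pronunciation
learning, plus the accompanying transcription statistics.

## The model in brief

* **Production** — a Maeda-style articulatory synthesizer: ten controls
  (jaw, tongue dorsum position/shape, apex, lip aperture/protrusion,
  larynx height, glottal area, F0, nasality) in [−1, 1] map through a
  linear-component table to a 29-section area function, rendered by a
  Kelly–Lochbaum reflection line at 24 kHz with an LF-type voice source,
  constriction noise, closure (touch) feedback and a nasal branch. Tract
  dimensions are scaled by 0.8 and the F0 mid-range is 400 Hz to
  approximate an infant.
* **Motor patterns** — gestural scores of up to three 31-element
  sub-patterns (10 targets, 10 start times, 10 holds, 1 speed); articulators
  follow the critically damped step response
  `x(t) = x₁ + (x₀ − x₁)(1 + ωt)e^(−ωt)`, with ω raised to 160 s⁻¹ just
  after a closure release.
* **Discovery** — candidates drawn uniformly over the articulatory
  space, improved for 3 bounded quasi-Newton iterations on the reward
  `R = w·salience + w·diversity − w·effort − w·sensitivity`, filtered
  for artifacts, clustered (K-means on motor vectors; DTW K-medoids on
  sounds) under caps of 15 vowels / 15 plosives / 10 fricatives, and
  expanded into CV/VC/VV composites.
* **Perception** — gammatone filterbank (ERB-spaced), autocorrelation
  F0, short-term-power segmentation and a path-normalized DTW distance.
* **Word learning** — two-pass DTW recognition (100 cluster-center
  templates, then all members of the best 5 clusters), intonation
  transfer via the linear (−0.9, 0.9) ↔ 100–300 / 150–400 Hz map,
  durations clamped to 250–600 ms, up to 4 attempts per prompt.
* **Analysis** — SAMPA transcription coding (CVC/CVV frames, `#`
  silent, `xxx` untranscribable), archiphoneme consolidation tables for
  English/German/French, pairwise same/different label counting, the
  pooled two-proportion z-test
  `z = (p̂₁ − p̂₂)/√(p̂(1−p̂)(1/n₁+1/n₂))` with two-sided decisions at
  α = 0.05/0.01/0.001, and Wald 95 % confidence intervals.

## Worked example

```r
library(vocalearn)

## a 500 ms neutral vowel from the articulatory synthesizer
cfg <- synthConfig()
res <- synthesizeFrames(matrix(0, 100, 10), cfg)
res
f0 <- estimateF0(waveform(res), sampleRate(res))
median(f0[f0 > 0])

## a caregiver inventory, an association memory, and recognition
set.seed(1)
spec  <- caregiverLanguageSpec()                  # 5 vowels + 3 consonants
train <- generateCaregiverTemplates(spec, nPerCategory = 7, seed = 201)
mem <- associationMemory()
for (i in seq_along(train$tokens)) {
  tok <- train$tokens[[i]]
  pat <- motorPattern(subPattern(c(runif(7, -0.3, 0.3), 0, 0, -1), 0, 0.25),
                      id = sprintf("resp_%02d", i))
  mem <- addAssociation(mem, pat, tok$waveform, train$sampleRate,
                        label = tok$label)
}
idx  <- buildTemplateIndex(mem, seed = 1)
held <- generateCaregiverTemplates(spec, nPerCategory = 1, seed = 909)
pred <- vapply(held$tokens, function(t)
  recognizeTwoPass(t$waveform, 24000, mem, idx)$label, character(1))

## two-syllable imitation and the transcription statistics
imit <- imitateWord(c(held$tokens[[1]]$waveform, numeric(7200),
                      held$tokens[[3]]$waveform), 24000, mem, idx, "female")
twoProportionZTest(40, 100, 60, 100)
proportionCI(50, 100)
```

This prints:

```
SynthResult: 500 ms at 24000 Hz, 100 frames, 0 with tract contact
median F0 (Hz): 400
AssociationMemory: 56 association(s), 0 deselected
  labels: a=7, b=7, d=7, e=7, g=7, i=7, o=7, u=7
  truth pred
1     a    a
2     e    o
3     i    u
4     o    o
5     u    u
6     b    b
7     d    d
8     g    g
held-out accuracy: 0.75
imitated word, recognized as: a u
output duration (s): 0.765
Two-proportion z-test: 40/100 vs 60/100, z = -2.82843, significant at: 0.05, 0.01
lower upper
0.402 0.598
```

The neutral posture synthesizes a voiced vowel whose measured F0 sits at
the 400 Hz infant mid-range. The memory holds 56 labelled caregiver
responses; six of eight held-out jittered tokens are recognized
correctly (the e→o and i→u confusions are between spectrally adjacent
vowels). The two-syllable word is segmented, recognized and re-rendered
through the agent's own vocal tract. The z-test worked example rejects
equality of 40 % vs 60 % at the 0.05 and 0.01 levels but not at 0.001,
and the 95 % interval for 50/100 is (0.402, 0.598).

A thin command-line front-end over the same functions ships in
`inst/cli/vocalearn.R` with `discover`, `interact`, `teach`, `analyze`
and `fixtures` subcommands.

## Scope

Human-subject results (response rates, reformulation percentages,
words-learned counts, Z statistics over the human transcription data)
depend on unpublished counts and human judgment and are deliberately out
of scope; the synthetic caregiver reproduces the structure of the
interaction, not its human content. See the methods vignette
(`vignettes/vocal-learning-model.Rmd`) for the model, parameter
defaults, design decisions and limitations.
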