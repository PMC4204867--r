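---
title: "A caregiver-guided model of learning to pronounce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A caregiver-guided model of learning to pronounce}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Most accounts of how infants learn to pronounce assume the child matches
his own acoustics against adult speech. This package implements the
alternative: the child never judges acoustic similarity himself. He
discovers motor patterns that make sounds, a caregiver responds to the
ones she can interpret — almost always by *reformulating* them into
well-formed sounds of her language — and the child associates each
retained motor pattern with the response it provoked. The judgment of
equivalence is the caregiver's. Once an inventory of motor-pattern ↔
response associations exists, word learning is serial imitation: segment
the caregiver's word into syllable-sized chunks, recognize each chunk
against the stored *caregiver* responses (so there is no speaker
normalization problem — caregiver speech is only ever compared with
caregiver speech), and replay the associated motor patterns.

The package runs the whole loop with a fully synthetic caregiver, so
every experiment is reproducible from a seed with no human, no audio
corpus and no network.

## Production: articulatory synthesis

`synthConfig()` / `synthesizeFrames()` implement a Maeda-style
articulatory synthesizer. Ten control parameters, all dimensionless in
[−1, 1]: p1 jaw, p2 tongue dorsum position, p3 dorsum shape, p4 tongue
apex, p5 lip aperture, p6 lip protrusion, p7 larynx height, p8 glottal
area, p9 fundamental frequency, p10 nasality.

* **Area model.** The seven articulatory parameters map through a
  linear-component coefficient table (one row per tract section, shipped
  as `inst/extdata/articulatory_model.csv` and swappable via
  `synthConfig(coefficientsPath=)`) to a 29-section area function,
  clamped at zero. A zero area *is* the touch (closure) signal — the
  proprioceptive feedback used by the plosive reward and the trajectory
  rate switch. The published coefficient tables of the original
  adult-female model were not available as open data, so the shipped
  table is a constructed set with the standard regional layout (jaw opens
  the oral cavity; dorsum position trades palatal against pharyngeal
  area; dorsum shape constricts the velar region; apex the alveolar
  region; lip aperture closes the lip sections at p5 ≤ −0.9 so that a
  critically damped approach can actually reach closure). It is
  documented as synthetic and every coefficient is inspectable.
* **Scaling.** Tract dimensions are scaled by 0.8 to approximate an
  infant tract, and the F0 mid-range sits at 400 Hz; the output rate is
  24 kHz. Halving the tract scale halves the acoustic length and shifts
  all resonances up (a tested invariant).
* **Acoustics.** A Kelly–Lochbaum reflection line (one section per
  sample of travel, reflection coefficients interpolated per sample,
  compiled in C++) filters the excitation. Voicing is a simplified
  LF-type pulse — raised-cosine opening, exponential return — whose only
  external controls are F0 (`f0 = 400·(1 + 0.5·p9)` Hz) and amplitude
  (`sin(π(p8+1)/2)`: silent at a sealed glottis, maximal at p8 = 0,
  silent again wide open). Turbulence noise is injected at the most
  constricted section when its area is below 0.3 cm² and a flow proxy
  (glottal opening over constriction area) exceeds the configurable
  Reynolds-like threshold; a short burst is injected at closure release.
  A one-way nasal branch diverts part of the forward wave at the velum
  in proportion to the port area (p10 maps affinely to [0, 0.8] cm²), so
  closed-lip configurations with an open port still radiate — nasals.
* **Determinism.** The turbulence noise comes from a config-seeded
  stream that saves and restores the session RNG, so identical frames
  and configuration give bit-identical waveforms.

Frame period is 5 ms (a standard articulatory control rate; the source
description leaves it open). The number of tube sections, the LF shape
parameters and the noise thresholds are likewise config-exposed defaults
rather than published values.

## Motor patterns and dynamics

A motor pattern (`motorPattern()`) is one to three sub-patterns; each
sub-pattern is a 10-element target vector, 10 start times, 10 hold
durations and one speed scaling — 31 scalars
(`serializeSubPattern()`). Articulators move toward their targets along
the critically damped second-order step response
`x(t) = x₁ + (x₀ − x₁)(1 + ωt)e^(−ωt)`, which approaches without
overshoot. ω defaults to 40 s⁻¹ — a typical articulation-speed constant;
the source text masks the printed default, so 40 is this package's
documented, non-canonical choice — and switches to the published
160 s⁻¹ for 50 ms after a detected closure release (touch present at one
frame, absent at the next), which sharpens plosive releases. At a rate
switch the trajectory is re-anchored at its current value: continuity is
kept, the (zero-velocity) closed form restarts, and no overshoot can be
introduced. Parameters hold their previous value until their target
activates, starting from the neutral resting state (all zeros).

## Perception

* `gammatoneAnalyze()`: 4th-order gammatone filterbank, ERB-spaced
  centers from 80 Hz to 90 % of Nyquist (64 channels by default, 32 in
  the discovery loop for speed), 100 frames/s, power-law compression
  with exponent 0.2 on frame power. The strong root compression keeps
  the weaker upper-formant channels discriminative in DTW comparisons;
  because it is a power law, scaling the waveform by *a* scales every
  energy by exactly `a^0.4` (a tested homogeneity invariant — log
  compression would not satisfy it).
* `estimateF0()`: frame-wise normalized autocorrelation directly on the
  waveform, peak picked in the [fmin, fmax] lag range with parabolic
  refinement; a frame is unvoiced (0) when the peak falls below 0.5 or
  the frame is essentially silent.
* `dtwDistance()`: dynamic programming over Euclidean frame distances
  with the symmetric step set (1,0), (0,1), (1,1), diagonal weight 2,
  normalized by the sum of the two lengths. This dialect is fixed so
  results are reproducible; the test suite holds it to an exhaustive
  enumeration over all monotone warping paths on small inputs. The
  one-frame case reduces to the frame metric itself.
* `detectActivity()`: short-term power against a noise floor, gaps under
  `minGap` merged, segments under `minLen` dropped. When no floor is
  given it is estimated as 4× the median power of the leading 200 ms
  (assumed silent); the word-segmentation wrapper `segmentWord()`
  instead uses a small absolute floor suited to normalized digital
  audio, plus a 30 ms padding margin on each kept segment so low-energy
  onsets and offsets are not clipped (the padding is what makes
  self-recognition of a stored token exact).

## Discovery by reward

`evaluateReward()` scores a candidate pattern as
`R = w_sal·salience + w_div·diversity − w_eff·effort − w_sens·sensitivity`:

* **Salience** — weighted mean low-band power, high-band power (2.5 kHz
  boundary) and touch. The attention preset decides the emphasis: low
  band for vowels, high band for fricatives, touch for plosives.
* **Diversity** — weighted minimum distances from the candidate to all
  previously kept patterns in acoustic (DTW on gammatone
  representations), tactile (Euclidean on length-20 resampled touch
  profiles) and motor (Euclidean on zero-padded 93-element serialized
  vectors) space; 1.0 against an empty memory so the first pattern is
  maximally novel.
* **Effort** — the time-integral of weighted squared articulator speeds
  plus the summed phonation contribution of p8. The squared-speed form
  is deliberate: for a monotone critically damped transition the sum of
  absolute frame-to-frame speeds telescopes to (excursion ÷ frame
  period) regardless of ω, which would make effort blind to movement
  speed; the quadratic integral grows with ω as an effort term must.
  Without the voicing penalty the optimizer always drives voicing to
  maximum, since that maximizes salience.
* **Sensitivity** — perturb each of p1..p5 of the (first) target by +0.1
  (5 % of the range, clipped to +1), re-synthesize the static posture,
  and take the root-sum-of-squares of the five auditory distances.
  Sensitive articulations only produce their sound under very accurate
  articulation and are penalized. Perturbed patterns are evaluated and
  discarded, never stored.

The four term weights are unpublished in the source account; the presets
here are this package's own, tuned only so that each attention preset
discovers its category, and are config-exposed and labelled
non-canonical.

`discoverPatterns()` draws each candidate's seven articulatory targets
uniformly from [−1, 1], fixes voicing and the nasal port per preset
(voiced/voiceless and oral/nasal variants are enumerated explicitly, not
optimized), and runs a bounded quasi-Newton ascent (L-BFGS-B with
forward-difference gradients) for exactly 3 outer iterations. Kept
candidates must pass the automated artifact filter, which replaces the
original by-hand removal of implausible sounds: clipping, > 50 %
near-silent frames (waived for the touch-attended plosive preset, whose
target articulations are silent closures), or a spectral-flux spike
above 0.15 between energetic frames (normalized-spectrum flux lies in
[0, 2]; sustained vowels, fricatives and legitimate plosive bursts
measure below ~0.07 while an additive click measures ~0.26, so the
threshold separates the two regimes with margin on both sides).
`clusterPatterns()` then caps the inventory: Lloyd's K-means on
serialized motor vectors for plosives, K-medoids (PAM) under DTW for
vocalic and fricative sounds, with caps of 15 vowels, 15 plosives and 10
fricatives. `generateComposites()` expands the singles into the CV
(CvV, CuV, FvV, FuV, NV), VC and VV families; VV pairs are ordered and
exclude self-pairs, since a doubled identical vowel is not a
diphthong-like token. A composite inherits the union of its parts'
voicing/nasality flags (a single port flag per pattern — NV composites
are rendered with a nasalized vowel, an accepted simplification).

## Interaction and association

`runResponseSession()` presents each inventory pattern, listens for 3 s,
and detects a response as any region whose short-term power exceeds the
background level (default absolute floor 10⁻⁶ mean-square). A response
is stored — audio, gammatone representation, optional label — as that
pattern's association; silence deselects the pattern; a caregiver error
skips it. One association per pattern, latest wins. The simulated
caregiver (`simulatedCaregiver()`) classifies what she hears against her
labelled prototype inventory by DTW and, within an acceptance radius and
a response probability, answers with her *prototype token* — a
reformulation, not an acoustic copy.

## Word learning

`imitateWord()` segments the word (the caregiver speaks with pauses),
recognizes each segment in two passes — pass 1 against up to 100 cluster
exemplars of all stored responses, pass 2 against every member of the 5
best clusters — and replays the associated motor patterns. Intonation
transfer fits a straight line to the segment's F0 track by least
squares, maps the endpoint frequencies through the linear
(−0.9, 0.9) ↔ 100–300 Hz (male) / 150–400 Hz (female) scaling, and
writes the resulting p9 values linearly across the pattern's frames
(endpoint targets alone cannot express a rising contour within a
single-target pattern, so the whole p9 trajectory is overwritten);
durations are clamped to [250, 600] ms and the pattern's times rescaled
proportionally. `runWordSession()` allows up to 4 attempts per spoken
prompt, walking down the next-ranked pass-2 candidates, before the
caregiver gives up. The pass-1 index is cached per memory snapshot
(`buildTemplateIndex()`), not re-clustered per session.

## Transcription analysis

The analysis layer is independent of the audio pipeline. Raw codes
follow the published conventions: `#` silent, `xxx` untranscribable,
otherwise comma-separated SAMPA phonemes in a CVC/CVV frame, with codes
beyond three elements truncated to the first three. The shipped
archiphoneme tables for English, German and French (
`inst/extdata/archiphonemes.csv`) expand every composite row of the
published consolidation into explicit phoneme → archiphoneme pairs so
lookup is total and testable; `compareDatasets()` counts same-label and
unordered different-label pairs per token, `sumGroupComparisons()` adds
them across session pairs, and `twoProportionZTest()` /
`proportionCI()` implement the pooled two-proportion z statistic with
two-sided decisions at α = 0.05, 0.01, 0.001 and the Wald 95 % interval.
No multiple-testing correction is applied, matching the raw-Z reporting
convention of the source analysis.

## What the synthetic caregiver does and does not emulate

`caregiverLanguageSpec()` defines 5 vowel prototypes (formant triples in
the adult-female range) and 3 consonant classes (burst spectral
centroids), spoken as formant-synthesized tokens with ±3 % formant and
F0 jitter per draw, F0 in 180–260 Hz. This emulates the *structure* of
caregiver behavior — selective response, reformulation into a fixed
native inventory, label consistency — not its content: real caregivers
vary response criteria between individuals, produce coarticulated and
prosodically rich speech, and interpret sounds against a full phonology.
Passing tests therefore show that the mechanisms (selection,
association, two-pass recognition, intonation transfer) work end-to-end
under controlled conditions; they do not predict human response rates,
reformulation percentages or words-learned counts, which depend on human
judgment and are out of scope.

## Numerical choices and problem sizes

Degenerate inputs are defined, not special-cased: empty memory gives the
diversity ceiling; a segment with fewer than two voiced frames gets a
flagged flat contour at the caregiver mapping midpoint; k = n clustering
returns singletons; DTW of identical inputs is exactly 0. Ties in
recognition resolve by stable ordering of stored ids.

The tests and the acceptance script run real synthesis throughout, so
problem sizes are chosen for a single CPU: 100 random target pairs for
the trajectory–ODE comparison, all 25 length combinations up to 5 frames
for the DTW enumeration, 100–200 random patterns for reward
decomposition exactness, a 56-token (8-category × 7) caregiver memory
with 24 held-out tokens for recognition, and 4-candidate discovery runs
for cap compliance and reproducibility. These sizes are the package's
stated test conditions, not limits of the method.

## Known limitations

* The articulatory coefficient table is constructed, not fitted to
  measurements; formant positions are plausible rather than calibrated.
* The nasal branch is one-way (no reflections back into the oral tract),
  so nasal antiresonances are approximated crudely.
* Composites share one voicing/nasality flag across their gestures.
* The caregiver acceptance radius defaults to infinite (respond to
  everything in range of the probability), which is the permissive end
  of observed caregiver behavior.
* Discovery cost is dominated by re-synthesis inside the reward; the
  iteration budget (3) follows the source procedure, but candidate
  counts here are far below the original 927-pattern inventory, which
  also involved hand curation that this package deliberately replaces
  with the automated artifact filter.
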