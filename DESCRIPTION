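Package: vocalearn
Title: Caregiver-Guided Vocal Learning in a Simulated Infant
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An articulatory model of how an infant can learn to pronounce
    first words without matching his own acoustics to adult speech. The model
    discovers sound-producing motor patterns for a Maeda-style articulatory
    synthesizer by reward-driven exploration (salience, diversity, effort and
    sensitivity terms), retains the patterns a caregiver responds to and
    associates each retained pattern with the caregiver's spoken reformulation,
    then imitates whole words by segmenting them, recognizing each syllable
    against the stored responses with a two-pass dynamic time warping
    recognizer, and replaying the associated motor patterns with the
    caregiver's intonation and duration transferred. A fully synthetic
    (formant-synthesized) caregiver closes the loop without human subjects,
    and an analysis layer provides SAMPA transcription coding, archiphoneme
    consolidation, pairwise label comparisons and two-proportion z-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    cluster,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
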