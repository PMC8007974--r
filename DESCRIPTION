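Package: seglab
Title: Simulating Prosodic-Cue Experiments on Statistical Word Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for building and analysing artificial-language-learning
    experiments on auditory statistical word segmentation. Generates
    constrained consonant-vowel pseudo-languages, concatenates them into
    continuous speech streams with balanced syllable transitional
    probabilities, overlays prosodic boundary cues (pauses, final lengthening
    or shortening, pitch rise or fall) on word-final syllables, renders
    streams to WAV with a parametric syllable synthesiser, enumerates
    word/part-word test items, simulates listener judgements under
    configurable cue-convergence and cue-conflict response models, and runs
    the signal-detection (d-prime) analysis with the 1/(2N) correction,
    group confidence intervals, and proportion-correct summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
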