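# seglab

Adults (and infants) can segment words out of continuous speech using
nothing but syllable co-occurrence statistics: in a stream built from
trisyllabic nonsense words, the transitional probability (TP)
`P(syllable B | syllable A)` is 1.0 inside words and about 0.33 across word
boundaries, and listeners exploit that drop to find the boundaries. Real
speech, however, also carries prosodic boundary cues — pauses, final
lengthening, pitch movement — which can converge with the statistics
(marking the same boundary) or conflict with them.

`seglab` is an end-to-end simulation and analysis toolkit for this class of
artificial-language-learning experiment, aimed at psycholinguists designing
or power-analysing segmentation studies. It covers:

* **Pseudo-language generation** — four-word CV languages under explicit
  distributional constraints (syllable inventories, unique syllables, vowel
  balance), singly or as mutually constrained sets of four, plus the five
  published languages used by the original designs (`builtin_languages()`).
* **Speech streams** — pseudo-random word orders with no immediate
  repetitions and maximally balanced word-to-word transitions (all ordered
  pair counts within 1 of each other), giving within-word TP = 1.0 and
  between-word TP ≈ 1/3 by construction; `transition_stats()` verifies this
  empirically on any stream.
* **Prosodic conditions** — a baseline (all syllables 500 ms, 210 Hz) and
  five single-cue manipulations of the word-final syllable: a 250 ms pause
  after each word, lengthening to 750 ms, shortening to 250 ms, pitch up to
  260 Hz, or pitch down to 160 Hz; plus the 15-syllable amplitude fade at
  the stream edges.
* **Audio rendering** — an optional parametric synthesiser (noise-burst
  onset + harmonic-complex vowel) that turns a symbolic stream into a
  16-bit PCM WAV with a sample-exact segment manifest.
* **Test items** — exhaustive enumeration of both part-word classes
  (PW1-2: final syllable + following initial/medial; PW2-1: medial/final +
  following initial; 12 each per language) and test-set selection, either
  the fixed published pilot list or random derangement-based sets in which
  every word contributes each of its parts exactly once per class.
* **Simulated listeners** — binary word/part-word judgements drawn from a
  logistic response model (per-cell endorsement probabilities plus a
  normal participant offset), for between-subjects (202 × 1 × 12 trials),
  within-subjects all-four (34 × 4 × 12) and four-of-six (42 × 4 × 12)
  designs.
* **Signal-detection analysis** — per-participant hit and false-alarm
  rates with the standard 1/(2N) correction, `d' = z(H) − z(F)`, t-based
  group confidence intervals, bootstrap proportion-correct summaries by
  condition × stimulus type, ggplot displays, and lossless long-format CSV
  export for external mixed-model fitting.

## Worked example

```r
library(seglab)

lang <- builtin_languages()$L1          # /bakupo/ /delaru/ /fumesi/ /gonite/
stream <- compose_stream(lang, "pause", n_repeats = 24, seed = 42)
stream_duration(stream)
#> [1] 168

transition_stats(stream) |>
  dplyr::group_by(type) |>
  dplyr::summarise(mean_tp = mean(tp), n_bigrams = dplyr::n())
#>   type    mean_tp n_bigrams
#> 1 between   0.333        12
#> 2 within    1             8

records <- simulate_responses(design_spec("between"), cue_pattern_model(), seed = 42)
dprime_summary(sdt_dprime(records))
#>   condition       n mean_d_prime    sd     se ci_low ci_high excludes_chance
#> 1 baseline       34        0.641 0.575 0.0985  0.440  0.841  TRUE
#> 2 lengthening    33        1.76  0.634 0.110   1.54   1.99   TRUE
#> 3 pause          33        1.95  0.587 0.102   1.74   2.16   TRUE
#> 4 pitch_down     35        0.640 0.787 0.133   0.370  0.910  TRUE
#> 5 pitch_up       33        1.03  0.865 0.151   0.726  1.34   TRUE
#> 6 shortening     34       -0.391 0.882 0.151  -0.699 -0.0833 TRUE
```

A 96-word pause-condition stream lasts exactly 168 s (96 × 1.75 s); the
stream's eight within-word bigrams all have TP 1.0 while the twelve
boundary-crossing bigrams average 1/3. The simulated between-subjects
experiment (202 listeners, 2,424 judgements) reproduces the qualitative
cue pattern built into the default response model: convergent cues (pause,
lengthening) lift d′ well above the statistics-only baseline, pitch cues
barely move it, and final shortening — a cue conflicting with the
statistical boundaries — drives discrimination below chance.
`autoplot()` on the summary (or on `proportion_correct(records)`) draws the
usual mean-and-CI displays.

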