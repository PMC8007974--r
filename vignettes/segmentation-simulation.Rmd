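---
title: "Simulating prosodic-cue experiments on statistical word segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating prosodic-cue experiments on statistical word segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seglab)
library(dplyr)
```

`seglab` rebuilds, as executable code, the full pipeline of an
artificial-language-learning experiment on auditory word segmentation: a
constrained nonsense lexicon, a continuous speech stream whose only
systematic structure is syllable transition statistics plus one prosodic
cue, test items probing where listeners place word boundaries, simulated
listeners, and the signal-detection analysis of their judgements. This
vignette documents the models, the parameters that matter, and the
numerical conventions, in the order the pipeline runs.

## Pseudo-languages

A language is four trisyllabic CV words. Two constraint profiles are built
in. The `"exp1"` profile draws from 4 vowels and 7 consonants and only
forbids repeating a syllable within a word. The `"exp2"` profile draws
from 5 vowels and 13 consonants and is much stricter, because
within-subjects designs expose one participant to four different languages
and must avoid cross-language priming: each language uses 12 distinct
consonants (hence all 12 syllables are unique), no word repeats a vowel,
and the 12 vowel slots split 3/3/2/2/2 over the five vowels. Sets of four
languages additionally cap every syllable at two occurrences across the
set.

Generation is rejection sampling: structured uniform draws (a 12-of-13
consonant permutation plus a shuffled vowel multiset for `"exp2"`) are
retried until `validate_language()` passes, with a 10,000-try cap so an
unsatisfiable request — for example a blocklist covering every candidate —
fails loudly rather than spinning. Rejection keeps the draw unbiased by
construction order, and the constraint sets are loose enough that a valid
draw is found within a handful of tries. An optional caller-supplied
blocklist stands in for "not a real word" screening; no lexicon is
bundled because no matching rule is well defined across languages.
`validate_language()` reports violations by name instead of erroring, and
the test suite checks it against an independently written brute-force
checker. The five published languages ship as `builtin_languages()`.

## Streams and transitional probabilities

The word order concatenates each word `n_repeats` times (10 for the
40-word pilot streams, 24 for the 96-word laboratory streams) such that no
word repeats immediately and each word is followed by each other word
"equally often". With `T = 4 * n_repeats - 1` transitions over 12 ordered
pairs, exact equality is impossible (39 and 95 are not multiples of 12),
so equal-often is implemented as *maximal balance*: every ordered pair
count is `floor(T/12)` or `ceil(T/12)`.

Rather than sampling orders greedily and backtracking out of dead ends,
the generator first fixes a balanced pair-count matrix whose row and
column sums match the word occurrence counts (the first and last word of
the stream each lose one degree), then walks it with a randomized
Hierholzer Eulerian-path traversal. Every such walk uses each transition
exactly the prescribed number of times, so the balance invariant holds by
construction, runtime is linear in stream length, and the random edge
choices still spread mass over many admissible orders. The price is that
the distribution over valid orders is not exactly uniform; nothing
downstream depends on uniformity, only on the balance and no-repeat
invariants, which the tests verify directly (including against exhaustive
enumeration at `n_repeats = 2`).

Consequences for TPs, computed by `transition_stats()` with the standard
bigram convention (the stream-final syllable has no outgoing transition):
within-word TPs are exactly 1.0; each between-word TP is near 1/3 but can
deviate by up to about 1/9 on a 40-word stream (a pair count of 3 vs 4
over ~10 antecedent tokens); and the unweighted mean over the twelve
boundary pairs is pinned to 1/3 because each word-final syllable's
outgoing TPs sum to one. Assertions on single pairs therefore use the
loose bound and assertions on the mean the tight one.

## Prosodic conditions

All six conditions share the 500 ms / 210 Hz syllable base (a deliberately
slow 2 syllables/s rate) and differ only on or after the word-final
syllable: a 250 ms silent pause after every word, lengthening to 750 ms,
shortening to 250 ms, or a pitch step to 260 Hz or 160 Hz. Durations and
frequencies are stored as exact integers with no jitter. The pause is
emitted after *every* word including the stream-final one, which makes the
printed stream totals exact rather than rounded: 50/60/70 s at 40 words
and 120/144/168 s at 96 words, depending on condition. The edge fade
steps amplitude by exactly 1/15 per syllable over the first and last 15
syllables (the published 6.66% is 1/15 rounded; the exact fraction
guarantees full amplitude precisely at the 16th syllable with no residue).

## Audio rendering

`render_stream()` synthesises each syllable parametrically: a 20 ms
broadband noise burst as the consonant onset, then a five-harmonic complex
(1/k roll-off) at the token's f0, peak-normalized to
`0.99 * amp_scale`, with 5 ms edge ramps against clicks. Durational
manipulation never rescales the first 20 ms, mirroring the convention of
protecting voice onset time when syllables are stretched or compressed.
Segment lengths are `round(duration * sample_rate / 1000)` samples, pauses
are digital silence, and a JSON manifest records every segment's half-open
0-based sample interval, so rendered timing can be checked sample-exactly.
The WAV writer/reader is a minimal 16-bit PCM mono implementation
(round-trip error at most one least significant bit). Each token is
rendered with a constant f0 (no micro-intonation contour): the analysis
contract downstream is duration/f0/amplitude/pause targets, not voice
naturalness, which is explicitly out of scope.

## Test items

Part-words span a word boundary: class 1-2 takes the final syllable of
word A plus the initial and medial syllables of word B; class 2-1 takes
the medial and final syllables of A plus the initial syllable of B
(A ≠ B). Each class has exactly 4 × 3 = 12 members, every one of which is
realized in a sufficiently long stream. The test set per
participant-condition is 12 items: the 4 words plus 4 items per part-word
class. The published pilot used a fixed list (`mode = "fixed_exp1"`, which
does *not* satisfy the later once-per-part rule — "toga" serves as second
part twice). The within-subjects rule — each first part and each second
part represented exactly once per class — is formalized as a derangement:
item *i* pairs word *i*'s part with word *σ(i)*'s part, σ a fixed-point-free
permutation. That reading is the unique one under which all eight parts
appear exactly once with A ≠ B; it yields exactly 9 admissible selections
per class, drawn uniformly.

## Simulated listeners

Human data are not shipped, so listeners are simulated. The response model
gives each (condition, stimulus type) cell an endorsement probability
("this is a word"), and each participant a logit offset
`u ~ Normal(0, subject_sd)` — the simplest structure compatible with
a random-intercept logistic account of such data. A trial is a Bernoulli
draw from `plogis(qlogis(p) + u)`; a response is correct if a word is
endorsed or a part-word rejected, so chance is 0.5 everywhere.

The `cue_pattern_model()` preset encodes the qualitative
convergence/conflict pattern, with `subject_sd = 0.5`:

```{r preset, echo = FALSE}
cue_pattern_model()$p_word |>
  tidyr::pivot_wider(names_from = stimulus_type, values_from = p_word)
```

These magnitudes are illustrative free parameters, not fitted values; only
their ordinal structure is meaningful and tested: pauses and lengthening
give high hits and few false alarms; shortening inverts the pattern — words
are missed and PW2-1 items (whose shortened syllable sits word-medially,
where listeners expect a short syllable) are endorsed as words; pitch
conditions sit near baseline. Passing tests therefore show that the
pipeline *propagates* such a pattern faithfully from response
probabilities through to d′ and proportion-correct displays — not that
human listeners behave this way, and none of the published effect sizes
are reproduced or asserted numerically.

The three design layouts reproduce the published arithmetic: between
subjects, 202 participants (group sizes 34/33/33/34/33/35) × 12 trials =
2,424 records; all-four within, 34 × 4 × 12 = 1,632; four-of-six within
(baseline, pause, one durational, one pitch condition each), 42 × 4 × 12 =
2,016, with the four duration × pitch assignments balanced to within one
participant and condition order randomized (the published order effect is
null, so order carries no effect in the simulation either).

## Signal-detection analysis

Per participant-condition cell (4 signal trials, 8 noise trials): hit rate
H and false-alarm rate F, the 1/(2N) correction applied *per rate* with
that rate's own N (4 or 8) — the rule is stated per proportion and the
design is asymmetric — and `d' = qnorm(H') - qnorm(F')`. Group summaries
are means over participants with t-based confidence intervals; the t
interval is a documented assumption (the CI formula behind the published
figures is not stated, but the displayed intervals are symmetric, and the
t interval is the standard choice for between-participant means).
Correction per participant rather than on pooled group rates is likewise
assumed, consistent with per-participant d′ distributions being displayed.
Proportion-correct summaries bootstrap participants within condition
(percentile intervals, 1,000 draws by default, seeded).
`expected_d_prime()` gives the exact finite-trial expectation of d′
implied by cell probabilities (a binomial enumeration over the 5 × 9
possible count pairs), which is what simulated means are checked against —
at 4 and 8 trials the correction compresses extreme rates, so expected d′
is noticeably below the asymptotic `qnorm(h) - qnorm(f)`.

Mixed-model fitting itself is out of scope; `export_long_format()` writes
the exact one-row-per-judgement CSV (participant, condition, stimulus
type, language, order, trial, response, correctness) that external GLMM
tooling consumes, and round-trips losslessly.

## Problem sizes and numerical conventions

The package's own test and demonstration runs use the published stimulus
scales (40- and 96-word streams) throughout. Monte-Carlo checks use
10,000 simulated participants for parameter recovery and 1,000 replicates
of a 34-participant group for the chance-calibration coverage check;
audio checks render at 8 kHz, which the synthesis contract treats
identically to 44.1 kHz apart from sample counts. Ties in FFT peak
picking, RNG reproducibility (every stochastic entry point takes a
`seed`), and integer-exact duration bookkeeping in ms are the only other
numerical conventions of note. Known limitations: the synthesiser makes
no attempt at naturalistic voice quality or coarticulation; the simulated
listeners have no learning dynamics (their probabilities are stationary
within a condition); and uniformity over admissible word orders is
approximate, as discussed above.
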