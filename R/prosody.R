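#' Prosodic condition specifications
#'
#' The six experimental conditions share a common base: every syllable is
#' normalized to 500 ms and 210 Hz. Each non-baseline condition modifies only
#' the word-final syllable (for duration and pitch) or inserts silence after
#' it (for pauses):
#'
#' | condition     | final duration | final f0 | pause after word |
#' |---------------|---------------:|---------:|-----------------:|
#' | `baseline`    | 500 ms         | 210 Hz   | 0 ms             |
#' | `pause`       | 500 ms         | 210 Hz   | 250 ms           |
#' | `lengthening` | 750 ms         | 210 Hz   | 0 ms             |
#' | `shortening`  | 250 ms         | 210 Hz   | 0 ms             |
#' | `pitch_up`    | 500 ms         | 260 Hz   | 0 ms             |
#' | `pitch_down`  | 500 ms         | 160 Hz   | 0 ms             |
#'
#' @param name One of `"baseline"`, `"pause"`, `"lengthening"`,
#'   `"shortening"`, `"pitch_up"`, `"pitch_down"`.
#' @return A one-row tibble of class `seg_condition` with columns
#'   `condition`, `base_duration`, `base_f0`, `final_duration`, `final_f0`,
#'   `pause_after_final` (all durations ms, f0 Hz).
#' @examples
#' condition_spec("lengthening")
#' @export
condition_spec <- function(name = condition_names()) {
  name <- match.arg(name)
  spec <- tibble::tibble(
    condition = name,
    base_duration = 500,
    base_f0 = 210,
    final_duration = switch(name,
      lengthening = 750,
      shortening = 250,
      500
    ),
    final_f0 = switch(name,
      pitch_up = 260,
      pitch_down = 160,
      210
    ),
    pause_after_final = if (name == "pause") 250 else 0
  )
  class(spec) <- c("seg_condition", class(spec))
  spec
}

#' @rdname condition_spec
#' @export
condition_names <- function() {
  c("baseline", "pause", "lengthening", "shortening", "pitch_up", "pitch_down")
}

#' Apply a prosodic condition to a syllable token stream
#'
#' Attaches per-token acoustic targets. All tokens carry the base duration
#' and f0; tokens in `"final"` position carry the condition's final-syllable
#' duration and f0, and the condition's pause is emitted after every
#' word-final token, including the last word of the stream.
#'
#' @param tokens Token tibble from [build_stream()].
#' @param condition A condition name or a [condition_spec()].
#' @return The token tibble with added columns `duration` (ms), `f0` (Hz),
#'   `pause_after` (ms), `amp_scale` (1 until [fade_envelope()] is applied),
#'   and `condition`; class `seg_stream`.
#' @examples
#' lang <- builtin_languages()$L0
#' st <- build_stream(lang, generate_word_order(n_repeats = 10, seed = 1))
#' apply_condition(st, "pause")
#' @export
apply_condition <- function(tokens, condition = "baseline") {
  if (is.character(condition)) condition <- condition_spec(condition)
  stopifnot(nrow(tokens) > 0L, all(tokens$position %in% c("initial", "medial", "final")))
  spec <- as.list(condition)
  is_final <- tokens$position == "final"
  out <- tokens |>
    dplyr::mutate(
      condition = spec$condition,
      duration = ifelse(is_final, spec$final_duration, spec$base_duration),
      f0 = ifelse(is_final, spec$final_f0, spec$base_f0),
      pause_after = ifelse(is_final, spec$pause_after_final, 0),
      amp_scale = 1
    )
  class(out) <- c("seg_stream", class(tokens))
  out
}

#' Apply the stream-edge fade envelope
#'
#' The amplitude of the first 15 syllables (the first five words) ramps up in
#' steps of 1/15 of peak amplitude, reaching full amplitude at the 16th
#' syllable (the start of the sixth word); the last 15 syllables mirror this
#' ramp downwards, the final syllable ending at 1/15. This prevents the
#' perceived start and end of the stream from marking word boundaries.
#'
#' @param stream A `seg_stream` from [apply_condition()] with at least 30
#'   tokens.
#' @return The stream with `amp_scale` set.
#' @export
fade_envelope <- function(stream) {
  n <- nrow(stream)
  if (n < 30L) {
    stop("fade envelope needs at least 30 syllable tokens", call. = FALSE)
  }
  amp <- rep(1, n)
  k <- 1:15
  amp[k] <- k / 15
  amp[n - k + 1L] <- k / 15
  stream$amp_scale <- amp
  stream
}

#' Total duration of a prosodic stream in seconds
#'
#' Sums syllable durations and the pauses emitted after word-final syllables.
#'
#' @param stream A `seg_stream` (or any tibble with `duration` and
#'   `pause_after` in ms).
#' @return Duration in seconds.
#' @examples
#' lang <- builtin_languages()$L0
#' st <- build_stream(lang, generate_word_order(n_repeats = 10, seed = 1))
#' stream_duration(apply_condition(st, "pause")) # 70 s
#' @export
stream_duration <- function(stream) {
  if (nrow(stream) == 0L) {
    return(0)
  }
  sum(stream$duration + stream$pause_after) / 1000
}

#' Build a complete conditioned stream in one call
#'
#' Convenience wrapper: word order -> syllable tokens -> condition targets ->
#' fade envelope.
#'
#' @inheritParams build_stream
#' @inheritParams apply_condition
#' @param n_repeats Occurrences per word (10 or 24 in the published designs).
#' @param seed Seed for the word order.
#' @return A `seg_stream` tibble.
#' @examples
#' compose_stream(builtin_languages()$L1, "lengthening", n_repeats = 24, seed = 2)
#' @export
compose_stream <- function(language, condition = "baseline", n_repeats = 10L,
                           seed = NULL) {
  order <- generate_word_order(length(language$words), n_repeats, seed = seed)
  build_stream(language, order) |>
    apply_condition(condition) |>
    fade_envelope()
}
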