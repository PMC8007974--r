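#' Rendering configuration for parametric syllable synthesis
#'
#' Syllables are synthesised parametrically: a brief broadband noise burst
#' stands in for the consonant onset, followed by a harmonic complex (first
#' five harmonics, 1/k amplitude roll-off) at the token's f0 for the voiced
#' remainder. Durational manipulation never touches the first
#' `onset_protect` ms of a syllable, mirroring the practice of leaving voice
#' onset time intact when syllables are stretched or compressed.
#'
#' @param sample_rate Samples per second (>= 8000).
#' @param peak_amplitude Per-syllable absolute peak after scaling (0.99).
#' @param onset_protect Unscaled consonant onset, ms.
#' @param backend Synthesis backend; only `"harmonic"` is provided.
#' @return A list of class `seg_render_config`.
#' @export
render_config <- function(sample_rate = 44100, peak_amplitude = 0.99,
                          onset_protect = 20, backend = "harmonic") {
  if (sample_rate < 8000) stop("sample_rate must be >= 8000 Hz", call. = FALSE)
  if (peak_amplitude <= 0 || peak_amplitude > 1) {
    stop("peak_amplitude must be in (0, 1]", call. = FALSE)
  }
  if (!identical(backend, "harmonic")) {
    stop("unknown synthesis backend: ", backend, call. = FALSE)
  }
  structure(
    list(
      sample_rate = sample_rate, peak_amplitude = peak_amplitude,
      onset_protect = onset_protect, backend = backend
    ),
    class = "seg_render_config"
  )
}

## One syllable: onset_protect ms of noise burst, voiced harmonic remainder.
## Peak-normalized to `peak`; short linear ramps avoid boundary clicks.
synth_syllable <- function(duration_ms, f0, peak, config, seed_offset = 0L) {
  sr <- config$sample_rate
  n <- round(duration_ms * sr / 1000)
  n_burst <- min(n, round(config$onset_protect * sr / 1000))
  burst <- runif(n_burst, -1, 1) * seq(1, 0.3, length.out = n_burst)
  n_voice <- n - n_burst
  if (f0 >= sr / 2) stop("sample rate too low to represent f0", call. = FALSE)
  k_max <- max(1L, min(5L, floor((sr / 2 - 1) / f0)))
  t <- seq_len(n_voice) / sr
  voice <- rep(0, n_voice)
  for (k in seq_len(k_max)) voice <- voice + sin(2 * pi * k * f0 * t) / k
  ramp_n <- min(n_voice, round(0.005 * sr))
  if (ramp_n > 0) {
    voice[seq_len(ramp_n)] <- voice[seq_len(ramp_n)] * seq(0, 1, length.out = ramp_n)
    voice[n_voice - seq_len(ramp_n) + 1L] <-
      voice[n_voice - seq_len(ramp_n) + 1L] * seq(0, 1, length.out = ramp_n)
  }
  x <- c(burst * 0.4, voice)
  x / max(abs(x)) * peak
}

#' Render a prosodic stream to PCM samples (and optionally a WAV file)
#'
#' Each syllable token becomes a segment of exactly
#' `round(duration * sample_rate / 1000)` samples, peak-scaled to
#' `peak_amplitude * amp_scale`; pauses become runs of zero samples. A
#' segment manifest records every token's half-open sample interval
#' (0-based), so rendered timing can be checked against the symbolic stream
#' sample-exactly.
#'
#' @param stream A `seg_stream` (apply the fade envelope first).
#' @param config A [render_config()].
#' @param path Optional path; when given, a 16-bit PCM mono WAV is written
#'   there and a JSON segment manifest next to it (`<path>.json`).
#' @param seed Seed for the noise bursts.
#' @return A list of class `seg_rendering`: `samples` (numeric vector in
#'   \[-1, 1\]), `sample_rate`, `manifest` (tibble with `stream_index`,
#'   `syllable`, `onset`, `offset`, `pause_samples`, `duration`, `f0`,
#'   `amp_scale`), and `path` (or `NULL`).
#' @examples
#' st <- compose_stream(builtin_languages()$L0, "pause", n_repeats = 10, seed = 1)
#' r <- render_stream(st, render_config(sample_rate = 8000), seed = 1)
#' length(r$samples) / r$sample_rate # 70 s
#' @export
render_stream <- function(stream, config = render_config(), path = NULL,
                          seed = NULL) {
  stopifnot(inherits(stream, "seg_stream"))
  if (!is.null(seed)) withr::local_seed(seed)
  sr <- config$sample_rate

  seg_n <- round(stream$duration * sr / 1000)
  pause_n <- round(stream$pause_after * sr / 1000)
  onsets <- cumsum(c(0, head(seg_n + pause_n, -1L)))

  pieces <- vector("list", nrow(stream))
  for (i in seq_len(nrow(stream))) {
    syl <- synth_syllable(
      stream$duration[i], stream$f0[i],
      config$peak_amplitude * stream$amp_scale[i], config
    )
    pieces[[i]] <- c(syl, rep(0, pause_n[i]))
  }
  samples <- unlist(pieces, use.names = FALSE)

  manifest <- tibble::tibble(
    stream_index = stream$stream_index,
    syllable = stream$syllable,
    position = stream$position,
    onset = onsets,
    offset = onsets + seg_n,
    pause_samples = pause_n,
    duration = stream$duration,
    f0 = stream$f0,
    amp_scale = stream$amp_scale
  )

  if (!is.null(path)) {
    write_wav(samples, sr, path)
    jsonlite::write_json(
      list(
        sample_rate = sr, condition = stream$condition[1],
        segments = manifest
      ),
      paste0(path, ".json"),
      auto_unbox = TRUE, digits = NA
    )
  }

  structure(
    list(samples = samples, sample_rate = sr, manifest = manifest, path = path),
    class = "seg_rendering"
  )
}

#' Minimal 16-bit PCM mono WAV writer / reader
#'
#' @param samples Numeric vector in \[-1, 1\].
#' @param sample_rate Samples per second.
#' @param path Output file.
#' @return `write_wav()` returns `path` invisibly; `read_wav()` a list with
#'   `samples` (numeric, rescaled to \[-1, 1\]) and `sample_rate`.
#' @export
write_wav <- function(samples, sample_rate, path) {
  pcm <- as.integer(pmax(pmin(round(samples * 32767), 32767), -32768))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little") # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little") # PCM
  writeBin(1L, con, size = 2, endian = "little") # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little") # block align
  writeBin(16L, con, size = 2, endian = "little") # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  stopifnot(riff == "RIFF")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  stopifnot(readChar(con, 4) == "WAVE")
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "raw", size - 8))
    } else if (id == "data") {
      pcm <- readBin(con, "integer", size / 2, size = 2, endian = "little", signed = TRUE)
      return(list(samples = pcm / 32767, sample_rate = sample_rate))
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  stop("no data chunk found in ", path, call. = FALSE)
}
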