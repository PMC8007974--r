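#' Apply the 1/(2N) correction to hit / false-alarm proportions
#'
#' Proportions of exactly 0 are replaced by `1/(2N)` and proportions of
#' exactly 1 by `1 - 1/(2N)`, where `N` is the trial count behind that
#' proportion (so hits and false alarms use their own `N`: 4 signal and 8
#' noise trials per participant-condition cell in the published designs).
#' Interior proportions are unchanged. This keeps the normal quantiles, and
#' hence d-prime, finite.
#'
#' @param rate Observed proportion(s) in \[0, 1\].
#' @param n Trial count(s) behind each proportion.
#' @return Adjusted proportion(s), strictly inside (0, 1).
#' @examples
#' adjust_rate(1, 4) # 0.875
#' adjust_rate(0, 8) # 0.0625
#' @export
adjust_rate <- function(rate, n) {
  if (any(n <= 0)) stop("trial counts must be positive", call. = FALSE)
  dplyr::case_when(
    rate <= 0 ~ 1 / (2 * n),
    rate >= 1 ~ 1 - 1 / (2 * n),
    .default = rate
  )
}

#' Per-participant signal-detection results
#'
#' For every participant-condition cell, counts hits (words endorsed as
#' words), misses, false alarms (part-words endorsed as words) and correct
#' rejections, applies the 1/(2N) correction to the hit and false-alarm
#' rates, and computes `d' = qnorm(adjusted hit rate) - qnorm(adjusted
#' false-alarm rate)`. `d' = 0` is chance discrimination of words from
#' part-words; positive values mean words were endorsed more readily than
#' part-words.
#'
#' @param records Response records from [simulate_responses()] (or any
#'   tibble with `participant`, `condition`, `stimulus_type`, `response`).
#' @return A tibble of class `seg_dprime` with one row per
#'   participant-condition: counts, `n_signal`, `n_noise`, raw and adjusted
#'   rates, `d_prime`.
#' @examples
#' records <- simulate_responses(design_spec("between"), cue_pattern_model(), seed = 1)
#' sdt_dprime(records)
#' @export
sdt_dprime <- function(records) {
  stopifnot(nrow(records) > 0L)
  out <- records |>
    dplyr::mutate(
      is_signal = .data$stimulus_type == "WORD",
      endorsed = .data$response == "WORD_YES"
    ) |>
    dplyr::group_by(.data$participant, .data$condition) |>
    dplyr::summarise(
      hits = sum(.data$is_signal & .data$endorsed),
      misses = sum(.data$is_signal & !.data$endorsed),
      false_alarms = sum(!.data$is_signal & .data$endorsed),
      correct_rejections = sum(!.data$is_signal & !.data$endorsed),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_signal = .data$hits + .data$misses,
      n_noise = .data$false_alarms + .data$correct_rejections,
      raw_hit_rate = .data$hits / .data$n_signal,
      raw_fa_rate = .data$false_alarms / .data$n_noise,
      adj_hit_rate = adjust_rate(.data$raw_hit_rate, .data$n_signal),
      adj_fa_rate = adjust_rate(.data$raw_fa_rate, .data$n_noise),
      d_prime = qnorm(.data$adj_hit_rate) - qnorm(.data$adj_fa_rate)
    )
  if (any(out$n_signal == 0L) || any(out$n_noise == 0L)) {
    stop("every participant-condition cell needs both signal and noise trials",
      call. = FALSE
    )
  }
  class(out) <- c("seg_dprime", class(out))
  out
}

#' Group-level d-prime summary with confidence intervals
#'
#' Per condition: mean d-prime over participants with a t-based confidence
#' interval (`mean +/- t(n-1, 1-(1-level)/2) * SE`), a flag for whether the
#' interval excludes 0 (chance), and the participant count.
#'
#' @param dprime A `seg_dprime` tibble from [sdt_dprime()].
#' @param level Confidence level (0.95).
#' @return A tibble of class `seg_dprime_summary`: `condition`, `n`,
#'   `mean_d_prime`, `sd`, `ci_low`, `ci_high`, `excludes_chance`.
#' @export
dprime_summary <- function(dprime, level = 0.95) {
  counts <- dplyr::count(dprime, .data$condition)
  if (any(counts$n < 2L)) {
    stop("confidence intervals need at least 2 participants per condition",
      call. = FALSE
    )
  }
  out <- dprime |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_d_prime = mean(.data$d_prime),
      sd = sd(.data$d_prime),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      se = .data$sd / sqrt(.data$n),
      ci_low = .data$mean_d_prime - qt(1 - (1 - level) / 2, .data$n - 1) * .data$se,
      ci_high = .data$mean_d_prime + qt(1 - (1 - level) / 2, .data$n - 1) * .data$se,
      excludes_chance = .data$ci_low > 0 | .data$ci_high < 0
    )
  class(out) <- c("seg_dprime_summary", class(out))
  out
}

#' @export
tidy.seg_dprime <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.seg_dprime <- function(x, ...) {
  tibble::tibble(
    n_participants = dplyr::n_distinct(x$participant),
    n_conditions = dplyr::n_distinct(x$condition),
    mean_d_prime = mean(x$d_prime),
    sd_d_prime = sd(x$d_prime)
  )
}

#' Proportion of correct answers by condition and stimulus type
#'
#' A response is correct when a word is endorsed or a part-word rejected,
#' so chance is 0.5 in every cell. The cell estimate is the mean over
#' participants of each participant's proportion correct; the confidence
#' interval is a percentile bootstrap that resamples participants within
#' each condition.
#'
#' @param records Response records.
#' @param n_boot Bootstrap draws (1000).
#' @param level Confidence level.
#' @param seed Seed for the bootstrap.
#' @return A tibble of class `seg_prop_correct`: `condition`,
#'   `stimulus_type`, `n_participants`, `prop_correct`, `ci_low`, `ci_high`.
#' @examples
#' records <- simulate_responses(design_spec("between"), cue_pattern_model(), seed = 1)
#' proportion_correct(records, n_boot = 200, seed = 2)
#' @export
proportion_correct <- function(records, n_boot = 1000L, level = 0.95,
                               seed = NULL) {
  stopifnot(nrow(records) > 0L)
  if (!is.null(seed)) withr::local_seed(seed)
  alpha <- (1 - level) / 2

  per_part <- records |>
    dplyr::group_by(.data$condition, .data$stimulus_type, .data$participant) |>
    dplyr::summarise(prop = mean(.data$correct), .groups = "drop")

  boot_cell <- function(props) {
    means <- vapply(
      seq_len(n_boot),
      function(i) mean(props[sample.int(length(props), replace = TRUE)]),
      numeric(1)
    )
    quantile(means, c(alpha, 1 - alpha), names = FALSE)
  }

  out <- per_part |>
    dplyr::group_by(.data$condition, .data$stimulus_type) |>
    dplyr::summarise(
      n_participants = dplyr::n(),
      prop_correct = mean(.data$prop),
      ci = list(boot_cell(.data$prop)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ci_low = purrr::map_dbl(.data$ci, 1),
      ci_high = purrr::map_dbl(.data$ci, 2)
    ) |>
    dplyr::select(-"ci")
  class(out) <- c("seg_prop_correct", class(out))
  out
}

#' Export / import response records as long-format CSV
#'
#' One row per judgment with dummy-codable columns, the exact table needed
#' to fit logistic mixed models (condition x stimulus type with
#' participant random effects) in external tooling. The round trip is
#' lossless.
#'
#' @param records Response records.
#' @param path CSV path.
#' @return `export_long_format()` returns `path` invisibly;
#'   `read_long_format()` returns the records tibble.
#' @export
export_long_format <- function(records, path) {
  cols <- c(
    "participant", "condition", "stimulus_type", "language_id",
    "condition_order", "trial", "response", "correct"
  )
  missing <- setdiff(cols, names(records))
  for (m in missing) records[[m]] <- NA
  readr::write_csv(records[cols], path)
  invisible(path)
}

#' @rdname export_long_format
#' @export
read_long_format <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      participant = readr::col_integer(),
      condition = readr::col_character(),
      stimulus_type = readr::col_character(),
      language_id = readr::col_character(),
      condition_order = readr::col_integer(),
      trial = readr::col_integer(),
      response = readr::col_character(),
      correct = readr::col_logical()
    )
  )
}

#' Analytic expected d-prime implied by a response model cell
#'
#' For endorsement probability `h` on words and `f` on part-words (no
#' participant heterogeneity), the expected per-participant d-prime is the
#' exact binomial expectation of `qnorm(adjusted hit rate) - qnorm(adjusted
#' false-alarm rate)` over the 4 signal and 8 noise trials. Simulated mean
#' d-prime converges to this value as the number of participants grows;
#' used for parameter-recovery checks.
#'
#' @param h Endorsement probability for words.
#' @param f Endorsement probability for part-words.
#' @param n_signal,n_noise Trials per cell (4 and 8).
#' @return Expected d-prime (scalar).
#' @export
expected_d_prime <- function(h, f, n_signal = 4L, n_noise = 8L) {
  e_z <- function(p, n) {
    k <- 0:n
    sum(stats::dbinom(k, n, p) * qnorm(adjust_rate(k / n, n)))
  }
  e_z(h, n_signal) - e_z(f, n_noise)
}
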