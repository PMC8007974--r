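#' Listener response models
#'
#' A response model specifies, for every (condition, stimulus type) cell, the
#' probability that a simulated listener endorses a test item as a "word",
#' plus a between-participant spread: each participant draws a logit offset
#' from `Normal(0, subject_sd)` that shifts all their endorsement
#' probabilities, mirroring a random-intercept structure.
#'
#' @param p_word A tibble with columns `condition`, `stimulus_type`
#'   (`"WORD"`, `"PW12"`, `"PW21"`), `p_word` (probabilities strictly inside
#'   (0, 1)).
#' @param subject_sd Standard deviation of the per-participant logit offset.
#' @return A list of class `seg_response_model`.
#' @seealso [guessing_model()], [cue_pattern_model()]
#' @export
response_model <- function(p_word, subject_sd = 0) {
  stopifnot(
    all(c("condition", "stimulus_type", "p_word") %in% names(p_word)),
    all(p_word$p_word > 0 & p_word$p_word < 1),
    subject_sd >= 0
  )
  structure(
    list(p_word = tibble::as_tibble(p_word), subject_sd = subject_sd),
    class = "seg_response_model"
  )
}

#' @describeIn response_model Pure guessing: every cell has endorsement
#'   probability 0.5 and no participant heterogeneity, so accuracy and
#'   d-prime are at chance in every condition.
#' @export
guessing_model <- function() {
  cells <- tidyr::expand_grid(
    condition = condition_names(),
    stimulus_type = c("WORD", "PW12", "PW21")
  )
  response_model(dplyr::mutate(cells, p_word = 0.5), subject_sd = 0)
}

# Illustrative endorsement probabilities (probability of calling the item a
# "word"). Magnitudes are free parameters; only the ordinal structure is
# meaningful: pauses and final lengthening converge with the statistical
# cue (high hits, few false alarms), final shortening conflicts with it
# (missed words, frequent endorsement of PW21 items whose shortened syllable
# sits word-medially), and pitch cues barely move performance off baseline.
cue_pattern_cells <- function() {
  tibble::tribble(
    ~condition, ~WORD, ~PW12, ~PW21,
    "baseline", 0.62, 0.38, 0.38,
    "pause", 0.85, 0.15, 0.15,
    "lengthening", 0.83, 0.17, 0.17,
    "shortening", 0.35, 0.28, 0.72,
    "pitch_up", 0.66, 0.36, 0.36,
    "pitch_down", 0.60, 0.40, 0.40
  ) |>
    tidyr::pivot_longer(-"condition",
      names_to = "stimulus_type", values_to = "p_word"
    )
}

#' @describeIn response_model Cue-convergence/cue-conflict preset encoding
#'   the qualitative pattern of the published experiments (see Details of
#'   the probabilities in the package vignette).
#' @export
cue_pattern_model <- function(subject_sd = 0.5) {
  response_model(cue_pattern_cells(), subject_sd = subject_sd)
}

#' Experimental design specifications
#'
#' Three layouts mirror the published experiments:
#'
#' * `"between"` — each participant is tested on exactly one of the six
#'   conditions. The default group sizes are the published ones (pause,
#'   lengthening, pitch-up: 33; baseline, shortening: 34; pitch-down: 35;
#'   202 in total), all on language `L0`. With custom `n_participants` or
#'   `conditions`, participants are spread over conditions as evenly as
#'   possible.
#' * `"within_all4"` — every participant is tested on all four conditions
#'   baseline/pause/lengthening/shortening (default n = 34), with the four
#'   languages `L1`–`L4` assigned to conditions by a per-participant random
#'   permutation and condition order randomized.
#' * `"within_4of6"` — every participant is tested on baseline, pause, one
#'   durational condition (lengthening or shortening) and one pitch
#'   condition (default n = 42); the four duration-by-pitch assignments are
#'   balanced to within one participant.
#'
#' Every participant-condition cell has 12 trials: 4 words, 4 part-words
#' 1-2, 4 part-words 2-1.
#'
#' @param layout `"between"`, `"within_all4"` or `"within_4of6"`.
#' @param n_participants Number of participants (defaults: 202 / 34 / 42).
#' @param conditions Conditions used (defaults per layout).
#' @return A list of class `seg_design`.
#' @examples
#' design_spec("within_all4")
#' @export
design_spec <- function(layout = c("between", "within_all4", "within_4of6"),
                        n_participants = NULL, conditions = NULL) {
  layout <- match.arg(layout)
  defaults <- switch(layout,
    between = list(n = 202L, conditions = condition_names()),
    within_all4 = list(
      n = 34L,
      conditions = c("baseline", "pause", "lengthening", "shortening")
    ),
    within_4of6 = list(n = 42L, conditions = condition_names())
  )
  structure(
    list(
      layout = layout,
      n_participants = as.integer(n_participants %||% defaults$n),
      conditions = conditions %||% defaults$conditions,
      trials_per_condition = 12L
    ),
    class = "seg_design"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Published Exp-1 group sizes, reused whenever the between design is run at
## its default size over all six conditions.
between_group_sizes <- c(
  baseline = 34L, pause = 33L, lengthening = 33L,
  shortening = 34L, pitch_up = 33L, pitch_down = 35L
)

## participant -> condition assignment table with language and order labels
assign_conditions <- function(design) {
  n <- design$n_participants
  conds <- design$conditions
  if (design$layout == "between") {
    sizes <- if (n == 202L && setequal(conds, condition_names())) {
      between_group_sizes[conds]
    } else {
      k <- length(conds)
      base <- n %/% k
      extra <- sample(conds, n %% k)
      stats::setNames(base + as.integer(conds %in% extra), conds)
    }
    assignment <- tibble::tibble(
      participant = seq_len(n),
      condition = sample(rep(conds, times = sizes)),
      language_id = "L0",
      condition_order = 1L
    )
  } else if (design$layout == "within_all4") {
    assignment <- purrr::map_dfr(seq_len(n), function(p) {
      tibble::tibble(
        participant = p,
        condition = sample(conds),
        language_id = paste0("L", sample(4L)),
        condition_order = seq_along(conds)
      )
    })
  } else { # within_4of6
    combos <- tidyr::expand_grid(
      duration = c("lengthening", "shortening"),
      pitch = c("pitch_up", "pitch_down")
    )
    # balance the 4 duration x pitch assignments to within one participant
    idx <- sample(rep(seq_len(4L), length.out = n))
    assignment <- purrr::map_dfr(seq_len(n), function(p) {
      cset <- c(
        "baseline", "pause",
        combos$duration[idx[p]], combos$pitch[idx[p]]
      )
      tibble::tibble(
        participant = p,
        condition = sample(cset),
        language_id = paste0("L", sample(4L)),
        condition_order = 1:4
      )
    })
  }
  assignment
}

#' Simulate listener responses for a full experimental design
#'
#' Draws one binary "word"/"not word" judgment per trial. For participant
#' `j` with offset `u_j ~ Normal(0, subject_sd)` and cell probability `p`,
#' the endorsement probability is `plogis(qlogis(p) + u_j)`. A response is
#' correct when a word is endorsed or a part-word is rejected.
#'
#' @param design A [design_spec()].
#' @param model A [response_model()].
#' @param seed Integer seed; identical seeds give identical record tables.
#' @return A tibble with one row per judgment: `participant`, `condition`,
#'   `language_id`, `condition_order`, `trial`, `stimulus_type`, `response`
#'   (`"WORD_YES"`/`"WORD_NO"`), `correct` (logical).
#' @examples
#' records <- simulate_responses(design_spec("between"), cue_pattern_model(), seed = 1)
#' nrow(records) # 2424
#' @export
simulate_responses <- function(design, model, seed = NULL) {
  stopifnot(inherits(design, "seg_design"), inherits(model, "seg_response_model"))
  if (!is.null(seed)) withr::local_seed(seed)

  needed <- tidyr::expand_grid(
    condition = design$conditions,
    stimulus_type = c("WORD", "PW12", "PW21")
  )
  missing_cells <- dplyr::anti_join(needed, model$p_word,
    by = c("condition", "stimulus_type")
  )
  if (nrow(missing_cells) > 0L) {
    stop("response model is missing cells: ",
      paste(missing_cells$condition, missing_cells$stimulus_type,
        sep = ":", collapse = ", "
      ),
      call. = FALSE
    )
  }

  assignment <- assign_conditions(design)
  offsets <- tibble::tibble(
    participant = seq_len(design$n_participants),
    offset = rnorm(design$n_participants, 0, model$subject_sd)
  )

  trial_types <- rep(c("WORD", "PW12", "PW21"), each = 4L)
  records <- assignment |>
    tidyr::expand_grid(slot = seq_len(12L)) |>
    dplyr::group_by(.data$participant, .data$condition) |>
    dplyr::mutate(
      stimulus_type = sample(trial_types),
      trial = .data$slot
    ) |>
    dplyr::ungroup() |>
    dplyr::left_join(model$p_word, by = c("condition", "stimulus_type")) |>
    dplyr::left_join(offsets, by = "participant") |>
    dplyr::mutate(
      p = stats::plogis(stats::qlogis(.data$p_word) + .data$offset),
      endorsed = runif(dplyr::n()) < .data$p,
      response = ifelse(.data$endorsed, "WORD_YES", "WORD_NO"),
      correct = .data$endorsed == (.data$stimulus_type == "WORD")
    ) |>
    dplyr::select(
      "participant", "condition", "language_id", "condition_order",
      "trial", "stimulus_type", "response", "correct"
    ) |>
    dplyr::arrange(.data$participant, .data$condition_order, .data$trial)
  records
}
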