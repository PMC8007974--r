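test_that("the three designs produce the published record counts", {
  m <- cue_pattern_model()
  r1 <- simulate_responses(design_spec("between"), m, seed = 1)
  expect_identical(nrow(r1), 2424L) # 202 participants x 12 trials
  expect_identical(dplyr::n_distinct(r1$participant), 202L)
  # each participant sees exactly one condition, with the published group sizes
  per <- dplyr::distinct(r1, participant, condition)
  expect_identical(nrow(per), 202L)
  sizes <- sort(as.integer(table(per$condition)))
  expect_identical(sizes, c(33L, 33L, 33L, 34L, 34L, 35L))

  r2 <- simulate_responses(design_spec("within_all4"), m, seed = 2)
  expect_identical(nrow(r2), 1632L) # 34 x 4 x 12
  expect_true(all(table(r2$participant) == 48))

  r3 <- simulate_responses(design_spec("within_4of6"), m, seed = 3)
  expect_identical(nrow(r3), 2016L) # 42 x 4 x 12
})

test_that("each cell has 4 words, 4 PW12 and 4 PW21 trials", {
  r <- simulate_responses(design_spec("within_all4"), guessing_model(), seed = 5)
  cells <- r |>
    dplyr::count(participant, condition, stimulus_type)
  expect_true(all(cells$n == 4))
})

test_that("within-subject layouts assign languages and conditions correctly", {
  r2 <- simulate_responses(design_spec("within_all4"), guessing_model(), seed = 6)
  per <- dplyr::distinct(r2, participant, condition, language_id)
  # every participant: all four conditions, all four languages, bijectively
  by_part <- split(per, per$participant)
  for (p in by_part) {
    expect_setequal(p$condition, c("baseline", "pause", "lengthening", "shortening"))
    expect_setequal(p$language_id, paste0("L", 1:4))
  }

  r3 <- simulate_responses(design_spec("within_4of6"), guessing_model(), seed = 7)
  per3 <- dplyr::distinct(r3, participant, condition)
  for (p in split(per3, per3$participant)) {
    expect_true(all(c("baseline", "pause") %in% p$condition))
    expect_identical(sum(p$condition %in% c("lengthening", "shortening")), 1L)
    expect_identical(sum(p$condition %in% c("pitch_up", "pitch_down")), 1L)
  }
  # the 4 duration x pitch assignments are balanced to within one participant
  combos <- per3 |>
    dplyr::group_by(participant) |>
    dplyr::summarise(
      combo = paste(sort(condition[!condition %in% c("baseline", "pause")]),
        collapse = "+"
      )
    )
  tab <- table(combos$combo)
  expect_identical(length(tab), 4L)
  expect_lte(max(tab) - min(tab), 1L)
})

test_that("identical seeds give identical record tables", {
  d <- design_spec("within_4of6")
  m <- cue_pattern_model()
  expect_identical(
    simulate_responses(d, m, seed = 42),
    simulate_responses(d, m, seed = 42)
  )
})

test_that("a missing model cell is reported", {
  m <- response_model(
    tibble::tibble(
      condition = "baseline",
      stimulus_type = c("WORD", "PW12", "PW21"),
      p_word = 0.5
    )
  )
  expect_error(
    simulate_responses(design_spec("between"), m, seed = 1),
    "missing cells"
  )
})

test_that("the guessing preset yields chance-level accuracy in every cell", {
  r <- simulate_responses(design_spec("between"), guessing_model(), seed = 9)
  cells <- r |>
    dplyr::group_by(condition, stimulus_type) |>
    dplyr::summarise(acc = mean(correct), n = dplyr::n(), .groups = "drop")
  # 3 SE binomial band around 0.5
  expect_true(all(abs(cells$acc - 0.5) <= 3 * sqrt(0.25 / cells$n)))
})

test_that("injected cell probabilities are recovered at large n", {
  h <- 0.72
  f <- 0.31
  m <- response_model(
    tibble::tibble(
      condition = "baseline",
      stimulus_type = c("WORD", "PW12", "PW21"),
      p_word = c(h, f, f)
    ),
    subject_sd = 0
  )
  d <- design_spec("between", n_participants = 10000, conditions = "baseline")
  r <- simulate_responses(d, m, seed = 10)
  rates <- r |>
    dplyr::group_by(stimulus_type) |>
    dplyr::summarise(
      endorsed = sum(response == "WORD_YES"),
      n = dplyr::n()
    )
  for (i in seq_len(nrow(rates))) {
    target <- if (rates$stimulus_type[i] == "WORD") h else f
    ci <- stats::binom.test(rates$endorsed[i], rates$n[i],
      conf.level = 0.99
    )$conf.int
    expect_gte(target, ci[1])
    expect_lte(target, ci[2])
  }
})
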