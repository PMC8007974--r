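# Frozen quantile values cross-checked against an inverse-error-function
# oracle (qnorm(p) = sqrt(2) * erfinv(2p - 1)):
#   z(0.875) - z(0.0625) = 2.684470
#   z(0.75)  - z(0.25)   = 1.348980

test_that("the 1/(2N) rule maps boundary proportions and leaves the interior alone", {
  expect_identical(adjust_rate(1, 4), 0.875)
  expect_identical(adjust_rate(0, 8), 0.0625)
  expect_identical(adjust_rate(0.5, 4), 0.5)
  expect_identical(adjust_rate(c(0, 0.25, 1), 8), c(0.0625, 0.25, 0.9375))
  expect_error(adjust_rate(0.5, 0), "positive")
})

make_records <- function(hits, fas, participant = 1, condition = "baseline") {
  tibble::tibble(
    participant = participant,
    condition = condition,
    stimulus_type = c(rep("WORD", 4), rep("PW12", 4), rep("PW21", 4)),
    response = c(
      rep("WORD_YES", hits), rep("WORD_NO", 4 - hits),
      rep("WORD_YES", fas), rep("WORD_NO", 8 - fas)
    )
  ) |>
    dplyr::mutate(correct = (response == "WORD_YES") == (stimulus_type == "WORD"))
}

test_that("d-prime matches the normal-quantile oracle on hand-built cells", {
  skip_if_not_installed("pracma")
  z <- function(p) sqrt(2) * pracma::erfinv(2 * p - 1)

  perfect <- sdt_dprime(make_records(hits = 4, fas = 0))
  expect_identical(
    c(perfect$hits, perfect$misses, perfect$false_alarms, perfect$correct_rejections),
    c(4L, 0L, 0L, 8L)
  )
  expect_identical(c(perfect$adj_hit_rate, perfect$adj_fa_rate), c(0.875, 0.0625))
  expect_equal(perfect$d_prime, 2.684470, tolerance = 1e-6)
  expect_equal(perfect$d_prime, z(0.875) - z(0.0625), tolerance = 1e-9)

  mid <- sdt_dprime(make_records(hits = 3, fas = 2))
  expect_equal(mid$d_prime, 1.348980, tolerance = 1e-6)
  expect_equal(mid$d_prime, z(0.75) - z(0.25), tolerance = 1e-9)

  chance <- sdt_dprime(make_records(hits = 2, fas = 4))
  expect_identical(chance$d_prime, 0)
})

test_that("d-prime is monotone in hits and false alarms", {
  d_of <- function(h, f) sdt_dprime(make_records(h, f))$d_prime
  for (f in c(0, 3, 8)) {
    ds <- vapply(0:4, d_of, numeric(1), f = f)
    expect_true(all(diff(ds) > 0))
  }
  for (h in c(0, 2, 4)) {
    ds <- vapply(0:8, function(f) d_of(h, f), numeric(1))
    expect_true(all(diff(ds) < 0))
  }
})

test_that("group summaries use t intervals over participants", {
  recs <- dplyr::bind_rows(
    make_records(4, 0, participant = 1),
    make_records(3, 2, participant = 2),
    make_records(2, 4, participant = 3)
  )
  dp <- sdt_dprime(recs)
  gs <- dprime_summary(dp)
  d <- dp$d_prime
  expect_equal(gs$mean_d_prime, mean(d))
  half <- qt(0.975, 2) * sd(d) / sqrt(3)
  expect_equal(gs$ci_low, mean(d) - half)
  expect_equal(gs$ci_high, mean(d) + half)
  expect_identical(gs$n, 3L)
  expect_error(dprime_summary(sdt_dprime(make_records(4, 0))), "at least 2")
})

test_that("proportion correct matches hand-computed values on a toy table", {
  recs <- dplyr::bind_rows(
    make_records(4, 0, participant = 1), # WORD 1.00, PW 1.00
    make_records(2, 4, participant = 2), # WORD 0.50, PW 0.50
    make_records(1, 6, participant = 3) # WORD 0.25, PW 0.25
  )
  pc <- proportion_correct(recs, n_boot = 50, seed = 1)
  word <- pc[pc$stimulus_type == "WORD", ]
  expect_equal(word$prop_correct, mean(c(1, 0.5, 0.25)))
  expect_identical(word$n_participants, 3L)
  expect_true(all(pc$ci_low <= pc$prop_correct & pc$prop_correct <= pc$ci_high))
})

test_that("long-format export round-trips losslessly", {
  recs <- simulate_responses(design_spec("within_all4"), cue_pattern_model(), seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  export_long_format(recs, path)
  lines <- readLines(path)
  expect_identical(length(lines), nrow(recs) + 1L) # header + one row per record
  back <- read_long_format(path)
  expect_identical(
    as.data.frame(back[order(back$participant, back$condition_order, back$trial), ]),
    as.data.frame(recs[
      order(recs$participant, recs$condition_order, recs$trial),
      names(back)
    ])
  )
  # empty record set yields a header-only file
  path2 <- withr::local_tempfile(fileext = ".csv")
  export_long_format(recs[0, ], path2)
  expect_identical(length(readLines(path2)), 1L)
})

test_that("simulated mean d-prime converges to the analytic expectation", {
  h <- 0.8
  f <- 0.3
  m <- response_model(
    tibble::tibble(
      condition = "baseline",
      stimulus_type = c("WORD", "PW12", "PW21"),
      p_word = c(h, f, f)
    ),
    subject_sd = 0
  )
  d <- design_spec("between", n_participants = 10000, conditions = "baseline")
  dp <- sdt_dprime(simulate_responses(d, m, seed = 13))
  analytic <- expected_d_prime(h, f)
  mc_se <- sd(dp$d_prime) / sqrt(nrow(dp))
  expect_lt(abs(mean(dp$d_prime) - analytic), 4 * mc_se)
})

test_that("tidy and glance work on d-prime tables", {
  recs <- simulate_responses(
    design_spec("between", n_participants = 12, conditions = c("baseline", "pause")),
    cue_pattern_model(),
    seed = 14
  )
  dp <- sdt_dprime(recs)
  expect_s3_class(tidy(dp), "tbl_df")
  gl <- glance(dp)
  expect_identical(gl$n_participants, 12L)
  expect_identical(gl$n_conditions, 2L)
})

test_that("plot builders return ggplot objects", {
  recs <- simulate_responses(design_spec("within_all4"), cue_pattern_model(), seed = 15)
  gs <- dprime_summary(sdt_dprime(recs))
  expect_s3_class(autoplot(gs), "ggplot")
  pc <- proportion_correct(recs, n_boot = 20, seed = 1)
  expect_s3_class(autoplot(pc), "ggplot")
  st <- compose_stream(builtin_languages()$L0, "pause", n_repeats = 10, seed = 1)
  expect_s3_class(plot_stream(st), "ggplot")
})
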