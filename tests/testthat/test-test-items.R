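test_that("each part-word class has exactly 12 distinct members", {
  for (lang in builtin_languages()) {
    for (cls in c("PW12", "PW21")) {
      pw <- enumerate_part_words(lang, cls)
      expect_identical(nrow(pw), 12L)
      expect_identical(dplyr::n_distinct(pw$item), 12L)
      expect_false(any(pw$item %in% lang$words))
    }
  }
})

test_that("part-words follow the class construction rules", {
  lang <- builtin_languages()$L1
  pw12 <- enumerate_part_words(lang, "PW12")
  expect_true("podela" %in% pw12$item) # po | de la
  for (i in seq_len(nrow(pw12))) {
    expect_identical(pw12$syl1[i], lang$syllables[pw12$source_a[i], "final"][[1]])
    expect_identical(pw12$syl2[i], lang$syllables[pw12$source_b[i], "initial"][[1]])
    expect_identical(pw12$syl3[i], lang$syllables[pw12$source_b[i], "medial"][[1]])
    expect_true(pw12$source_a[i] != pw12$source_b[i])
  }
  pw21 <- enumerate_part_words(lang, "PW21")
  expect_true("kupode" %in% pw21$item) # ku po | de
  for (i in seq_len(nrow(pw21))) {
    expect_identical(pw21$syl1[i], lang$syllables[pw21$source_a[i], "medial"][[1]])
    expect_identical(pw21$syl2[i], lang$syllables[pw21$source_a[i], "final"][[1]])
    expect_identical(pw21$syl3[i], lang$syllables[pw21$source_b[i], "initial"][[1]])
  }
})

test_that("enumerated part-words equal the boundary triples realized in a long stream", {
  lang <- builtin_languages()$L2
  st <- build_stream(lang, generate_word_order(4, 24, seed = 11))
  syl <- st$syllable
  pos <- st$position
  n <- length(syl)
  triples <- paste0(syl[1:(n - 2)], syl[2:(n - 1)], syl[3:n])
  # boundary-spanning windows by the position of their first syllable
  observed_pw12 <- unique(triples[pos[1:(n - 2)] == "final"])
  observed_pw21 <- unique(triples[pos[1:(n - 2)] == "medial"])
  expect_setequal(observed_pw12, enumerate_part_words(lang, "PW12")$item)
  expect_setequal(observed_pw21, enumerate_part_words(lang, "PW21")$item)
})

test_that("the fixed pilot test set matches the published item lists", {
  ts <- select_test_set(builtin_languages()$L0, mode = "fixed_exp1")
  expect_identical(nrow(ts), 12L)
  expect_setequal(
    ts$item[ts$stimulus_type == "WORD"],
    c("batuki", "togabi", "punido", "dapiku")
  )
  expect_setequal(
    ts$item[ts$stimulus_type == "PW12"],
    c("kutoga", "kipuni", "dotoga", "bidapi")
  )
  expect_setequal(
    ts$item[ts$stimulus_type == "PW21"],
    c("tukipu", "pikuba", "tukida", "nidoba")
  )
  # the published pilot list does NOT satisfy the once-per-part constraint:
  # "toga" appears as second part twice in the PW12 list
  second_parts <- ts$source_b[ts$stimulus_type == "PW12"]
  expect_true(any(duplicated(second_parts)))
  expect_error(
    select_test_set(builtin_languages()$L1, mode = "fixed_exp1"),
    "only defined for language L0"
  )
})

test_that("random test sets pair each first and second part exactly once per class", {
  lang <- builtin_languages()$L3
  for (seed in 1:8) {
    ts <- select_test_set(lang, mode = "random_exp2", seed = seed)
    expect_identical(nrow(ts), 12L)
    expect_identical(sum(ts$stimulus_type == "WORD"), 4L)
    for (cls in c("PW12", "PW21")) {
      sel <- ts[ts$stimulus_type == cls, ]
      expect_setequal(sel$source_a, 1:4)
      expect_setequal(sel$source_b, 1:4)
      expect_true(all(sel$source_a != sel$source_b))
    }
  }
})

test_that("exactly 9 per-class selections exist (derangements of 4)", {
  # brute force over all 24 permutations of the second parts
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), , drop = FALSE]
  valid <- perms[apply(perms, 1, function(p) all(p != 1:4)), , drop = FALSE]
  expect_identical(nrow(valid), 9L)
  expect_identical(nrow(derangements(4)), 9L)
  expect_setequal(
    apply(valid, 1, paste, collapse = ""),
    apply(derangements(4), 1, paste, collapse = "")
  )
})

test_that("random selections are uniform over the 9 derangements", {
  lang <- builtin_languages()$L4
  d <- derangements(4)
  keys <- apply(d, 1, paste, collapse = "")
  draws <- character(9000)
  set.seed(77)
  for (i in seq_along(draws)) {
    ts <- select_test_set(lang, mode = "random_exp2")
    sel <- ts[ts$stimulus_type == "PW12", ]
    draws[i] <- paste(sel$source_b[order(sel$source_a)], collapse = "")
  }
  expect_true(all(draws %in% keys))
  p <- stats::chisq.test(table(factor(draws, levels = keys)))$p.value
  expect_gt(p, 0.01)
})
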