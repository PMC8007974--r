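#' Enumerate all part-words of one class for a language
#'
#' Part-words are boundary-spanning syllable triples. A part-word 1-2
#' (`"PW12"`) takes the final syllable of word A followed by the initial and
#' medial syllables of word B; a part-word 2-1 (`"PW21"`) takes the medial
#' and final syllables of A followed by the initial syllable of B (A != B in
#' both classes). With four words each class has exactly 4 * 3 = 12 members,
#' and every member actually occurs across some word boundary in the stream.
#'
#' @param language A `seg_language`.
#' @param part_word_class `"PW12"` or `"PW21"`.
#' @return A tibble with one row per part-word: `item`, `syl1`–`syl3`,
#'   `stimulus_type`, `source_a`, `source_b` (word indices).
#' @examples
#' enumerate_part_words(builtin_languages()$L1, "PW12")
#' @export
enumerate_part_words <- function(language, part_word_class = c("PW12", "PW21")) {
  part_word_class <- match.arg(part_word_class)
  stopifnot(inherits(language, "seg_language"))
  syl <- language$syllables
  pairs <- tidyr::expand_grid(source_a = 1:4, source_b = 1:4) |>
    dplyr::filter(.data$source_a != .data$source_b)
  triples <- if (part_word_class == "PW12") {
    cbind(
      syl[pairs$source_a, "final"],
      syl[pairs$source_b, "initial"],
      syl[pairs$source_b, "medial"]
    )
  } else {
    cbind(
      syl[pairs$source_a, "medial"],
      syl[pairs$source_a, "final"],
      syl[pairs$source_b, "initial"]
    )
  }
  tibble::tibble(
    item = paste0(triples[, 1], triples[, 2], triples[, 3]),
    syl1 = triples[, 1], syl2 = triples[, 2], syl3 = triples[, 3],
    stimulus_type = part_word_class,
    source_a = pairs$source_a,
    source_b = pairs$source_b
  )
}

## All permutations of 1:n (n small), as a matrix with one row each.
permutations <- function(n) {
  if (n == 1L) {
    return(matrix(1L, 1, 1))
  }
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Derangements of 1:n
#'
#' Permutations with no fixed point; there are 9 for n = 4. Used to select
#' part-word test sets in which every word contributes its "first part" and
#' its "second part" exactly once per class.
#'
#' @param n Number of elements.
#' @return Integer matrix, one derangement per row.
#' @export
derangements <- function(n) {
  p <- permutations(n)
  p[apply(p, 1, function(x) all(x != seq_len(n))), , drop = FALSE]
}

# The fixed Exp-1 test list for language L0 (/batuki/ /togabi/ /punido/
# /dapiku/), as (source_a, source_b) word-index pairs:
# PW12 /ku-toga/ /ki-puni/ /do-toga/ /bi-dapi/; PW21 /tuki-pu/ /piku-ba/
# /tuki-da/ /nido-ba/. Note the PW12 list reuses "toga" twice, so the later
# once-per-part constraint does not hold for this list.
fixed_exp1_pairs <- list(
  PW12 = cbind(a = c(4L, 1L, 3L, 2L), b = c(2L, 3L, 2L, 4L)),
  PW21 = cbind(a = c(1L, 4L, 1L, 3L), b = c(3L, 1L, 4L, 1L))
)

#' Select a 12-item test set (4 words, 4 PW12, 4 PW21)
#'
#' Two selection modes:
#'
#' * `"fixed_exp1"` — the fixed published list for language `L0`.
#' * `"random_exp2"` — per class, a uniformly drawn derangement `s` of the
#'   word indices pairs word `i`'s part with word `s(i)`'s part, so that each
#'   first part and each second part is represented exactly once per class.
#'   There are exactly 9 such selections per class.
#'
#' @param language A `seg_language`.
#' @param mode `"random_exp2"` or `"fixed_exp1"`.
#' @param seed Seed for the random selection.
#' @return A tibble of 12 test items (columns as [enumerate_part_words()],
#'   with `source_a = source_b = NA` replaced by the word's own index for
#'   `WORD` rows), class `seg_test_set`.
#' @examples
#' select_test_set(builtin_languages()$L1, seed = 1)
#' @export
select_test_set <- function(language, mode = c("random_exp2", "fixed_exp1"),
                            seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(language, "seg_language"))
  if (!is.null(seed)) withr::local_seed(seed)

  words <- tibble::tibble(
    item = language$words,
    syl1 = language$syllables[, "initial"],
    syl2 = language$syllables[, "medial"],
    syl3 = language$syllables[, "final"],
    stimulus_type = "WORD",
    source_a = 1:4,
    source_b = 1:4
  )

  pick <- function(class) {
    all_items <- enumerate_part_words(language, class)
    if (mode == "fixed_exp1") {
      if (language$language_id != "L0") {
        stop("fixed_exp1 selection is only defined for language L0", call. = FALSE)
      }
      pairs <- fixed_exp1_pairs[[class]]
    } else {
      d <- derangements(4L)
      s <- d[sample(nrow(d), 1L), ]
      pairs <- cbind(a = 1:4, b = s)
    }
    dplyr::inner_join(
      tibble::tibble(source_a = pairs[, 1], source_b = pairs[, 2]),
      all_items,
      by = c("source_a", "source_b")
    ) |>
      dplyr::select(dplyr::all_of(names(all_items)))
  }

  out <- dplyr::bind_rows(words, pick("PW12"), pick("PW21"))
  out$language_id <- language$language_id
  class(out) <- c("seg_test_set", class(words))
  out
}
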