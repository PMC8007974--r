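#' Language profiles for pseudo-language generation
#'
#' A profile fixes the syllable inventory (vowel and consonant pools) and the
#' distributional constraints that a four-word CV pseudo-language must satisfy.
#' Two profiles are built in:
#'
#' * `"exp1"` — 4 vowels (a, u, i, o), 7 consonants (p, t, k, b, d, g, n);
#'   the only word-level constraint is that no syllable repeats within a word.
#' * `"exp2"` — 5 vowels (a, e, i, o, u), 13 consonants (stops b, d, g, p, t,
#'   k; fricatives f, v, s; sonorants m, n, l, r). A language uses 12 distinct
#'   consonants (so every syllable is unique within the language), no word
#'   contains the same vowel twice, and across the 12 vowel slots two vowels
#'   occur three times and three occur twice.
#'
#' @param name `"exp1"` or `"exp2"`.
#' @return A list of class `seg_profile` with elements `name`, `vowels`,
#'   `consonants`.
#' @examples
#' language_profile("exp2")
#' @export
language_profile <- function(name = c("exp1", "exp2")) {
  name <- match.arg(name)
  prof <- switch(name,
    exp1 = list(
      name = "exp1",
      vowels = c("a", "u", "i", "o"),
      consonants = c("p", "t", "k", "b", "d", "g", "n")
    ),
    exp2 = list(
      name = "exp2",
      vowels = c("a", "e", "i", "o", "u"),
      consonants = c("b", "d", "g", "p", "t", "k", "f", "v", "s", "m", "n", "l", "r")
    )
  )
  structure(prof, class = "seg_profile")
}

#' @export
print.seg_profile <- function(x, ...) {
  cat("<seg_profile ", x$name, ">\n", sep = "")
  cat("  vowels:     ", paste(x$vowels, collapse = " "), "\n")
  cat("  consonants: ", paste(x$consonants, collapse = " "), "\n")
  invisible(x)
}

## Split a 6-character CV word into its three CV syllables.
split_syllables <- function(word) {
  stopifnot(nchar(word) == 6L)
  substring(word, c(1L, 3L, 5L), c(2L, 4L, 6L))
}

new_language <- function(words, profile, language_id) {
  syl <- t(vapply(words, split_syllables, character(3L)))
  dimnames(syl) <- list(NULL, c("initial", "medial", "final"))
  structure(
    list(
      language_id = language_id,
      words = unname(words),
      syllables = syl,
      profile = profile
    ),
    class = "seg_language"
  )
}

#' Construct a pseudo-language from explicit word strings
#'
#' @param words Character vector of four 6-character CV words (e.g.
#'   `"batuki"`).
#' @param profile A [language_profile()] (or its name).
#' @param language_id Label for the language.
#' @return A `seg_language` object.
#' @examples
#' pseudo_language(c("batuki", "togabi", "punido", "dapiku"), "exp1", "L0")
#' @export
pseudo_language <- function(words, profile = "exp2", language_id = "L") {
  if (is.character(profile)) profile <- language_profile(profile)
  if (length(words) != 4L || any(nchar(words) != 6L)) {
    stop("a pseudo-language needs exactly 4 six-character CV words", call. = FALSE)
  }
  new_language(words, profile, language_id)
}

#' @export
print.seg_language <- function(x, ...) {
  cat("<seg_language ", x$language_id, "> [", x$profile$name, "] ",
    paste0("/", x$words, "/", collapse = " "), "\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn pseudo_language One row per word with its three syllables.
#' @param x A `seg_language`.
#' @param ... Unused.
#' @export
tidy.seg_language <- function(x, ...) {
  tibble::tibble(
    language_id = x$language_id,
    word_index = seq_along(x$words),
    word = x$words,
    initial = x$syllables[, "initial"],
    medial = x$syllables[, "medial"],
    final = x$syllables[, "final"]
  )
}

#' @describeIn pseudo_language One-row summary (profile, validity, pool usage).
#' @export
glance.seg_language <- function(x, ...) {
  rep <- validate_language(x)
  syl <- as.vector(x$syllables)
  tibble::tibble(
    language_id = x$language_id,
    profile = x$profile$name,
    n_words = length(x$words),
    n_distinct_syllables = dplyr::n_distinct(syl),
    n_distinct_consonants = dplyr::n_distinct(substr(syl, 1, 1)),
    valid = rep$pass
  )
}

#' The published pseudo-languages
#'
#' Returns the five fixed pseudo-languages used by the three experimental
#' designs: `L0` (the single language of the between-subjects pilot, built on
#' the `"exp1"` profile) and `L1`–`L4` (the four mutually constrained
#' languages of the within-subjects designs, `"exp2"` profile).
#'
#' @return Named list of `seg_language` objects.
#' @examples
#' builtin_languages()$L1
#' @export
builtin_languages <- function() {
  list(
    L0 = pseudo_language(c("batuki", "togabi", "punido", "dapiku"), "exp1", "L0"),
    L1 = pseudo_language(c("bakupo", "delaru", "fumesi", "gonite"), "exp2", "L1"),
    L2 = pseudo_language(c("pifoke", "rovali", "nusema", "tabigu"), "exp2", "L2"),
    L3 = pseudo_language(c("dafego", "pebomi", "kirune", "lutiva"), "exp2", "L3"),
    L4 = pseudo_language(c("mabopi", "veduka", "sigale", "tonifu"), "exp2", "L4")
  )
}

#' Validate a pseudo-language against its profile constraints
#'
#' Checks every constraint of the language's profile and reports each
#' violation by name rather than raising an error, so corrupted languages can
#' be inspected.
#'
#' Constraint names: `"word count"`, `"syllable form"`,
#' `"identical syllables within word"`, `"repeated vowel within word"`,
#' `"repeated consonant within language"`, `"vowel distribution"`,
#' `"duplicate words"`.
#'
#' @param language A `seg_language`.
#' @return A list with `pass` (logical) and `violations` (character vector of
#'   violated constraint names, empty when valid).
#' @examples
#' validate_language(builtin_languages()$L1)$pass
#' @export
validate_language <- function(language) {
  stopifnot(inherits(language, "seg_language"))
  prof <- language$profile
  v <- character(0)

  if (length(language$words) != 4L) v <- c(v, "word count")

  syl <- as.vector(t(language$syllables)) # word-major order
  cons <- substr(syl, 1, 1)
  vows <- substr(syl, 2, 2)
  if (any(nchar(syl) != 2L) || !all(cons %in% prof$consonants) ||
    !all(vows %in% prof$vowels)) {
    v <- c(v, "syllable form")
  }

  per_word <- split(syl, rep(seq_along(language$words), each = 3L))
  if (any(vapply(per_word, anyDuplicated, 0L) > 0L)) {
    v <- c(v, "identical syllables within word")
  }
  if (anyDuplicated(language$words)) v <- c(v, "duplicate words")

  if (prof$name == "exp2") {
    per_word_vowels <- split(vows, rep(seq_along(language$words), each = 3L))
    if (any(vapply(per_word_vowels, anyDuplicated, 0L) > 0L)) {
      v <- c(v, "repeated vowel within word")
    }
    if (anyDuplicated(cons)) v <- c(v, "repeated consonant within language")
    counts <- sort(as.integer(table(vows)), decreasing = TRUE)
    if (!identical(counts, c(3L, 3L, 2L, 2L, 2L))) v <- c(v, "vowel distribution")
  }

  list(pass = length(v) == 0L, violations = v)
}

#' Generate a random pseudo-language
#'
#' Rejection sampling over uniformly drawn candidate words: candidates are
#' drawn from the profile pools and kept only if the assembled language
#' passes [validate_language()] and contains no blocklisted word. For the
#' `"exp2"` profile the sampler draws 12 of the 13 consonants without
#' replacement and a vowel multiset with two vowels three times and three
#' vowels twice, then retries until no word repeats a vowel.
#'
#' @param profile A [language_profile()] or its name.
#' @param seed Integer seed; the same seed always yields the same language.
#' @param blocklist Optional character vector of forbidden word strings
#'   (e.g. real German/English words to screen out).
#' @param language_id Label for the generated language.
#' @param max_tries Retry cap before generation is declared unsatisfiable.
#' @return A valid `seg_language`.
#' @examples
#' generate_language("exp2", seed = 1)
#' @export
generate_language <- function(profile = "exp2", seed = NULL, blocklist = NULL,
                              language_id = "L", max_tries = 10000L) {
  if (is.character(profile)) profile <- language_profile(profile)
  if (!is.null(seed)) withr::local_seed(seed)

  for (i in seq_len(max_tries)) {
    lang <- switch(profile$name,
      exp1 = draw_language_exp1(profile, language_id),
      exp2 = draw_language_exp2(profile, language_id)
    )
    if (is.null(lang)) next
    if (!is.null(blocklist) && any(lang$words %in% blocklist)) next
    if (validate_language(lang)$pass) {
      return(lang)
    }
  }
  stop("could not generate a valid pseudo-language in ", max_tries,
    " tries (constraints or blocklist unsatisfiable)",
    call. = FALSE
  )
}

draw_language_exp1 <- function(profile, language_id) {
  draw_word <- function() {
    repeat {
      s <- paste0(
        sample(profile$consonants, 3L, replace = TRUE),
        sample(profile$vowels, 3L, replace = TRUE)
      )
      if (!anyDuplicated(s)) {
        return(paste(s, collapse = ""))
      }
    }
  }
  words <- replicate(4L, draw_word())
  if (anyDuplicated(words)) {
    return(NULL)
  }
  new_language(words, profile, language_id)
}

draw_language_exp2 <- function(profile, language_id) {
  cons <- sample(profile$consonants, 12L)
  v3 <- sample(profile$vowels, 2L)
  v2 <- setdiff(profile$vowels, v3)
  pool <- c(rep(v3, each = 3L), rep(v2, each = 2L))
  vows <- sample(pool, 12L)
  word_of <- rep(1:4, each = 3L)
  if (any(vapply(split(vows, word_of), anyDuplicated, 0L) > 0L)) {
    return(NULL)
  }
  syl <- paste0(cons, vows)
  words <- vapply(split(syl, word_of), paste, character(1L), collapse = "")
  new_language(words, profile, language_id)
}

#' Generate a mutually constrained set of pseudo-languages
#'
#' Generates `n_languages` languages one at a time, rejecting any language
#' that would make some syllable occur more than twice across the whole set
#' (the cross-language constraint of the within-subjects designs).
#'
#' @inheritParams generate_language
#' @param n_languages Number of languages (4 in the published designs).
#' @param max_tries Per-language retry cap.
#' @return A named list of `seg_language` objects (`L1`, `L2`, ...).
#' @examples
#' langs <- generate_language_set(seed = 42)
#' max(table(unlist(lapply(langs, function(l) l$syllables))))
#' @export
generate_language_set <- function(profile = "exp2", n_languages = 4L,
                                  seed = NULL, blocklist = NULL,
                                  max_tries = 10000L) {
  if (is.character(profile)) profile <- language_profile(profile)
  if (!is.null(seed)) withr::local_seed(seed)

  langs <- list()
  tally <- integer(0) # syllable -> occurrences so far
  for (k in seq_len(n_languages)) {
    ok <- FALSE
    for (i in seq_len(max_tries)) {
      cand <- tryCatch(
        generate_language(profile,
          seed = NULL, blocklist = blocklist,
          language_id = paste0("L", k), max_tries = max_tries
        ),
        error = function(e) NULL
      )
      if (is.null(cand)) next
      syl <- as.vector(cand$syllables)
      new_tally <- tally
      for (s in syl) new_tally[s] <- (if (s %in% names(new_tally)) new_tally[[s]] else 0L) + 1L
      if (all(new_tally <= 2L)) {
        tally <- new_tally
        langs[[paste0("L", k)]] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("cross-language syllable constraint unsatisfiable after ",
        max_tries, " tries",
        call. = FALSE
      )
    }
  }
  langs
}

#' Check the cross-language constraint on a set of languages
#'
#' @param languages List of `seg_language` objects.
#' @param max_occurrences Maximum allowed occurrences of any syllable across
#'   the set (2 in the published designs).
#' @return A list with `pass` and the syllable occurrence table (tibble).
#' @export
validate_language_set <- function(languages, max_occurrences = 2L) {
  syl <- unlist(lapply(languages, function(l) as.vector(l$syllables)))
  tab <- tibble::as_tibble(table(syllable = syl), .name_repair = "minimal")
  names(tab) <- c("syllable", "n")
  tab$n <- as.integer(tab$n)
  list(
    pass = all(tab$n <= max_occurrences) &&
      all(vapply(languages, function(l) validate_language(l)$pass, TRUE)),
    counts = tab
  )
}

#' Serialize / restore pseudo-languages as a JSON manifest
#'
#' @param languages A `seg_language` or list of them.
#' @param path File path for the manifest.
#' @return `write_language_manifest()` returns `path` invisibly;
#'   `read_language_manifest()` returns a named list of `seg_language`.
#' @export
write_language_manifest <- function(languages, path) {
  if (inherits(languages, "seg_language")) languages <- list(languages)
  payload <- lapply(languages, function(l) {
    list(language_id = l$language_id, words = l$words, profile = l$profile$name)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_language_manifest
#' @export
read_language_manifest <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  langs <- lapply(payload, function(p) {
    pseudo_language(p$words, p$profile, p$language_id)
  })
  names(langs) <- vapply(langs, function(l) l$language_id, character(1))
  langs
}
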